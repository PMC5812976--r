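test_that("pg_dist validates the simplex and exposes p, k, p1", {
  d <- pg_dist(c(0.15, 0.20, 0.05, 0.10, 0.30, 0.20))
  expect_equal(allele_freq(d), 0.15 + 0.10 + (0.20 + 0.30) / 2)
  expect_equal(pheno_freq(d), 0.4)
  expect_error(pg_dist(c(0.5, 0.5, 0.1, 0, 0, 0)), "sum to 1")
  expect_error(pg_dist(c(-0.1, 0.4, 0.1, 0.2, 0.2, 0.2)), "nonnegative")

  expect_equal(reduced_coordinates(pg_dist(rep(1 / 6, 6))),
               c(k = 0.5, p1 = 0.5))
  allp2 <- pg_dist(c(0, 0, 0, 0.25, 0.5, 0.25))
  expect_warning(rc <- reduced_coordinates(allp2), "undefined")
  expect_true(is.na(rc["p1"]))
})

test_that("mendelian segregation is exact", {
  expect_equal(unname(mendelian_offspring("Aa", "Aa")), c(0.25, 0.5, 0.25))
  expect_equal(unname(mendelian_offspring("AA", "aa")), c(0, 1, 0))
  expect_equal(unname(mendelian_offspring("AA", "Aa")), c(0.5, 0.5, 0))
  expect_error(mendelian_offspring("AB", "Aa"), "unknown genotype")
})

test_that("mating distribution is the m-mixture with exact margins", {
  d <- pg_dist(c(0.15, 0.20, 0.05, 0.10, 0.30, 0.20))
  x <- as.vector(unclass(d))

  M0 <- mating_distribution(d, 0)
  expect_equal(unclass(M0)[, ], tcrossprod(x), ignore_attr = TRUE)

  M1 <- mating_distribution(d, 1)
  concordant <- sum(M1[1:3, 1:3]) + sum(M1[4:6, 4:6])
  expect_equal(concordant, 1)
  expect_equal(sum(M1[1:3, 1:3]), 0.4)  # mass with both spouses phenotype 1

  for (m in c(0, 0.3, 0.7, 1)) {
    M <- mating_distribution(d, m)
    expect_equal(unname(rowSums(M)), x, tolerance = 1e-14)
    expect_equal(unname(colSums(M)), x, tolerance = 1e-14)
    expect_equal(unclass(M)[, ], naive_mating_matrix(d, m),
                 ignore_attr = TRUE, tolerance = 1e-14)
  }
  expect_error(mating_distribution(d, 1.2), "\\[0, 1\\]")
})

test_that("one-generation recursion matches closed forms and the naive oracle", {
  # constant transmission: k' equals the constant regardless of dist and m
  flat <- bilinear_table(alpha = 0, beta = 0.3, eta = 0)
  for (m in c(0, 0.5)) {
    d <- next_generation(pg_dist(c(0.05, 0.1, 0.15, 0.2, 0.25, 0.25)),
                         flat, m)
    expect_equal(pheno_freq(d), 0.3)
  }

  # additive genetics only: k' = beta + 2 alpha p^2 + 2 p q sigma alpha
  tab <- bilinear_table(alpha = 0.2, beta = 0.2, eta = 0)
  d1 <- next_generation(hw_init(0.5, 0.5), tab, 0)
  expect_equal(pheno_freq(d1), 0.4)

  # engine agrees with the naive loop enumeration on random inputs
  set.seed(41)
  for (rep in 1:20) {
    rb <- random_bilinear()
    d <- random_pg_dist()
    m <- runif(1)
    expect_equal(unclass(next_generation(d, rb$table, m)),
                 unclass(naive_next_generation(d, rb$table, m)),
                 tolerance = 1e-12)
  }
})

test_that("allele frequency and total mass are conserved by the recursion", {
  set.seed(42)
  for (rep in 1:25) {
    rb <- random_bilinear()
    d <- random_pg_dist()
    m <- runif(1)
    p0 <- allele_freq(d)
    for (step in 1:5) d <- next_generation(d, rb$table, m)
    expect_equal(sum(unclass(d)), 1, tolerance = 1e-12)
    expect_equal(allele_freq(d), p0, tolerance = 1e-12)
  }
})

test_that("equilibrium solver converges to known fixed points", {
  # linear cultural recursion: k* = beta / (1 - 2 eta)
  tab <- bilinear_table(alpha = 0, beta = 0.2, eta = 0.25)
  eq <- find_equilibrium(tab, 0, hw_init(0.5, 0.9))
  expect_true(eq$converged)
  expect_equal(pheno_freq(eq$dist), 0.4, tolerance = 1e-10)

  # constant transmission reaches equilibrium in one step
  flat <- bilinear_table(alpha = 0, beta = 0.6, eta = 0)
  eq <- find_equilibrium(flat, 0, hw_init(0.3, 0.1))
  expect_equal(pheno_freq(eq$dist), 0.6)
  expect_equal(unname(rowSums(unclass(eq$dist))), c(0.09, 0.42, 0.49),
               tolerance = 1e-12)

  # additive-genetics equilibrium, reached in one step under random mating
  tab <- bilinear_table(alpha = 0.2, beta = 0.2, eta = 0)
  one <- next_generation(hw_init(0.5, 0.77), tab, 0)
  two <- next_generation(one, tab, 0)
  expect_equal(unclass(two), unclass(one), tolerance = 1e-12)
  eq <- find_equilibrium(tab, 0, hw_init(0.5, 0.2))
  expect_equal(pheno_freq(eq$dist), 0.4, tolerance = 1e-12)
  expect_equal(unname(rowSums(unclass(eq$dist))), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
  expect_equal(reduced_coordinates(eq$dist), c(k = 0.4, p1 = 0.625),
               tolerance = 1e-10)

  # equilibrium is a fixed point of the map
  tab <- bilinear_table(alpha = 0.2, beta = 0.1, eta = 0.2)
  eq <- find_equilibrium(tab, 0.5, hw_init(0.5, 0.1))
  stepped <- next_generation(eq$dist, tab, 0.5)
  expect_lt(max(abs(unclass(stepped) - unclass(eq$dist))), 1e-11)
})

test_that("non-convergence is reported honestly, not raised", {
  tab <- bilinear_table(alpha = 0.2, beta = 0.1, eta = 0.2)
  eq <- find_equilibrium(tab, 0.5, hw_init(0.5, 0.1), max_iter = 3)
  expect_false(eq$converged)
  expect_equal(eq$iterations, 3L)
  expect_gt(eq$residual, 1e-12)
})
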
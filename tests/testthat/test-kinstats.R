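# closed-form oracles used below:
#   pure additive, random mating (eta = 0, m = 0, sigma = 1, alpha = beta =
#   0.2, p = 0.5): V_A = 0.02, V_P = 0.24, r_po = r_dz = V_A / (2 V_P),
#   r_mz = V_A / V_P
#   pure cultural, tau = 1, m = 0 (alpha = 0, eta = 0.25, beta = 0.2):
#   r_po = eta, r_mz = r_dz = 2 eta^2

additive_fit <- function()
  gc_model(alpha = 0.2, beta = 0.2, eta = 0, m = 0, p = 0.5)
cultural_fit <- function()
  gc_model(alpha = 0, beta = 0.2, eta = 0.25, m = 0, p = 0.5)

test_that("phi correlation of a 2x2 joint matches its definition", {
  expect_equal(phi_correlation(matrix(c(0.28, 0.12, 0.12, 0.48), 2, 2)), 0.5)
  ind <- outer(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(phi_correlation(ind), 0)
  expect_equal(phi_correlation(matrix(c(0.4, 0, 0, 0.6), 2, 2)), 1)
  expect_error(phi_correlation(matrix(c(1, 0, 0, 0), 2, 2)), "degenerate")
})

test_that("spouse joint follows the assortment mixture", {
  d <- hw_init(0.5, 0.4)  # k = 0.4
  q <- spouse_joint(mating_distribution(d, 0.5))
  expect_equal(q[1, 1], 0.5 * 0.4 + 0.5 * 0.16)
  expect_equal(phi_correlation(q), 0.5)

  q0 <- spouse_joint(mating_distribution(d, 0))
  expect_equal(unclass(q0), outer(c(0.4, 0.6), c(0.4, 0.6)),
               ignore_attr = TRUE)
  q1 <- spouse_joint(mating_distribution(d, 1))
  expect_equal(q1[1, 2], 0)
  expect_equal(q1[2, 1], 0)
})

test_that("spousal correlation equals the assortment rate at any interior k", {
  set.seed(7)
  for (rep in 1:10) {
    rb <- random_bilinear()
    m <- runif(1, 0.05, 0.95)
    eq <- find_equilibrium(rb$table, m, hw_init(runif(1, 0.2, 0.8), 0.5))
    k <- pheno_freq(eq$dist)
    if (k <= 1e-6 || k >= 1 - 1e-6) next
    expect_equal(phi_correlation(spouse_joint(mating_distribution(eq$dist, m))),
                 m, tolerance = 1e-9)
  }
})

test_that("parent-offspring correlation matches closed forms", {
  # pure cultural transmission: r_po = eta
  fit <- cultural_fit()
  expect_equal(fit$kin$r_po, 0.25, tolerance = 1e-9)

  # pure additive genetics: r_po = V_A / (2 V_P)
  fit <- additive_fit()
  expect_equal(fit$kin$r_po, 0.02 / (2 * 0.24), tolerance = 1e-9)

  # no transmission at all: joint factorizes
  flat <- bilinear_table(alpha = 0, beta = 0.3, eta = 0)
  eq <- find_equilibrium(flat, 0, hw_init(0.5, 0.3))
  q <- parent_offspring_joint(eq$dist, flat, 0)
  expect_equal(phi_correlation(q), 0, tolerance = 1e-12)

  # bilinear tables are parentally symmetric
  tab <- bilinear_table(alpha = 0.2, beta = 0.1, eta = 0.2, tau = 1.5)
  eq <- find_equilibrium(tab, 0.5, hw_init(0.4, 0.1))
  qm <- parent_offspring_joint(eq$dist, tab, 0.5, "mother")
  qf <- parent_offspring_joint(eq$dist, tab, 0.5, "father")
  expect_equal(unclass(qm), unclass(qf), tolerance = 1e-12)
})

test_that("twin joints implement shared-genotype MZ vs independent DZ", {
  # additive: r_dz = V_A / (2 V_P), r_mz = V_A / V_P
  fit <- additive_fit()
  expect_equal(fit$kin$r_dz, 0.02 / 0.48, tolerance = 1e-9)
  expect_equal(fit$kin$r_mz, 0.02 / 0.24, tolerance = 1e-9)
  expect_equal(fit$kin$r_po, fit$kin$r_dz, tolerance = 1e-9)
  expect_equal(fit$kin$r_mz, 2 * fit$kin$r_dz, tolerance = 1e-9)

  # pure cultural: genotype is irrelevant, so MZ and DZ joints coincide
  fit <- cultural_fit()
  expect_equal(fit$kin$r_mz, fit$kin$r_dz, tolerance = 1e-12)
  expect_equal(fit$kin$r_mz, 2 * 0.25^2, tolerance = 1e-9)
  eq <- fit$equilibrium$dist
  expect_equal(unclass(twin_joint(eq, fit$table, 0, "MZ")),
               unclass(twin_joint(eq, fit$table, 0, "DZ")),
               tolerance = 1e-14)

  # r_mz >= r_dz whenever genetics contributes
  set.seed(11)
  for (rep in 1:10) {
    rb <- random_bilinear()
    if (rb$par$alpha < 0.05) next
    m <- runif(1, 0, 0.9)
    eq <- find_equilibrium(rb$table, m, hw_init(runif(1, 0.2, 0.8), 0.5))
    kin <- kin_correlations(eq$dist, rb$table, m)
    expect_gte(kin$r_mz, kin$r_dz - 1e-12)
  }
})

test_that("twin joints agree with the naive enumeration oracle", {
  set.seed(13)
  for (rep in 1:8) {
    rb <- random_bilinear()
    m <- runif(1)
    eq <- find_equilibrium(rb$table, m, hw_init(runif(1, 0.2, 0.8), 0.5))
    for (zy in c("DZ", "MZ")) {
      expect_equal(unclass(twin_joint(eq$dist, rb$table, m, zy)),
                   naive_twin_joint(eq$dist, rb$table, m, zy),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("all kin joints have margins (k, 1 - k) at equilibrium", {
  tab <- bilinear_table(alpha = 0.2, beta = 0.1, eta = 0.2, sigma = 1.5,
                        tau = 0.8)
  eq <- find_equilibrium(tab, 0.6, hw_init(0.35, 0.1))$dist
  k <- pheno_freq(eq)
  joints <- list(spouse_joint(mating_distribution(eq, 0.6)),
                 parent_offspring_joint(eq, tab, 0.6),
                 twin_joint(eq, tab, 0.6, "DZ"),
                 twin_joint(eq, tab, 0.6, "MZ"))
  for (q in joints) {
    expect_equal(sum(q[1, ]), k, tolerance = 1e-9)
    expect_equal(sum(q[, 1]), k, tolerance = 1e-9)
  }
})
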
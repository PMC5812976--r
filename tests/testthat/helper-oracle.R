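# Naive enumeration oracles, written as plain loops over the public
# single-entry lookups so they stay independent of the vectorized
# quadratic-form engine they are used to check.

GENO <- c("AA", "Aa", "aa")

# state index i in 1..6 -> (genotype label, phenotype)
state_geno <- function(i) GENO[(i - 1L) %% 3L + 1L]
state_phen <- function(i) (i - 1L) %/% 3L + 1L

naive_mating_matrix <- function(dist, m) {
  x <- as.vector(unclass(dist))
  M <- matrix(0, 6, 6)
  k <- c(sum(x[1:3]), sum(x[4:6]))
  for (i in 1:6) for (j in 1:6) {
    R <- x[i] * x[j]
    A <- 0
    if (state_phen(i) == state_phen(j) && k[state_phen(i)] > 0)
      A <- x[i] * x[j] / k[state_phen(i)]
    M[i, j] <- m * A + (1 - m) * R
  }
  M
}

naive_next_generation <- function(dist, table, m) {
  M <- naive_mating_matrix(dist, m)
  out <- matrix(0, 3, 2)
  for (i in 1:6) for (j in 1:6) {
    if (M[i, j] == 0) next
    men <- mendelian_offspring(state_geno(i), state_geno(j))
    for (g in 1:3) {
      t1 <- transmission_prob(table, state_phen(i), state_phen(j), GENO[g])
      out[g, 1] <- out[g, 1] + M[i, j] * men[g] * t1
      out[g, 2] <- out[g, 2] + M[i, j] * men[g] * (1 - t1)
    }
  }
  pg_dist(out, normalize = TRUE)
}

naive_twin_joint <- function(eq, table, m, zygosity) {
  M <- naive_mating_matrix(eq, m)
  q <- matrix(0, 2, 2)
  for (i in 1:6) for (j in 1:6) {
    if (M[i, j] == 0) next
    men <- mendelian_offspring(state_geno(i), state_geno(j))
    tg <- vapply(1:3, function(g)
      transmission_prob(table, state_phen(i), state_phen(j), GENO[g]), 0)
    if (zygosity == "MZ") {
      p11 <- sum(men * tg^2); p1 <- sum(men * tg)
      q[1, 1] <- q[1, 1] + M[i, j] * p11
      q[1, 2] <- q[1, 2] + M[i, j] * (p1 - p11)
      q[2, 1] <- q[2, 1] + M[i, j] * (p1 - p11)
      q[2, 2] <- q[2, 2] + M[i, j] * (1 - 2 * p1 + p11)
    } else {
      p1 <- sum(men * tg)
      q[1, 1] <- q[1, 1] + M[i, j] * p1^2
      q[1, 2] <- q[1, 2] + M[i, j] * p1 * (1 - p1)
      q[2, 1] <- q[2, 1] + M[i, j] * (1 - p1) * p1
      q[2, 2] <- q[2, 2] + M[i, j] * (1 - p1)^2
    }
  }
  q
}

# random valid bilinear parameter set (entries guaranteed inside [0, 1])
random_bilinear <- function() {
  repeat {
    par <- list(alpha = runif(1, 0, 0.3), beta = runif(1, 0.02, 0.4),
                eta = runif(1, 0, 0.25), sigma = runif(1, 0, 2),
                tau = runif(1, 0, 2))
    tab <- try(bilinear_table(bilinear_params(par$alpha, par$beta, par$eta,
                                              par$sigma, par$tau)),
               silent = TRUE)
    if (!inherits(tab, "try-error")) return(list(par = par, table = tab))
  }
}

random_pg_dist <- function() pg_dist(stats::runif(6), normalize = TRUE)
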
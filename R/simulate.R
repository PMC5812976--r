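# Finite-population forward simulator: the stochastic counterpart of the
# deterministic recursion, sharing its mating law (the same
# mating_distribution object is sampled), Mendelian segregation, and
# Bernoulli phenotype acquisition from the transmission table.  Serves as
# an independent Monte-Carlo oracle and as a synthetic twin-data generator.

# sample n ordered matings (cells of the 6 x 6 mating distribution);
# returns a data.frame of parental genotype indices and phenotypes
sample_matings <- function(M, n) {
  cells <- stats::rmultinom(1L, n, as.vector(unclass(M)))[, 1L]
  idx <- rep.int(seq_len(36L), cells)
  i <- ((idx - 1L) %% 6L) + 1L   # mother state
  j <- ((idx - 1L) %/% 6L) + 1L  # father state
  data.frame(g_m = PG_GENO[i], g_f = PG_GENO[j],
             phi_m = PG_PHEN[i], phi_f = PG_PHEN[j])
}

# vectorized Mendelian genotype draw for mating rows
draw_offspring_genotype <- function(mat) {
  P <- matrix(mendel_array[cbind(rep(mat$g_m, 3L), rep(mat$g_f, 3L),
                                 rep(1:3, each = nrow(mat)))],
              nrow(mat), 3L)
  u <- stats::runif(nrow(mat))
  1L + (u > P[, 1L]) + (u > P[, 1L] + P[, 2L])
}

# vectorized phenotype draw (1/2) given parental phenotypes and own genotype
draw_offspring_phenotype <- function(table, mat, g_off) {
  p1 <- table[cbind(pair_row(mat$phi_m, mat$phi_f), g_off)]
  2L - (stats::runif(length(g_off)) < p1)
}

empirical_pg_dist <- function(genotype, phenotype) {
  counts <- tabulate(genotype + 3L * (phenotype - 1L), nbins = 6L)
  pg_dist(counts / sum(counts))
}

#' Simulate a finite population forward in time
#'
#' Agent-based realization of the deterministic model: the population starts
#' at Hardy-Weinberg proportions for `p0` with phenotype 1 assigned
#' independently at rate `k0`; each generation, `N/2` ordered matings are
#' drawn from the [mating_distribution()] of the current empirical
#' phenogenotype distribution, and each mating produces two offspring
#' (independent Mendelian genotype draws; phenotype Bernoulli from the
#' transmission table).  Fully reproducible given `seed`.
#'
#' @param table A `"transmission_table"`.
#' @param m Assortment rate in `[0, 1]`.
#' @param p0 Initial frequency of allele `A`.
#' @param N Population size (even, at least 2).
#' @param generations Number of generations to simulate.
#' @param seed Integer seed for the single pseudo-random stream of the run.
#' @param k0 Initial frequency of phenotype 1; defaults to the table's
#'   baseline rate (the `(2,2) x aa` entry, `beta` for a bilinear table).
#' @return A list of class `"agent_population"`: `genotype` and `phenotype`
#'   (integer vectors, genotype coded 1 = AA, 2 = Aa, 3 = aa; phenotype 1/2),
#'   `N`, `generations`, `seed`, `m`, `table`, `k_trajectory` (frequency of
#'   phenotype 1 per generation, starting at generation 0), and `matings`
#'   (the final generation's sampled parental pairs, for spousal
#'   correlation estimates).
#' @examples
#' tab <- bilinear_table(alpha = 0, beta = 0.3, eta = 0)
#' pop <- simulate_population(tab, m = 0, p0 = 0.5, N = 1000,
#'                            generations = 3, seed = 1)
#' mean(pop$phenotype == 1)
#' @export
simulate_population <- function(table, m, p0, N, generations, seed,
                                k0 = NULL) {
  stopifnot(inherits(table, "transmission_table"))
  check_m(m)
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N %% 2 != 0)
    stop("'N' must be an even integer >= 2", call. = FALSE)
  if (p0 < 0 || p0 > 1) stop("'p0' must lie in [0, 1]", call. = FALSE)
  if (is.null(k0)) k0 <- unname(table["2x2", "aa"])
  set.seed(seed)
  N <- as.integer(N)
  genotype <- sample.int(3L, N, replace = TRUE,
                         prob = c(p0^2, 2 * p0 * (1 - p0), (1 - p0)^2))
  phenotype <- 2L - (stats::runif(N) < k0)
  k_traj <- numeric(generations + 1L)
  k_traj[1L] <- mean(phenotype == 1L)
  matings <- NULL
  for (gen in seq_len(generations)) {
    M <- mating_distribution(empirical_pg_dist(genotype, phenotype), m)
    matings <- sample_matings(M, N %/% 2L)
    # two offspring per mating, independent draws
    mat2 <- matings[rep(seq_len(nrow(matings)), 2L), ]
    genotype <- draw_offspring_genotype(mat2)
    phenotype <- draw_offspring_phenotype(table, mat2, genotype)
    k_traj[gen + 1L] <- mean(phenotype == 1L)
  }
  structure(list(genotype = genotype, phenotype = phenotype, N = N,
                 generations = generations, seed = seed, m = m,
                 table = table, k_trajectory = k_traj, matings = matings),
            class = "agent_population")
}

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf(
    "Agent population: N = %d, %d generation%s, seed = %d, m = %g\n",
    x$N, x$generations, if (x$generations == 1L) "" else "s", x$seed, x$m))
  cat(sprintf("  final k = %.4f, p = %.4f\n", mean(x$phenotype == 1L),
              mean(2L - (x$genotype - 1L)) / 2))
  invisible(x)
}

#' Empirical phenogenotype distribution of a simulated population
#'
#' @param population An `"agent_population"`.
#' @return A `"pg_dist"` of the empirical frequencies.
#' @export
population_dist <- function(population) {
  stopifnot(inherits(population, "agent_population"))
  empirical_pg_dist(population$genotype, population$phenotype)
}

#' Generate synthetic twin pairs from a simulated population
#'
#' Draws matings from the mating distribution of the population's current
#' empirical phenogenotype frequencies and realizes twin phenotype pairs:
#' DZ pairs draw two genotypes independently by Mendelian segregation, MZ
#' pairs share a single genotype draw; in both cases the two phenotypes are
#' realized independently given own genotype and parental phenotypes.
#'
#' @param population An `"agent_population"` (phenotype must not be
#'   degenerate).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param n_pairs Number of twin pairs.
#' @param seed Integer seed.
#' @param table,m Transmission table and assortment rate; default to those
#'   stored in the population.
#' @return A data.frame of class `"twin_sample"` with columns `pair_id`,
#'   `zygosity`, `twin1`, `twin2` (phenotypes coded 1/2).
#' @export
sample_twin_pairs <- function(population, zygosity = c("DZ", "MZ"), n_pairs,
                              seed, table = population$table,
                              m = population$m) {
  stopifnot(inherits(population, "agent_population"))
  zygosity <- match.arg(zygosity)
  k <- mean(population$phenotype == 1L)
  if (k <= 0 || k >= 1)
    stop("population phenotype distribution is degenerate", call. = FALSE)
  set.seed(seed)
  M <- mating_distribution(population_dist(population), m)
  mat <- sample_matings(M, n_pairs)
  g1 <- draw_offspring_genotype(mat)
  g2 <- if (zygosity == "MZ") g1 else draw_offspring_genotype(mat)
  t1 <- draw_offspring_phenotype(table, mat, g1)
  t2 <- draw_offspring_phenotype(table, mat, g2)
  structure(data.frame(pair_id = seq_len(n_pairs), zygosity = zygosity,
                       twin1 = t1, twin2 = t2),
            class = c("twin_sample", "data.frame"))
}

#' Intraclass correlation of twin phenotypes
#'
#' Estimated by double entry: each pair contributes both orderings, and the
#' Pearson correlation of the doubled sample is the intraclass correlation.
#' The standard error is approximated as `(1 - r^2) / sqrt(n)`.
#'
#' @param sample A `"twin_sample"` (or any data.frame with columns `twin1`,
#'   `twin2`) with at least two pairs.
#' @return A list with `r`, `se` and `n` (number of pairs).
#' @export
estimate_correlation <- function(sample) {
  stopifnot(all(c("twin1", "twin2") %in% names(sample)))
  n <- nrow(sample)
  if (n < 2L)
    stop("at least 2 twin pairs are required", call. = FALSE)
  x <- c(sample$twin1, sample$twin2)
  y <- c(sample$twin2, sample$twin1)
  if (stats::var(x) == 0)
    stop("zero phenotype variance in the doubled sample: correlation undefined",
         call. = FALSE)
  r <- stats::cor(x, y)
  list(r = r, se = (1 - r^2) / sqrt(n), n = n)
}

#' Simulate finite populations from a fitted model
#'
#' Runs the agent-based forward simulator with the model's transmission
#' table, assortment rate and allele frequency.
#'
#' @param object A `"gc_model"`.
#' @param nsim Number of independent replicate populations.
#' @param seed Integer seed; replicate `i` uses `seed + i - 1`.
#' @param N,generations Size and length of each run.
#' @param ... Unused.
#' @return An `"agent_population"` if `nsim = 1`, else a list of them.
#' @export
simulate.gc_model <- function(object, nsim = 1, seed = 1, N = 20000,
                              generations = 20, ...) {
  runs <- lapply(seq_len(nsim), function(i)
    simulate_population(object$table, object$m, p0 = object$p, N = N,
                        generations = generations, seed = seed + i - 1L))
  if (nsim == 1L) runs[[1L]] else runs
}
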
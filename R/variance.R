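# Variance decomposition at equilibrium and the classical twin estimators.

#' Additive genetic variance of the phenotype indicator
#'
#' Least-squares regression of the phenotype-1 indicator on the count of
#' `A` alleles (dosage 0/1/2) over the realized joint genotype-phenotype
#' distribution: `V_A = slope^2 * Var(dosage)`.  Using the realized genotype
#' margin keeps the decomposition well defined when phenotypic assortment
#' distorts genotype frequencies away from Hardy-Weinberg; under random
#' mating it coincides with the textbook average-effect formula.
#'
#' @param dist A `"pg_dist"` (normally an equilibrium).
#' @return `V_A`, nonnegative.  When the locus is fixed (zero dosage
#'   variance) or the phenotype is degenerate, returns 0 with a warning.
#' @examples
#' tab <- bilinear_table(alpha = 0.2, beta = 0.2, eta = 0)
#' eq <- find_equilibrium(tab, m = 0, init = hw_init(0.5, 0.2))$dist
#' additive_variance(eq)  # 0.02
#' @export
additive_variance <- function(dist) {
  stopifnot(inherits(dist, "pg_dist"))
  m <- unclass(dist)
  k <- sum(m[, 1L])
  if (k <= 0 || k >= 1) {
    warning("degenerate phenotype distribution: V_A set to 0", call. = FALSE)
    return(0)
  }
  d <- c(2, 1, 0)                      # dosage of A by genotype row
  w <- rowSums(m)                      # genotype margin
  Ed <- sum(w * d)
  Vd <- sum(w * d^2) - Ed^2
  if (Vd <= .Machine$double.eps) {
    warning("allele effectively fixed (zero dosage variance): V_A set to 0",
            call. = FALSE)
    return(0)
  }
  cov_dphi <- sum(d * m[, 1L]) - Ed * k
  cov_dphi^2 / Vd                      # slope^2 * Vd
}

#' Actual narrow-sense heritability at equilibrium
#'
#' `h2_A = V_A / V_P` with phenotypic variance `V_P = k (1 - k)` of the
#' binary indicator.  Undefined (error) for a degenerate phenotype.
#'
#' @inheritParams additive_variance
#' @return `h2_A` in `[0, 1]`.
#' @export
narrow_heritability <- function(dist) {
  k <- pheno_freq(dist)
  if (k <= 0 || k >= 1)
    stop("narrow-sense heritability undefined: k is 0 or 1", call. = FALSE)
  additive_variance(dist) / (k * (1 - k))
}

#' Classical twin-correlation (Falconer) estimators
#'
#' The Method-1 estimators computed from MZ and DZ twin correlations:
#' genetic component `h2_F = 2 (r_mz - r_dz)` and common-environment
#' component `c2_F = 2 r_dz - r_mz`.  Values are reported as computed, not
#' clipped to `[0, 1]`, which keeps the identity `h2_F + c2_F = r_mz` exact.
#'
#' @param r_mz,r_dz Twin correlations in `[-1, 1]`.
#' @return Named vector `c(h2_F = , c2_F = )`.
#' @examples
#' falconer_estimates(0.65, 0.375)  # h2_F = 0.55, c2_F = 0.10
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  stopifnot(is.numeric(r_mz), is.numeric(r_dz),
            abs(r_mz) <= 1, abs(r_dz) <= 1)
  c(h2_F = 2 * (r_mz - r_dz), c2_F = 2 * r_dz - r_mz)
}
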
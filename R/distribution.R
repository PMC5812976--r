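# The state of the deterministic system: frequencies of the six
# phenogenotypes AA1, AA2, Aa1, Aa2, aa1, aa2 on the simplex.
# Internally a 3 x 2 matrix (genotype x phenotype); the length-6
# column-major vector (AA1, Aa1, aa1, AA2, Aa2, aa2) drives the recursion.

PG_TOL <- 1e-12

#' Phenogenotype frequency distribution
#'
#' Construct and validate the joint distribution of genotype (AA/Aa/aa) and
#' dichotomous phenotype (1/2) — six frequencies on the simplex.
#'
#' @param x A 3 x 2 matrix (rows AA, Aa, aa; columns phenotypes 1, 2) or a
#'   length-6 vector ordered `AA1, Aa1, aa1, AA2, Aa2, aa2`.
#' @param normalize If `TRUE`, rescale a nonnegative `x` to sum to 1.
#' @return A 3 x 2 matrix of class `"pg_dist"`.
#' @examples
#' pg_dist(c(0.15, 0.20, 0.05, 0.10, 0.30, 0.20))
#' @export
pg_dist <- function(x, normalize = FALSE) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(3L, 2L)))
      stop("'x' must be 3 x 2 (genotype x phenotype)", call. = FALSE)
    m <- x
  } else {
    if (length(x) != 6L)
      stop("'x' must have 6 frequencies", call. = FALSE)
    m <- matrix(x, nrow = 3L, ncol = 2L)
  }
  m <- unclass(m)
  if (any(!is.finite(m)) || any(m < -PG_TOL))
    stop("phenogenotype frequencies must be finite and nonnegative",
         call. = FALSE)
  m[m < 0] <- 0
  s <- sum(m)
  if (normalize) {
    if (s <= 0) stop("cannot normalize a zero distribution", call. = FALSE)
    m <- m / s
  } else if (abs(s - 1) > 1e-8) {
    stop(sprintf("frequencies must sum to 1 (got %.10g)", s), call. = FALSE)
  } else {
    m <- m / s
  }
  dimnames(m) <- list(GENOTYPES, c("1", "2"))
  structure(m, class = "pg_dist")
}

as_pg_vector <- function(dist) as.vector(unclass(dist))

#' Hardy-Weinberg initial distribution
#'
#' Genotypes at Hardy-Weinberg proportions for allele frequency `p`, with
#' phenotype 1 assigned independently with probability `k0` (clamped to
#' `[0, 1]`).  The default starting point of the solver.
#'
#' @param p Frequency of allele `A` in `[0, 1]`.
#' @param k0 Initial frequency of phenotype 1.
#' @return A `"pg_dist"`.
#' @export
hw_init <- function(p, k0) {
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]", call. = FALSE)
  k0 <- min(max(k0, 0), 1)
  g <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  pg_dist(cbind(g * k0, g * (1 - k0)))
}

#' Allele and phenotype frequencies of a distribution
#'
#' `allele_freq()` returns the frequency `p` of allele `A`;
#' `pheno_freq()` the frequency `k` of phenotype 1.  Both are invariant
#' summaries: `p` is conserved exactly by the recursion (no selection),
#' `k` converges to its equilibrium value.
#'
#' @param dist A `"pg_dist"`.
#' @return A number in `[0, 1]`.
#' @export
allele_freq <- function(dist) {
  m <- unclass(dist)
  unname(sum(m["AA", ]) + sum(m["Aa", ]) / 2)
}

#' @rdname allele_freq
#' @export
pheno_freq <- function(dist) {
  unname(sum(unclass(dist)[, 1L]))
}

#' Reduced coordinates (k, p1)
#'
#' The two summary coordinates of the dynamics: the frequency `k` of
#' phenotype 1 and the frequency `p1` of allele `A` among phenotype-1
#' individuals.  `p1` is undefined (returned as `NA` with a warning)
#' when `k = 0`.
#'
#' @param dist A `"pg_dist"`.
#' @return Named vector `c(k = , p1 = )`.
#' @examples
#' reduced_coordinates(pg_dist(rep(1 / 6, 6)))
#' @export
reduced_coordinates <- function(dist) {
  m <- unclass(dist)
  k <- sum(m[, 1L])
  if (k <= 0) {
    warning("k = 0: frequency of A among phenotype-1 individuals is undefined",
            call. = FALSE)
    return(c(k = 0, p1 = NA_real_))
  }
  p1 <- (m["AA", 1L] + m["Aa", 1L] / 2) / k
  c(k = unname(k), p1 = unname(p1))
}

#' @export
print.pg_dist <- function(x, digits = 6, ...) {
  cat("Phenogenotype distribution:\n")
  m <- unclass(x)
  colnames(m) <- c("phenotype 1", "phenotype 2")
  print(round(m, digits), ...)
  k <- pheno_freq(x)
  cat(sprintf("k = %.6g, p = %.6g", k, allele_freq(x)))
  if (k > 0) cat(sprintf(", p1 = %.6g", unname(reduced_coordinates(x)["p1"])))
  cat("\n")
  invisible(x)
}
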
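# One-generation recursion over the six phenogenotypes.  Mating is the
# standard partial-assortment mixture: with probability m a pair is drawn
# at random within a phenotype class, otherwise at random from the whole
# population.  Offspring genotypes follow Mendelian segregation; offspring
# phenotypes are Bernoulli with the transmission-table probability.

#' Mendelian offspring genotype distribution
#'
#' Exact segregation probabilities for the offspring of two diploid parents
#' at a diallelic locus.
#'
#' @param g_m,g_f Parental genotypes: `"AA"`, `"Aa"` or `"aa"`.
#' @return Named probability vector over `AA, Aa, aa`.
#' @examples
#' mendelian_offspring("Aa", "Aa")  # (1/4, 1/2, 1/4)
#' @export
mendelian_offspring <- function(g_m, g_f) {
  mendel_array[genotype_index(g_m), genotype_index(g_f), ]
}

# Precompute the quadratic-form kernels of the recursion for a fixed table:
#   W1[[g]](i, j) = Mendel(g | g_i, g_j) * P(phenotype 1 | table, pair, g)
#   W0[[g]](i, j) = Mendel(g | g_i, g_j)
# so that under mating distribution M, offspring frequencies are
#   x'[g, 1] = sum(M * W1[[g]]),  x'[g, .] = sum(M * W0[[g]]).
# Kernels are stacked 6 x 18 so all three genotypes evaluate in one product.
step_engine <- function(table) {
  stopifnot(inherits(table, "transmission_table"))
  men6 <- lapply(1:3, function(g)
    matrix(mendel_array[cbind(rep(PG_GENO, 6L), rep(PG_GENO, each = 6L), g)],
           6L, 6L))
  t6 <- lapply(1:3, function(g) matrix(table[PG_PAIR, g], 6L, 6L))
  W1 <- lapply(1:3, function(g) men6[[g]] * t6[[g]])
  W0 <- men6
  idx1 <- 1:3; idx2 <- 4:6
  list(
    Wb1 = do.call(cbind, W1),
    Wb0 = do.call(cbind, W0),
    # within-class blocks for the assortative component
    A1b1 = do.call(cbind, lapply(W1, function(w) w[idx1, idx1])),
    A1b0 = do.call(cbind, lapply(W0, function(w) w[idx1, idx1])),
    A2b1 = do.call(cbind, lapply(W1, function(w) w[idx2, idx2])),
    A2b0 = do.call(cbind, lapply(W0, function(w) w[idx2, idx2])),
    # per-mating offspring phenotype-1 probability and its MZ square
    S = Reduce(`+`, W1),
    S2 = Reduce(`+`, lapply(1:3, function(g) men6[[g]] * t6[[g]]^2)),
    table = table
  )
}

# quadratic forms x' W x for a 6 x 18 (or 3 x 9) stack of three kernels
qf3 <- function(x, Wb) {
  n <- length(x)
  .colSums(matrix(x %*% Wb, n, 3L) * x, n, 3L)
}

# one generation, raw length-6 state in / out (hot path, no validation)
step_raw <- function(x, eng, m) {
  q1 <- qf3(x, eng$Wb1)
  q0 <- qf3(x, eng$Wb0)
  if (m > 0) {
    x1 <- x[1:3]; x2 <- x[4:6]
    k1 <- x1[1L] + x1[2L] + x1[3L]; k2 <- 1 - k1
    a1 <- if (k1 > 0) qf3(x1, eng$A1b1) / k1 else numeric(3L)
    a0 <- if (k1 > 0) qf3(x1, eng$A1b0) / k1 else numeric(3L)
    if (k2 > 0) {
      a1 <- a1 + qf3(x2, eng$A2b1) / k2
      a0 <- a0 + qf3(x2, eng$A2b0) / k2
    }
    q1 <- m * a1 + (1 - m) * q1
    q0 <- m * a0 + (1 - m) * q0
  }
  # the step conserves total mass exactly in exact arithmetic, but it is
  # quadratic in x, so floating-point mass error would double per
  # generation without renormalization
  c(q1, q0 - q1) / sum(q0)
}

check_m <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0 || m > 1)
    stop("assortment rate 'm' must lie in [0, 1]", call. = FALSE)
  m
}

#' Mating distribution under partial phenotypic assortment
#'
#' The distribution over ordered (mother, father) phenogenotype pairs is the
#' mixture `m * A + (1 - m) * R`, where `R` is random pairing (outer product
#' of the adult distribution with itself) and `A` is random pairing within
#' phenotype class.  Phenotype classes with zero frequency contribute no
#' assortative mass.  Both margins equal the adult distribution exactly, and
#' the spousal phenotypic correlation equals `m` whenever `0 < k < 1`.
#'
#' @param dist A `"pg_dist"` of the adult population.
#' @param m Assortment rate in `[0, 1]`.
#' @return A 6 x 6 matrix of class `"mating_distribution"` over ordered
#'   phenogenotype pairs `AA1, Aa1, aa1, AA2, Aa2, aa2` (rows: mother), with
#'   attributes `m` and `dist`.
#' @examples
#' d <- hw_init(p = 0.5, k0 = 0.4)
#' M <- mating_distribution(d, m = 0.5)
#' rowSums(M)  # equals the adult distribution
#' @export
mating_distribution <- function(dist, m) {
  stopifnot(inherits(dist, "pg_dist"))
  check_m(m)
  x <- as_pg_vector(dist)
  M <- (1 - m) * tcrossprod(x)
  if (m > 0) {
    x1 <- x[1:3]; x2 <- x[4:6]
    k1 <- sum(x1); k2 <- sum(x2)
    if (k1 > 0) M[1:3, 1:3] <- M[1:3, 1:3] + m * tcrossprod(x1) / k1
    if (k2 > 0) M[4:6, 4:6] <- M[4:6, 4:6] + m * tcrossprod(x2) / k2
  }
  nm <- paste0(GENOTYPES[PG_GENO], PG_PHEN)
  dimnames(M) <- list(mother = nm, father = nm)
  structure(M, class = "mating_distribution", m = m, dist = dist)
}

#' @export
print.mating_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("Mating distribution (ordered pairs), m = %g:\n", attr(x, "m")))
  m <- unclass(x); attributes(m)[c("m", "dist")] <- NULL
  print(round(m, digits), ...)
  invisible(x)
}

#' Advance the phenogenotype distribution one generation
#'
#' Parents pair according to [mating_distribution()]; each mating produces
#' offspring whose genotype follows Mendelian segregation and whose
#' phenotype is 1 with the transmission-table probability for the parents'
#' phenotype pair and the offspring's own genotype.  Allele frequency is
#' conserved exactly (no selection).
#'
#' @param dist A `"pg_dist"`.
#' @param table A `"transmission_table"`.
#' @param m Assortment rate in `[0, 1]`.
#' @return The offspring `"pg_dist"`.
#' @examples
#' tab <- bilinear_table(alpha = 0.2, beta = 0.2, eta = 0)
#' next_generation(hw_init(0.5, 0.5), tab, m = 0)
#' @export
next_generation <- function(dist, table, m) {
  stopifnot(inherits(dist, "pg_dist"))
  check_m(m)
  eng <- step_engine(table)
  pg_dist(step_raw(as_pg_vector(dist), eng, m))
}

#' Solve for the equilibrium phenogenotype distribution
#'
#' Fixed-point iteration of [next_generation()] until the L-infinity change
#' per generation falls to `tol` or `max_iter` is reached.  Non-convergence
#' is reported in the result, not raised as an error.
#'
#' @param table A `"transmission_table"`.
#' @param m Assortment rate in `[0, 1]`.
#' @param init Starting `"pg_dist"` (e.g. [hw_init()]).
#' @param tol Convergence tolerance on the L-infinity change (default 1e-12).
#' @param max_iter Iteration cap.
#' @param trace_k If `TRUE`, record the trajectory of `(k, p1)` (capped at
#'   the first 10000 generations).
#' @return A list of class `"equilibrium_result"`: `dist` (the equilibrium
#'   `"pg_dist"`), `iterations`, `converged`, `residual`, and optionally
#'   `trajectory` (matrix with columns `k`, `p1`).
#' @examples
#' tab <- bilinear_table(alpha = 0, beta = 0.2, eta = 0.25)
#' eq <- find_equilibrium(tab, m = 0, init = hw_init(0.5, 0.2))
#' pheno_freq(eq$dist)  # beta / (1 - 2 * eta) = 0.4
#' @export
find_equilibrium <- function(table, m, init, tol = 1e-12, max_iter = 1e6,
                             trace_k = FALSE) {
  stopifnot(inherits(init, "pg_dist"))
  check_m(m)
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  eng <- step_engine(table)
  x <- as_pg_vector(init)
  traj <- if (trace_k) vector("list", 0L) else NULL
  trace_cap <- 10000L
  it <- 0L
  residual <- Inf
  repeat {
    x_new <- step_raw(x, eng, m)
    it <- it + 1L
    residual <- max(abs(x_new - x))
    if (trace_k && it <= trace_cap) {
      k <- sum(x_new[1:3])
      p1 <- if (k > 0) (x_new[1L] + x_new[2L] / 2) / k else NA_real_
      traj[[it]] <- c(k = k, p1 = p1)
    }
    x <- x_new
    if (residual <= tol || it >= max_iter) break
  }
  out <- list(dist = pg_dist(x), iterations = it,
              converged = residual <= tol, residual = residual)
  if (trace_k) out$trajectory <- do.call(rbind, traj)
  class(out) <- "equilibrium_result"
  out
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium %s after %d iteration%s (residual %.3g)\n",
              if (x$converged) "reached" else "NOT reached",
              x$iterations, if (x$iterations == 1L) "" else "s", x$residual))
  print(x$dist, ...)
  invisible(x)
}
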
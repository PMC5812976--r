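# Exact enumeration of equilibrium joint phenotype distributions for
# spouse, parent-offspring and twin pairs, and their phi (Pearson)
# correlations.  Twin phenotypes are conditionally independent given own
# genotype and parental phenotypes; MZ twins share a single genotype draw,
# DZ twins (= full sibs) draw genotypes independently.

new_joint2x2 <- function(q, tol = 1e-9) {
  dimnames(q) <- list(member1 = c("1", "2"), member2 = c("1", "2"))
  if (any(q < -tol) || abs(sum(q) - 1) > 1e-8)
    stop("joint distribution must be nonnegative and sum to 1", call. = FALSE)
  q[q < 0] <- 0
  structure(q / sum(q), class = "joint2x2")
}

#' @export
print.joint2x2 <- function(x, digits = 6, ...) {
  cat("Joint phenotype distribution (2 x 2):\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Joint phenotype distribution of mates
#'
#' Aggregates a mating distribution over genotypes, leaving the 2 x 2 joint
#' distribution of the two spouses' phenotypes.  For the partial-assortment
#' mixture this equals `m * k_a * [a == b]` plus `(1 - m)` times the product
#' of the margins.
#'
#' @param M A `"mating_distribution"`.
#' @return A `"joint2x2"`.
#' @export
spouse_joint <- function(M) {
  stopifnot(inherits(M, "mating_distribution"))
  q <- matrix(c(sum(M[1:3, 1:3]), sum(M[4:6, 1:3]),
                sum(M[1:3, 4:6]), sum(M[4:6, 4:6])), 2L, 2L)
  new_joint2x2(q)
}

#' Joint phenotype distribution of a parent and its offspring
#'
#' Enumerates, over the equilibrium mating distribution, the joint
#' probability that the designated parent has phenotype `a` and the
#' offspring acquires phenotype `b`.  At equilibrium both margins equal
#' `(k, 1 - k)`.
#'
#' @param eq An equilibrium `"pg_dist"`.
#' @param table A `"transmission_table"`.
#' @param m Assortment rate.
#' @param role `"mother"` or `"father"` — which parent's phenotype is
#'   member 1.  The bilinear table is parentally symmetric, so the two roles
#'   coincide there; a general table may distinguish them.
#' @return A `"joint2x2"` (member 1 = parent, member 2 = offspring).
#' @export
parent_offspring_joint <- function(eq, table, m,
                                   role = c("mother", "father")) {
  role <- match.arg(role)
  M <- mating_distribution(eq, m)
  S <- step_engine(table)$S
  MS <- unclass(M) * S
  if (role == "mother") {
    p11 <- sum(MS[1:3, ]); p21 <- sum(MS[4:6, ])
    k1 <- sum(unclass(M)[1:3, ])
  } else {
    p11 <- sum(MS[, 1:3]); p21 <- sum(MS[, 4:6])
    k1 <- sum(unclass(M)[, 1:3])
  }
  q <- matrix(c(p11, p21, k1 - p11, 1 - k1 - p21), 2L, 2L)
  new_joint2x2(q)
}

#' Joint phenotype distribution of a twin pair
#'
#' For each mating, a DZ pair draws two genotypes independently by Mendelian
#' segregation and each twin's phenotype independently given its own
#' genotype and the parental phenotypes; an MZ pair shares a single genotype
#' draw but still realizes the two phenotypes independently.  The joints are
#' aggregated over the equilibrium mating distribution, so the MZ-DZ
#' difference is purely genetic in origin.
#'
#' @inheritParams parent_offspring_joint
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A `"joint2x2"`.
#' @export
twin_joint <- function(eq, table, m, zygosity = c("DZ", "MZ")) {
  zygosity <- match.arg(zygosity)
  M <- unclass(mating_distribution(eq, m))
  eng <- step_engine(table)
  S <- eng$S
  both1 <- if (zygosity == "DZ") sum(M * S * S) else sum(M * eng$S2)
  k <- sum(M * S)  # each twin's marginal phenotype-1 probability
  q <- matrix(c(both1, k - both1, k - both1, 1 - 2 * k + both1), 2L, 2L)
  new_joint2x2(q)
}

#' Phi correlation of a 2 x 2 joint distribution
#'
#' Pearson correlation of the two members' phenotype-1 indicators,
#' `(q11 - k1 * k2) / sqrt(k1 (1 - k1) k2 (1 - k2))`.  Undefined (error)
#' when either margin is degenerate.
#'
#' @param q A `"joint2x2"` or plain 2 x 2 matrix of probabilities.
#' @return A correlation in `[-1, 1]`.
#' @examples
#' phi_correlation(matrix(c(0.28, 0.12, 0.12, 0.48), 2, 2))  # 0.5
#' @export
phi_correlation <- function(q) {
  if (!inherits(q, "joint2x2")) q <- new_joint2x2(as.matrix(q))
  k1 <- sum(q[1L, ]); k2 <- sum(q[, 1L])
  v1 <- k1 * (1 - k1); v2 <- k2 * (1 - k2)
  if (v1 <= 0 || v2 <= 0)
    stop("phi correlation undefined: a phenotype margin is degenerate",
         call. = FALSE)
  unname((q[1L, 1L] - k1 * k2) / sqrt(v1 * v2))
}

#' Equilibrium kin correlations
#'
#' Phi correlations of the phenotype indicators for spouses,
#' parent-offspring (each role and their mean), DZ twins and MZ twins,
#' computed by exact enumeration at equilibrium.
#'
#' @inheritParams parent_offspring_joint
#' @return A list of class `"kin_correlations"` with elements `r_spouse`,
#'   `r_po_mother`, `r_po_father`, `r_po`, `r_dz`, `r_mz`.
#' @examples
#' tab <- bilinear_table(alpha = 0.2, beta = 0.2, eta = 0)
#' eq <- find_equilibrium(tab, m = 0, init = hw_init(0.5, 0.2))$dist
#' kin_correlations(eq, tab, m = 0)
#' @export
kin_correlations <- function(eq, table, m) {
  k <- pheno_freq(eq)
  if (k <= 0 || k >= 1)
    stop("kin correlations undefined: phenotype distribution is degenerate",
         call. = FALSE)
  M <- mating_distribution(eq, m)
  r_pm <- phi_correlation(parent_offspring_joint(eq, table, m, "mother"))
  r_pf <- phi_correlation(parent_offspring_joint(eq, table, m, "father"))
  structure(list(
    r_spouse = phi_correlation(spouse_joint(M)),
    r_po_mother = r_pm,
    r_po_father = r_pf,
    r_po = (r_pm + r_pf) / 2,
    r_dz = phi_correlation(twin_joint(eq, table, m, "DZ")),
    r_mz = phi_correlation(twin_joint(eq, table, m, "MZ"))
  ), class = "kin_correlations")
}

#' @export
print.kin_correlations <- function(x, digits = 6, ...) {
  cat("Equilibrium kin correlations (phenotype indicators):\n")
  v <- unlist(x)
  print(round(v, digits))
  invisible(x)
}
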
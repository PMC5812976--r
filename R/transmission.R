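# Phenogenotypic transmission tables: the probability that an offspring
# acquires phenotype 1 given its own genotype and the ordered pair of its
# parents' phenotypes.  Twelve rates in the general case; five parameters
# (alpha, beta, eta, sigma, tau) in the bilinear scheme.

#' Bilinear transmission parameters
#'
#' Bundle and validate the five parameters of the bilinear transmission
#' scheme for a dichotomous phenotype determined jointly by a diallelic
#' locus and the phenotypes of the two parents.
#'
#' @param alpha Probability increment contributed per `A` allele
#'   (scaled by `sigma` in the heterozygote).
#' @param beta Baseline probability that any offspring acquires phenotype 1,
#'   regardless of genotype or parental phenotypes.
#' @param eta Cultural increment contributed by each parent of phenotype 1
#'   (scaled by `tau` when only one parent has phenotype 1).
#' @param sigma Genetic dominance coefficient in `[0, 2]`: the heterozygote
#'   receives `sigma * alpha`.  `sigma = 1` is additive, `sigma = 2` complete
#'   dominance of `A`.
#' @param tau Marital dominance coefficient in `[0, 2]`: a single phenotype-1
#'   parent contributes `tau * eta`.  `tau = 2` makes one such parent as
#'   effective as two.
#' @return A list of class `"bilinear_params"`.
#' @examples
#' bilinear_params(alpha = 0.2, beta = 0.1, eta = 0.2)
#' @export
bilinear_params <- function(alpha, beta, eta, sigma = 1, tau = 1) {
  for (nm in c("alpha", "beta", "eta", "sigma", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (sigma < 0 || sigma > 2)
    stop(sprintf("'sigma' must lie in [0, 2], got %g", sigma), call. = FALSE)
  if (tau < 0 || tau > 2)
    stop(sprintf("'tau' must lie in [0, 2], got %g", tau), call. = FALSE)
  structure(list(alpha = alpha, beta = beta, eta = eta,
                 sigma = sigma, tau = tau),
            class = "bilinear_params")
}

#' @export
print.bilinear_params <- function(x, ...) {
  cat("Bilinear transmission parameters:\n")
  cat(sprintf("  alpha = %g  beta = %g  eta = %g  sigma = %g  tau = %g\n",
              x$alpha, x$beta, x$eta, x$sigma, x$tau))
  invisible(x)
}

# validate a 4x3 matrix of acquisition probabilities; rows are ordered
# parental phenotype pairs, columns offspring genotypes
validate_table_entries <- function(entries) {
  bad <- which(entries < 0 | entries > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "transmission probability out of [0, 1]: entry[(%s), %s] = %g",
      sub("x", ",", rownames(entries)[i]), colnames(entries)[j],
      entries[i, j]), call. = FALSE)
  }
  invisible(entries)
}

new_transmission_table <- function(entries, params = NULL) {
  dimnames(entries) <- list(PAIR_LABELS, GENOTYPES)
  validate_table_entries(entries)
  structure(entries, class = "transmission_table", params = params)
}

#' Build a bilinear transmission table
#'
#' Expand the five bilinear parameters into the full table of twelve
#' acquisition probabilities.  The genetic increments by genotype are
#' `2 * alpha` (AA), `sigma * alpha` (Aa) and `0` (aa); the cultural
#' increment is `2 * eta` when both parents have phenotype 1, `tau * eta`
#' when exactly one does, and `0` otherwise; `beta` is added throughout.
#'
#' All twelve implied entries must lie in `[0, 1]` (in particular
#' `2 * eta + 2 * alpha + beta <= 1`); the first offending cell is named in
#' the error otherwise.
#'
#' @param params A [bilinear_params()] object, or `alpha` given directly as
#'   a number together with the remaining parameters.
#' @inheritParams bilinear_params
#' @return A 4 x 3 matrix of class `"transmission_table"`: rows are ordered
#'   parental phenotype pairs `(1,1), (1,2), (2,1), (2,2)` (mother x father),
#'   columns offspring genotypes `AA, Aa, aa`.  Each entry is the probability
#'   the offspring acquires phenotype 1; phenotype 2 has the complementary
#'   probability.
#' @examples
#' bilinear_table(alpha = 0.2, beta = 0.1, eta = 0.2)
#' @export
bilinear_table <- function(params = NULL, beta, eta, sigma = 1, tau = 1,
                           alpha = NULL) {
  if (!inherits(params, "bilinear_params")) {
    if (is.numeric(params) && is.null(alpha)) alpha <- params
    params <- bilinear_params(alpha, beta, eta, sigma, tau)
  }
  gen <- c(2 * params$alpha, params$sigma * params$alpha, 0)
  cult <- c(2 * params$eta, params$tau * params$eta,
            params$tau * params$eta, 0)
  entries <- outer(cult, gen, `+`) + params$beta
  new_transmission_table(entries, params = params)
}

#' General transmission table from twelve rates
#'
#' Store an arbitrary table of twelve acquisition probabilities.  Unlike the
#' bilinear scheme, the `(1,2)` and `(2,1)` rows may differ, allowing
#' asymmetric maternal and paternal cultural roles.
#'
#' @param rates A 4 x 3 matrix (rows: parental pairs `(1,1), (1,2), (2,1),
#'   (2,2)`; columns: genotypes `AA, Aa, aa`) or a length-12 vector filled
#'   row-pair by row-pair in that order.
#' @return A `"transmission_table"` object.
#' @examples
#' general_table(matrix(0.5, 4, 3))
#' @export
general_table <- function(rates) {
  if (is.matrix(rates)) {
    if (!all(dim(rates) == c(4L, 3L)))
      stop("'rates' matrix must be 4 x 3 (parental pairs x genotypes)",
           call. = FALSE)
    entries <- rates
  } else {
    if (length(rates) != 12L)
      stop("'rates' must supply exactly 12 probabilities", call. = FALSE)
    entries <- matrix(rates, nrow = 4L, ncol = 3L, byrow = TRUE)
  }
  new_transmission_table(entries)
}

#' Look up a transmission probability
#'
#' @param table A `"transmission_table"`.
#' @param phi_m,phi_f Phenotypes (1 or 2) of mother and father.
#' @param genotype Offspring genotype: `"AA"`, `"Aa"` or `"aa"`.
#' @return The probability that the offspring acquires phenotype 1; the
#'   probability of phenotype 2 is its complement.
#' @examples
#' tab <- bilinear_table(alpha = 0.2, beta = 0.1, eta = 0.2)
#' transmission_prob(tab, 1, 1, "Aa")
#' @export
transmission_prob <- function(table, phi_m, phi_f, genotype) {
  stopifnot(inherits(table, "transmission_table"))
  unname(table[pair_row(phi_m, phi_f), genotype_index(genotype)])
}

#' @export
print.transmission_table <- function(x, ...) {
  cat("Phenogenotypic transmission table (P[offspring phenotype = 1]):\n")
  m <- unclass(x)
  attr(m, "params") <- NULL
  rownames(m) <- sub("x", " x ", rownames(m))
  print(m, ...)
  p <- attr(x, "params")
  if (!is.null(p))
    cat(sprintf("Bilinear: alpha = %g, beta = %g, eta = %g, sigma = %g, tau = %g\n",
                p$alpha, p$beta, p$eta, p$sigma, p$tau))
  invisible(x)
}

#' Read or write bilinear parameters as YAML or JSON
#'
#' The on-disk record uses keys `alpha`, `beta`, `eta`, `sigma`, `tau`;
#' the format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_params()` returns a [bilinear_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  rec <- read_config(path)
  need <- c("alpha", "beta", "eta")
  if (!all(need %in% names(rec)))
    stop("parameter record must contain keys alpha, beta, eta", call. = FALSE)
  bilinear_params(rec$alpha, rec$beta, rec$eta,
                  sigma = if (is.null(rec$sigma)) 1 else rec$sigma,
                  tau = if (is.null(rec$tau)) 1 else rec$tau)
}

#' @rdname read_params
#' @param params A [bilinear_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "bilinear_params"))
  rec <- unclass(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(rec, path)
  } else if (ext == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported extension: use .yaml, .yml or .json", call. = FALSE)
  invisible(path)
}
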
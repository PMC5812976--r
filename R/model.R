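# The end-to-end pipeline as a classed model object: build the transmission
# table, iterate to the equilibrium phenogenotype distribution, enumerate
# kin correlations, and decompose the variance.

#' Fit the gene-culture transmission model
#'
#' Runs the full pipeline for one parameter set: builds the bilinear
#' transmission table (or accepts a general one), iterates the
#' six-phenogenotype recursion under partial phenotypic assortment to its
#' equilibrium, enumerates the exact spouse, parent-offspring and twin joint
#' phenotype distributions, and computes the additive genetic variance, the
#' actual narrow-sense heritability `h2_A`, and the twin-based Falconer
#' estimates `h2_F = 2 (r_MZ - r_DZ)` and `c2_F = 2 r_DZ - r_MZ`.
#'
#' @param alpha,beta,eta,sigma,tau Bilinear transmission parameters (see
#'   [bilinear_params()]).  Ignored if `table` is supplied.
#' @param m Assortment rate in `[0, 1]`; the equilibrium spousal phenotype
#'   correlation equals `m`.
#' @param p Frequency of allele `A` (conserved by the dynamics).
#' @param table Optionally a ready-made `"transmission_table"` (general
#'   tables allowed) instead of the bilinear parameters.
#' @param init Starting `"pg_dist"`; default is Hardy-Weinberg at `p` with
#'   phenotype 1 assigned independently at the table's baseline rate (the
#'   `(2,2) x aa` entry, `beta` for a bilinear table).
#' @param tol,max_iter Solver settings passed to [find_equilibrium()].
#' @param trace_k Record the `(k, p1)` trajectory for [plot.gc_model()].
#' @return An object of class `"gc_model"`: a list with the parameters,
#'   `table`, `equilibrium` (an `"equilibrium_result"`), `kin`
#'   (a `"kin_correlations"`), and the variance summary (`k`, `V_P`, `V_A`,
#'   `h2_A`, `h2_F`, `c2_F`).  Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate`.
#' @examples
#' fit <- gc_model(alpha = 0.2, beta = 0.2, eta = 0, m = 0, p = 0.5)
#' summary(fit)
#' @export
gc_model <- function(alpha = NULL, beta = NULL, eta = NULL,
                     sigma = 1, tau = 1, m = 0, p = 0.5,
                     table = NULL, init = NULL,
                     tol = 1e-12, max_iter = 1e6, trace_k = TRUE) {
  check_m(m)
  if (is.null(table)) {
    if (is.null(alpha) || is.null(beta) || is.null(eta))
      stop("supply either alpha/beta/eta (+ sigma, tau) or a 'table'",
           call. = FALSE)
    table <- bilinear_table(bilinear_params(alpha, beta, eta, sigma, tau))
  } else if (!inherits(table, "transmission_table")) {
    stop("'table' must be a transmission_table", call. = FALSE)
  }
  if (is.null(init)) init <- hw_init(p, k0 = unname(table["2x2", "aa"]))
  eqr <- find_equilibrium(table, m, init, tol = tol, max_iter = max_iter,
                          trace_k = trace_k)
  if (!eqr$converged)
    warning(sprintf(
      "equilibrium not reached in %d iterations (residual %.3g)",
      eqr$iterations, eqr$residual), call. = FALSE)
  eq <- eqr$dist
  k <- pheno_freq(eq)
  interior <- k > 0 && k < 1
  kin <- if (interior) kin_correlations(eq, table, m) else NULL
  V_P <- k * (1 - k)
  V_A <- if (interior) additive_variance(eq) else 0
  h2_A <- if (interior) V_A / V_P else NA_real_
  fal <- if (interior) falconer_estimates(kin$r_mz, kin$r_dz)
         else c(h2_F = NA_real_, c2_F = NA_real_)
  pars <- attr(table, "params")
  structure(list(
    params = pars, table = table, m = m, p = allele_freq(eq),
    init = init, equilibrium = eqr, kin = kin,
    k = k, V_P = V_P, V_A = V_A, h2_A = h2_A,
    h2_F = unname(fal["h2_F"]), c2_F = unname(fal["c2_F"]),
    call = match.call()
  ), class = "gc_model")
}

#' @export
print.gc_model <- function(x, digits = 4, ...) {
  cat("Gene-culture transmission model\n")
  if (!is.null(x$params))
    cat(sprintf("  alpha = %g, beta = %g, eta = %g, sigma = %g, tau = %g\n",
                x$params$alpha, x$params$beta, x$params$eta,
                x$params$sigma, x$params$tau))
  else cat("  (general 12-rate transmission table)\n")
  cat(sprintf("  m = %g, p = %g\n", x$m, x$p))
  eqr <- x$equilibrium
  cat(sprintf("Equilibrium%s: k = %s  (%d iterations)\n",
              if (eqr$converged) "" else " [NOT CONVERGED]",
              format(x$k, digits = digits), eqr$iterations))
  if (!is.null(x$kin))
    cat(sprintf("h2_A = %s, h2_F = %s, c2_F = %s\n",
                format(x$h2_A, digits = digits),
                format(x$h2_F, digits = digits),
                format(x$c2_F, digits = digits)))
  invisible(x)
}

#' @export
coef.gc_model <- function(object, ...) {
  p <- object$params
  if (is.null(p)) return(c(m = object$m, p = object$p))
  c(alpha = p$alpha, beta = p$beta, eta = p$eta, sigma = p$sigma,
    tau = p$tau, m = object$m, p = object$p)
}

#' Summarize a fitted gene-culture model
#'
#' @param object A `"gc_model"`.
#' @param ... Unused.
#' @return The object, invisibly, after printing the full heritability
#'   report (equilibrium state, kin correlations, variance components and
#'   both heritability estimates).
#' @export
summary.gc_model <- function(object, ...) {
  rep <- heritability_report(object)
  structure(list(report = rep, model = object), class = "summary.gc_model")
}

#' @export
print.summary.gc_model <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Predict offspring phenotype-1 probability
#'
#' Looks up the transmission probability for each row of `newdata`.
#'
#' @param object A `"gc_model"`.
#' @param newdata Data frame with columns `phi_m`, `phi_f` (1 or 2) and
#'   `genotype` (`"AA"`, `"Aa"`, `"aa"`).
#' @param ... Unused.
#' @return Numeric vector of probabilities of acquiring phenotype 1.
#' @export
predict.gc_model <- function(object, newdata, ...) {
  stopifnot(all(c("phi_m", "phi_f", "genotype") %in% names(newdata)))
  object$table[cbind(pair_row(newdata$phi_m, newdata$phi_f),
                     genotype_index(as.character(newdata$genotype)))]
}

#' Plot the approach to equilibrium
#'
#' Trajectory of the reduced coordinates: frequency `k` of phenotype 1 and
#' frequency `p1` of allele `A` among phenotype-1 individuals, by
#' generation.  Requires the model to have been fitted with
#' `trace_k = TRUE` (the default).
#'
#' @param x A `"gc_model"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gc_model <- function(x, ...) {
  traj <- x$equilibrium$trajectory
  if (is.null(traj))
    stop("no trajectory recorded; refit with trace_k = TRUE", call. = FALSE)
  graphics::matplot(seq_len(nrow(traj)), traj, type = "l", lty = 1:2,
                    col = c("black", "grey40"), xlab = "generation",
                    ylab = "frequency", ylim = c(0, 1), ...)
  graphics::legend("topright", legend = c("k (phenotype 1)",
                                          "p1 (A | phenotype 1)"),
                   lty = 1:2, col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' Heritability report for one parameter set
#'
#' End-to-end pipeline returning a flat report: equilibrium frequency,
#' kin correlations, variance components, the actual narrow-sense
#' heritability and the twin-based Falconer estimates, plus convergence
#' metadata and a parameter echo.  Accepts either a fitted `"gc_model"` or
#' the raw parameters (forwarded to [gc_model()]).
#'
#' @param object A `"gc_model"`, or the first bilinear parameter `alpha`.
#' @param ... Parameters forwarded to [gc_model()] when `object` is not a
#'   fitted model.
#' @return A list of class `"heritability_report"` with fields `alpha`,
#'   `beta`, `eta`, `sigma`, `tau`, `m`, `p`, `k_eq`, `p1_eq`, `r_spouse`,
#'   `r_po`, `r_dz`, `r_mz`, `V_P`, `V_A`, `h2_A`, `h2_F`, `c2_F`,
#'   `converged`, `iterations`, `residual`.
#' @examples
#' heritability_report(alpha = 0, beta = 0.1, eta = 0.4, m = 0.5, p = 0.5)
#' @export
heritability_report <- function(object = NULL, ...) {
  fit <- if (inherits(object, "gc_model")) object
         else if (is.null(object)) gc_model(...)
         else gc_model(alpha = object, ...)
  pars <- fit$params
  rc <- if (fit$k > 0) reduced_coordinates(fit$equilibrium$dist)
        else c(k = 0, p1 = NA_real_)
  structure(list(
    alpha = if (is.null(pars)) NA_real_ else pars$alpha,
    beta = if (is.null(pars)) NA_real_ else pars$beta,
    eta = if (is.null(pars)) NA_real_ else pars$eta,
    sigma = if (is.null(pars)) NA_real_ else pars$sigma,
    tau = if (is.null(pars)) NA_real_ else pars$tau,
    m = fit$m, p = fit$p,
    k_eq = fit$k, p1_eq = unname(rc["p1"]),
    r_spouse = if (is.null(fit$kin)) NA_real_ else fit$kin$r_spouse,
    r_po = if (is.null(fit$kin)) NA_real_ else fit$kin$r_po,
    r_dz = if (is.null(fit$kin)) NA_real_ else fit$kin$r_dz,
    r_mz = if (is.null(fit$kin)) NA_real_ else fit$kin$r_mz,
    V_P = fit$V_P, V_A = fit$V_A,
    h2_A = fit$h2_A, h2_F = fit$h2_F, c2_F = fit$c2_F,
    converged = fit$equilibrium$converged,
    iterations = fit$equilibrium$iterations,
    residual = fit$equilibrium$residual
  ), class = "heritability_report")
}

#' @export
print.heritability_report <- function(x, digits = 6, ...) {
  cat("Heritability report (equilibrium of the gene-culture model)\n")
  cat(sprintf("  parameters: alpha = %g, beta = %g, eta = %g, sigma = %g, tau = %g, m = %g, p = %g\n",
              x$alpha, x$beta, x$eta, x$sigma, x$tau, x$m, x$p))
  cat(sprintf("  equilibrium: k = %s  (converged = %s, %d iterations)\n",
              format(x$k_eq, digits = digits), x$converged, x$iterations))
  cat(sprintf("  correlations: spouse = %s, parent-offspring = %s, DZ = %s, MZ = %s\n",
              format(x$r_spouse, digits = digits),
              format(x$r_po, digits = digits),
              format(x$r_dz, digits = digits),
              format(x$r_mz, digits = digits)))
  cat(sprintf("  variance: V_P = %s, V_A = %s\n",
              format(x$V_P, digits = digits), format(x$V_A, digits = digits)))
  cat(sprintf("  heritability: h2_A (actual) = %s; twin-based h2_F = %s, c2_F = %s\n",
              format(x$h2_A, digits = digits),
              format(x$h2_F, digits = digits),
              format(x$c2_F, digits = digits)))
  invisible(x)
}

#' @export
as.data.frame.heritability_report <- function(x, ...) {
  as.data.frame(unclass(x)[c("alpha", "beta", "eta", "sigma", "tau", "m",
                             "p", "k_eq", "r_spouse", "r_po", "r_dz",
                             "r_mz", "V_A", "h2_A", "h2_F", "c2_F",
                             "converged", "iterations")],
                stringsAsFactors = FALSE)
}
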
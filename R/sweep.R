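# Parameter sweeps over the Cartesian grid of bilinear parameters, and
# config-file handling for the command-line driver.

#' Read a configuration file
#'
#' YAML or JSON, chosen by extension.  Recognized keys: `alpha`, `beta`,
#' `eta`, `sigma`, `tau`, `m`, `p`, `tol`, `max_iter`, `init` (optional
#' explicit six frequencies), `seed`, `N`, `generations`.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config extension: use .yaml, .yml or .json",
            call. = FALSE)
}

#' Sweep the bilinear parameter grid
#'
#' Runs [heritability_report()] on every combination of the supplied
#' parameter values (Cartesian product).  Combinations whose implied
#' transmission table is invalid, or whose equilibrium is phenotypically
#' degenerate, are reported in the `note` column and retain `NA` results
#' rather than being dropped.
#'
#' @param alpha,beta,eta,sigma,tau,m,p Vectors of parameter values.
#' @param tol,max_iter Solver settings applied to every combination.
#' @return A data.frame with one row per combination: the parameter echo,
#'   `k_eq`, `r_spouse`, `r_po`, `r_dz`, `r_mz`, `V_A`, `h2_A`, `h2_F`,
#'   `c2_F`, `converged`, `iterations`, `note`.
#' @examples
#' run_sweep(alpha = c(0, 0.2), beta = 0.1, eta = 0.2, m = 0.5, p = 0.5)
#' @export
run_sweep <- function(alpha, beta, eta, sigma = 1, tau = 1, m = 0.5,
                      p = 0.5, tol = 1e-12, max_iter = 1e6) {
  grid <- expand.grid(alpha = alpha, beta = beta, eta = eta, sigma = sigma,
                      tau = tau, m = m, p = p, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- tryCatch({
      rep <- suppressWarnings(heritability_report(
        alpha = g$alpha, beta = g$beta, eta = g$eta, sigma = g$sigma,
        tau = g$tau, m = g$m, p = g$p, tol = tol, max_iter = max_iter))
      df <- as.data.frame(rep)
      df$note <- ""
      df
    }, error = function(e) {
      df <- cbind(g, k_eq = NA_real_, r_spouse = NA_real_, r_po = NA_real_,
                  r_dz = NA_real_, r_mz = NA_real_, V_A = NA_real_,
                  h2_A = NA_real_, h2_F = NA_real_, c2_F = NA_real_,
                  converged = NA, iterations = NA_integer_)
      df$note <- conditionMessage(e)
      df
    })
    out
  })
  do.call(rbind, rows)
}

#' Internal-consistency validation suite
#'
#' Checks, for one parameter set: conservation of the simplex and of allele
#' frequency along the recursion; the closed-form limits (`k* = beta /
#' (1 - 2 eta)` when `alpha = 0`, `tau = 1`, `m = 0`; `h2_F = h2_A` and
#' `c2_F = 0` when `eta = 0`, `m = 0`, `sigma = 1`); the spousal
#' correlation equalling `m`; the Falconer identity `h2_F + c2_F = r_MZ`;
#' and agreement of the finite-population simulator with the deterministic
#' equilibrium within `3` Monte-Carlo standard errors.
#'
#' @param alpha,beta,eta,sigma,tau,m,p Parameter set to validate.
#' @param seed Seed for the Monte-Carlo checks.
#' @param N,generations Simulator size used in the agreement checks.
#' @param n_pairs Twin pairs per zygosity for the correlation checks.
#' @return A data.frame of class `"gc_validation"` with columns `check`,
#'   `observed`, `expected`, `tolerance`, `pass`.
#' @export
run_validate <- function(alpha = 0.2, beta = 0.1, eta = 0.2, sigma = 1,
                         tau = 1, m = 0.5, p = 0.5, seed = 1, N = 20000,
                         generations = 15, n_pairs = 20000) {
  fit <- gc_model(alpha = alpha, beta = beta, eta = eta, sigma = sigma,
                  tau = tau, m = m, p = p)
  eq <- fit$equilibrium$dist
  checks <- list()
  add <- function(check, observed, expected, tolerance)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, observed = observed, expected = expected,
      tolerance = tolerance, pass = abs(observed - expected) <= tolerance)

  add("simplex sum at equilibrium", sum(eq), 1, 1e-9)
  add("allele frequency conserved", allele_freq(eq), p, 1e-9)
  stepped <- next_generation(eq, fit$table, m)
  add("equilibrium is a fixed point",
      max(abs(unclass(stepped) - unclass(eq))), 0, 1e-9)
  add("spousal correlation equals m", fit$kin$r_spouse, m, 1e-9)
  add("Falconer identity h2_F + c2_F = r_MZ",
      fit$h2_F + fit$c2_F, fit$kin$r_mz, 1e-12)
  if (alpha == 0)
    add("alpha = 0 implies h2_A = 0", fit$h2_A, 0, 1e-9)
  if (alpha == 0 && tau == 1 && m == 0)
    add("k* = beta / (1 - 2 eta)", fit$k, beta / (1 - 2 * eta), 1e-9)
  if (eta == 0 && m == 0 && sigma == 1) {
    add("h2_F = h2_A (additive, random mating)", fit$h2_F, fit$h2_A, 1e-9)
    add("c2_F = 0 (additive, random mating)", fit$c2_F, 0, 1e-9)
  }

  pop <- simulate_population(fit$table, m, p0 = p, N = N,
                             generations = generations, seed = seed)
  k_hat <- mean(pop$phenotype == 1L)
  # genetic drift moves the finite population's allele frequency (a
  # martingale), which shifts its equilibrium k; condition on the realized
  # allele frequency so the check isolates sampling error
  p_hat <- mean(3L - pop$genotype) / 2
  k_cond <- pheno_freq(find_equilibrium(
    fit$table, m, hw_init(p_hat, k_hat))$dist)
  add("Monte-Carlo k within 3 SE (at realized allele frequency)",
      k_hat, k_cond, 3 * sqrt(k_cond * (1 - k_cond) / N))
  sp <- estimate_correlation(data.frame(twin1 = pop$matings$phi_m,
                                        twin2 = pop$matings$phi_f))
  add("Monte-Carlo spouse correlation within 3 SE", sp$r,
      fit$kin$r_spouse, 3 * sp$se)
  for (zy in c("DZ", "MZ")) {
    tw <- sample_twin_pairs(pop, zy, n_pairs, seed = seed + 1L)
    est <- estimate_correlation(tw)
    add(sprintf("Monte-Carlo %s correlation within 3 SE", zy), est$r,
        if (zy == "DZ") fit$kin$r_dz else fit$kin$r_mz, 3 * est$se)
  }
  out <- do.call(rbind, checks)
  class(out) <- c("gc_validation", "data.frame")
  out
}

#' @export
print.gc_validation <- function(x, ...) {
  cat(sprintf("Validation suite: %d/%d checks passed\n",
              sum(x$pass), nrow(x)))
  df <- as.data.frame(x)
  df$observed <- signif(df$observed, 6)
  df$expected <- signif(df$expected, 6)
  df$tolerance <- signif(df$tolerance, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
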
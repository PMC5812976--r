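test_that("gc_model returns a complete classed fit with working methods", {
  fit <- gc_model(alpha = 0.2, beta = 0.1, eta = 0.2, m = 0.5, p = 0.5)
  expect_s3_class(fit, "gc_model")
  expect_true(fit$equilibrium$converged)
  expect_equal(coef(fit),
               c(alpha = 0.2, beta = 0.1, eta = 0.2, sigma = 1, tau = 1,
                 m = 0.5, p = 0.5))
  expect_output(print(fit), "h2_A")
  expect_output(print(summary(fit)), "Heritability report")

  nd <- data.frame(phi_m = c(1, 2), phi_f = c(1, 2),
                   genotype = c("Aa", "aa"))
  expect_equal(predict(fit, nd), c(0.7, 0.1))

  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()

  # general tables work through the same interface
  gfit <- gc_model(table = general_table(matrix(0.4, 4, 3)), m = 0.2, p = 0.3)
  expect_equal(gfit$k, 0.4, tolerance = 1e-12)
  expect_null(gfit$params)
})

test_that("heritability report fields are internally consistent", {
  rep <- heritability_report(alpha = 0.2, beta = 0.1, eta = 0.2, sigma = 2,
                             tau = 2, m = 0.5, p = 0.5)
  expect_equal(rep$V_P, rep$k_eq * (1 - rep$k_eq))
  expect_equal(rep$h2_A, rep$V_A / rep$V_P)
  expect_equal(rep$h2_F + rep$c2_F, rep$r_mz, tolerance = 1e-12)
  expect_equal(rep$r_spouse, 0.5, tolerance = 1e-9)
  expect_true(rep$converged)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 1L)
})

test_that("sweep covers the grid, flags invalid cells, matches single runs", {
  sw <- run_sweep(alpha = c(0.4, 0.2, 0), beta = 0.1, eta = c(0, 0.2, 0.4),
                  m = 0.5, p = 0.5)
  expect_equal(nrow(sw), 9L)
  # infeasible cells (e.g. alpha = 0.4, eta = 0.4) are reported, not dropped
  bad <- sw$note != ""
  expect_true(any(bad))
  expect_true(all(is.na(sw$k_eq[bad])))
  ok <- sw[!bad, ]
  expect_true(all(abs(ok$r_spouse - 0.5) < 1e-9))
  zero_alpha <- ok[ok$alpha == 0, ]
  expect_true(all(abs(zero_alpha$h2_A) < 1e-9))
  expect_true(all(abs(zero_alpha$h2_F) < 1e-9))

  single <- run_sweep(alpha = 0.2, beta = 0.1, eta = 0.2, m = 0.5, p = 0.5)
  rep <- heritability_report(alpha = 0.2, beta = 0.1, eta = 0.2, m = 0.5,
                             p = 0.5)
  expect_equal(single$h2_F, rep$h2_F)
  expect_equal(single$k_eq, rep$k_eq)
  expect_error(run_sweep(alpha = numeric(0), beta = 0.1, eta = 0), "empty")
})

test_that("validation suite passes on a healthy configuration", {
  res <- run_validate(seed = 1, N = 10000, generations = 10,
                      n_pairs = 10000)
  expect_s3_class(res, "gc_validation")
  expect_true(all(res$pass))
})

test_that("config files round-trip and drive the model", {
  cfg <- list(alpha = 0.2, beta = 0.1, eta = 0.2, sigma = 1, tau = 1,
              m = 0.5, p = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  back <- read_config(path)
  expect_equal(back$eta, 0.2)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, ypath)
  expect_equal(read_config(ypath)$m, 0.5)
  expect_error(read_config("nope.yaml"), "no such file")
})

test_that("command-line driver reports, validates and sets exit codes", {
  cli <- system.file("cli", "cultherit.R", package = "cultherit")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")

  out <- withr::local_tempfile(fileext = ".json")
  status <- system2(rscript,
                    c(cli, "report", "--alpha", "0", "--beta", "0.1",
                      "--eta", "0.4", "--m", "0.5", "--out", out),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  rep <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_lt(abs(rep$h2_F), 1e-9)
  expect_lt(abs(rep$h2_A), 1e-9)
  expect_true(rep$converged)

  # invalid table: usage/validation exit code
  status <- system2(rscript,
                    c(cli, "report", "--alpha", "0.4", "--beta", "0.3",
                      "--eta", "0.4"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 1L)
})
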
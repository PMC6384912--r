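# a clearly partial agonist (tau = 1) keeps every parameter identifiable
make_single_curve <- function(log_r = 5.5, log_ka = -5.5, em = 100,
                              basal = 10, add_sd = 3, seed = 1) {
  grid <- expand.grid(replicate = 1:3, conc = 10^seq(-10, -4),
                      stringsAsFactors = FALSE)
  sys <- system_params(em, basal, 1)
  f <- operational_response(grid$conc, sys, log_ka, log_r)
  y <- withr::with_seed(seed, f + rnorm(nrow(grid), 0, add_sd))
  bias_dataset(data.frame(ligand = "L", pathway = "p", conc = grid$conc,
                          replicate = grid$replicate, response = y))
}

test_that("objective value matches the heteroscedastic Gaussian form", {
  ds <- suppressWarnings(  # deliberately minimal: a single observation
    bias_dataset(data.frame(ligand = "L", pathway = "p", conc = 1e-30,
                            replicate = 1, response = 12)))
  spec <- model_spec("marginal", "p", "L", error = "fixed",
                     error_values = list(add = 2, prop = 0))
  # f ~ basal at this concentration; y - f = 2, v = 4
  theta <- c("em[p]" = 100, "basal[p]" = 10, "logka[L,p]" = -5,
             "logr[L,p]" = 6)
  expect_equal(neg2_loglik(ds, spec, theta), 4 / 4 + log(4), tolerance = 1e-9)

  # perfect fit with unit variance: objective is exactly 0
  ds2 <- make_single_curve(add_sd = 0, seed = 1)
  spec2 <- model_spec("marginal", "p", "L", error = "fixed",
                      error_values = list(add = 1, prop = 0))
  th2 <- c("em[p]" = 100, "basal[p]" = 10, "logka[L,p]" = -5.5,
           "logr[L,p]" = 5.5)
  expect_equal(neg2_loglik(ds2, spec2, th2), 0, tolerance = 1e-18)

  # doubling residuals with fixed variance quadruples the quadratic term
  ds3 <- ds
  ds3$response <- 14  # residual 4 instead of 2
  expect_equal(neg2_loglik(ds3, spec, theta) - log(4),
               4 * (neg2_loglik(ds, spec, theta) - log(4)), tolerance = 1e-9)

  expect_error(
    neg2_loglik(ds, model_spec("marginal", "p", "L", error = "fixed",
                               error_values = list(add = 0, prop = 0)),
                theta),
    "degenerate|> 0")
})

test_that("noise-free data: intact fit recovers generating values to 1e-4", {
  design <- simulation_design(add_sd = c(0, 0), prop_sd = c(0, 0))
  ds <- simulate_dataset(design, dd_logr = 0.3)
  spec <- model_spec("intact", c("1", "2"), c("REF", "TEST"),
                     reference = "REF", error = "fixed",
                     error_values = list(add = 1e-3, prop = 0))
  fit <- fit_operational(ds, spec, fit_options(multistart = 3, seed = 9))
  est <- fit$estimates
  expect_equal(unname(est["ddlogr[TEST]"]), 0.3, tolerance = 1e-4)
  expect_equal(unname(est["logr[REF,1]"]), 7, tolerance = 1e-4)
  expect_equal(unname(est["logr[REF,2]"]), 7, tolerance = 1e-4)
  expect_equal(unname(est["logr[TEST,1]"]), 6.3, tolerance = 1e-4)
  expect_equal(unname(est["logkap[REF]"]), -5, tolerance = 1e-3)
  expect_equal(unname(est["logkap[TEST]"]), -6, tolerance = 1e-3)
  expect_equal(unname(est["em[1]"]), 100, tolerance = 1e-3)
  expect_equal(unname(est["basal[2]"]), 10, tolerance = 1e-3)
})

test_that("fit agrees with an independent least-squares oracle", {
  # additive-only error with fixed SD: the ML mean parameters equal the OLS
  # minimiser.  The dissociation constant is fixed at 0 on both routes (the
  # single-curve full-agonist convention), which keeps the three remaining
  # parameters sharply identified.  Oracle: coarse grid search + BFGS
  # polish, fully independent of the package optimiser and initialisation.
  grid0 <- expand.grid(replicate = 1:3, conc = 10^seq(-10, -4),
                       stringsAsFactors = FALSE)
  sys <- system_params(100, 10, 1)
  f0 <- operational_response(grid0$conc, sys, log_ka = 0, log_r = 6.5)
  y <- withr::with_seed(7, f0 + rnorm(nrow(grid0), 0, 2))
  ds <- bias_dataset(data.frame(ligand = "L", pathway = "p",
                                conc = grid0$conc,
                                replicate = grid0$replicate, response = y))
  spec <- model_spec("marginal", "p", "L", error = "fixed",
                     error_values = list(add = 2, prop = 0),
                     fix = list("logka[L,p]" = 0))
  fit <- fit_operational(ds, spec, fit_options(multistart = 6, seed = 3))

  sse_fun <- function(p) {
    f <- p[2] + (p[1] - p[2]) /
      (1 + (ds$conc / 1 + 1) / (10^p[3] * ds$conc))
    sum((ds$response - f)^2)
  }
  grid <- expand.grid(em = c(95, 100, 105), basal = c(8, 10, 12),
                      logr = seq(5.5, 7.5, 0.25))
  sses <- apply(grid, 1, sse_fun)
  start <- as.numeric(grid[which.min(sses), ])
  polish <- optim(start, sse_fun, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-15))
  polish <- optim(polish$par, sse_fun, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-15))
  oracle <- polish$par

  expect_equal(unname(fit$estimates["em[p]"]), oracle[1], tolerance = 1e-6)
  expect_equal(unname(fit$estimates["basal[p]"]), oracle[2], tolerance = 1e-6)
  expect_equal(unname(fit$estimates["logr[L,p]"]), oracle[3], tolerance = 1e-6)
})

test_that("concentration-unit invariance of predictions and objective", {
  # x10 concentrations with logKA' + 1 and logR - 1: A/KA and R*A are both
  # unchanged, so predictions, residuals and the objective are identical
  design <- simulation_design()
  ds <- simulate_dataset(design, dd_logr = 0.4, seed = 31)
  spec <- model_spec("intact", c("1", "2"), c("REF", "TEST"),
                     reference = "REF", error = "fixed",
                     error_values = list(add = 5, prop = 0.1))
  theta <- c("em[1]" = 100, "basal[1]" = 10, "em[2]" = 100, "basal[2]" = 10,
             "logkap[REF]" = -5, "logkap[TEST]" = -6,
             "logr[REF,1]" = 7, "logr[REF,2]" = 7,
             "logr[TEST,1]" = 6.4, "ddlogr[TEST]" = 0.4)
  ds10 <- ds
  ds10$conc <- ds$conc * 10
  theta10 <- theta
  kap <- grepl("^logkap", names(theta10))
  lr <- grepl("^logr", names(theta10))
  theta10[kap] <- theta10[kap] + 1
  theta10[lr] <- theta10[lr] - 1
  expect_equal(neg2_loglik(bias_dataset(ds10), spec, theta10),
               neg2_loglik(ds, spec, theta), tolerance = 1e-12)
})

test_that("covariance is symmetric and RSE is se over |estimate|", {
  ds <- make_single_curve(add_sd = 3, seed = 12)
  spec <- model_spec("marginal", "p", "L")
  fit <- fit_operational(ds, spec, fit_options(multistart = 3, seed = 5))
  expect_true(fit$converged)
  expect_equal(fit$cov, t(fit$cov), tolerance = 1e-10)
  free <- names(fit$estimates)[!fit$fixed]
  for (nm in free) {
    if (is.finite(fit$se[nm]) && fit$estimates[nm] != 0) {
      expect_equal(unname(fit$rse_pct[nm]),
                   100 * unname(fit$se[nm]) / abs(unname(fit$estimates[nm])),
                   tolerance = 1e-12)
    }
  }
})

test_that("nested models: richer model attains no worse an objective", {
  ds <- make_single_curve(add_sd = 3, seed = 21)
  spec_free <- model_spec("marginal", "p", "L", hill = "estimated")
  spec_fix <- model_spec("marginal", "p", "L", hill = "fixed", hill_value = 1)
  f_free <- fit_operational(ds, spec_free, fit_options(multistart = 4, seed = 2))
  f_fix <- fit_operational(ds, spec_fix, fit_options(multistart = 4, seed = 2))
  expect_identical(suppressMessages(ofv_compare(f_fix, f_fix)), 0)
  expect_lte(suppressMessages(ofv_compare(f_free, f_fix)), 1e-6)
})

test_that("full-agonist identifiability conventions", {
  design <- simulation_design()
  ds <- simulate_dataset(design, dd_logr = 0, seed = 77)
  spec <- model_spec("marginal", c("1", "2"), c("REF", "TEST"))
  out <- suppressMessages(apply_identifiability_conventions(spec, ds))
  # REF (tau = 100) is the full agonist in both pathways
  expect_equal(out$fix[["logka[REF,1]"]], 0)
  expect_equal(out$fix[["logka[REF,2]"]], 0)
  expect_null(out$fix[["logka[TEST,1]"]])

  # user-specified fix wins: spec returned unchanged
  spec_user <- model_spec("marginal", c("1", "2"), c("REF", "TEST"),
                          fix = list("logka[TEST,1]" = -6, "logka[TEST,2]" = -6))
  out_user <- suppressMessages(apply_identifiability_conventions(spec_user, ds))
  expect_identical(out_user$fix, spec_user$fix)

  # lone partial agonist (plateau below 0.9 Em): warn, fix nothing
  partial <- ds[ds$ligand == "TEST", ]
  spec_p <- model_spec("marginal", c("1", "2"), "TEST",
                       fix = list("em[1]" = 100, "em[2]" = 100))
  w <- testthat::capture_warnings(
    out_p <- apply_identifiability_conventions(spec_p, bias_dataset(partial)))
  expect_match(w, "partial", all = TRUE)
  expect_null(out_p$fix[["logka[TEST,1]"]])

  # intact variant: ligand full in every pathway has logkap fixed
  spec_i <- model_spec("intact", c("1", "2"), c("REF", "TEST"),
                       reference = "REF")
  out_i <- suppressMessages(apply_identifiability_conventions(spec_i, ds))
  expect_equal(out_i$fix[["logkap[REF]"]], 0)
  expect_null(out_i$fix[["logkap[TEST]"]])
})

test_that("five-ligand joint intact fit converges with finite RSEs", {
  fit <- example2_fit()
  expect_true(fit$converged)
  free <- names(fit$estimates)[!fit$fixed]
  expect_true(all(is.finite(fit$se[free])))
  rep_ <- parameter_report(fit)
  expect_true(all(c("parameter", "estimate", "se", "rse_pct", "fixed")
                  %in% names(rep_)))
})

test_that("opposing-intact fit recovers the ligand preference profile", {
  ds <- make_fixture("example1_shape", seed = 6)
  spec <- model_spec("opposing-intact", pathways = c("low", "high"),
                     ligands = "UK14304-like", hill = "estimated")
  fit <- fit_operational(ds, spec, fit_options(multistart = 8, seed = 2))
  expect_true(fit$converged)
  free <- names(fit$estimates)[!fit$fixed]
  expect_true(all(is.finite(fit$se[free])))
  # directly estimated preference profile near the generating 2.28
  expect_lt(abs(unname(fit$estimates["pref_i_s"]) - 2.28), 0.6)
  # shared basal is well determined
  expect_lt(unname(fit$rse_pct["basal"]), 5)
})
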
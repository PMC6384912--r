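# Shared per-session cache so expensive simulation-estimation batches are
# computed once and reused across test files.
.operbias_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .operbias_test_cache)) {
    assign(name, force(expr), envir = .operbias_test_cache)
  }
  get(name, envir = .operbias_test_cache)
}

# One null (or alternative) simulation-estimation batch: returns per-replicate
# Wald statistic plus the bias estimate and its SE (intact) so the same batch
# serves cutoff, coverage and bias checks.
run_sse_batch <- function(model, n_sim, seed, stream, dd_logr = 0) {
  design <- simulation_design()
  out <- data.frame(wald = rep(NA_real_, n_sim), dd = NA_real_, se = NA_real_)
  for (i in seq_len(n_sim)) {
    s <- operbias:::child_seed(seed, stream, i)
    ds <- simulate_dataset(design, dd_logr = dd_logr, seed = s)
    opt <- operbias:::sse_fit_options(seed = s)
    if (model == "intact") {
      spec <- operbias:::sse_spec("intact", design)
      spec <- suppressMessages(apply_identifiability_conventions(spec, ds))
      fit <- operbias:::fit_with_rescue(ds, spec, opt)
      if (!is.null(fit) && fit$converged) {
        dd <- unname(fit$estimates["ddlogr[TEST]"])
        se <- unname(fit$se["ddlogr[TEST]"])
        if (is.finite(se) && se > 0) {
          out[i, ] <- c((dd / se)^2, dd, se)
        }
      }
    } else {
      spec <- operbias:::sse_spec("marginal", design)
      spec <- suppressMessages(
        tryCatch(apply_identifiability_conventions(spec, ds),
                 warning = function(w) spec))
      fit <- operbias:::fit_with_rescue(ds, spec, opt)
      if (!is.null(fit) && fit$converged) {
        g <- function(l, p) unname(fit$estimates[sprintf("logr[%s,%s]", l, p)])
        gs <- function(l, p) unname(fit$se[sprintf("logr[%s,%s]", l, p)])
        ses <- c(gs("TEST", "1"), gs("REF", "1"), gs("TEST", "2"), gs("REF", "2"))
        if (all(is.finite(ses))) {
          dd <- ddlogr_posthoc(g("TEST", "1"), g("REF", "1"),
                               g("TEST", "2"), g("REF", "2"))
          se <- se_posthoc(ses[1], ses[2], ses[3], ses[4])
          if (se > 0) out[i, ] <- c((dd / se)^2, dd, se)
        }
      }
    }
  }
  out
}

null_batch <- function(model, n_sim = 200) {
  cached(paste0("null_", model),
         run_sse_batch(model, n_sim = n_sim, seed = 424242, stream = 0))
}

calibrated_cutoff <- function(model) {
  w <- null_batch(model)$wald
  empirical_percentile(w[is.finite(w)], 0.95)
}

example2_data <- function() {
  cached("ex2_data", make_fixture("example2_shape", seed = 8))
}

example2_fit <- function() {
  cached("ex2_fit", {
    spec <- model_spec("intact", c("1", "2"),
                       c("BUF", "DOI", "LSD", "QUI", "TFMPP"),
                       reference = "BUF", hill = "estimated",
                       fix = list("basal[2]" = 0))
    fit_operational(example2_data(), spec, fit_options(multistart = 4, seed = 4))
  })
}
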
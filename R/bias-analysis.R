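#' Ligand-bias metric from per-pathway transduction coefficients
#'
#' The doubly normalised bias metric
#' `ddlogr = (logR1 - logR1_ref) - (logR2 - logR2_ref)`: the test ligand's
#' between-pathway logR difference minus the reference ligand's, which
#' cancels system and observational bias.
#'
#' @param logr1,logr2 Test-ligand log10 transduction coefficients for
#'   pathways 1 and 2.
#' @param logr1_ref,logr2_ref Reference-ligand values.
#' @return Dimensionless bias metric.
#' @examples
#' ddlogr_posthoc(6.70, 6.51, 6.65, 6.14)  # -0.32
#' @export
ddlogr_posthoc <- function(logr1, logr1_ref, logr2, logr2_ref) {
  stopifnot(is.finite(logr1), is.finite(logr1_ref),
            is.finite(logr2), is.finite(logr2_ref))
  (logr1 - logr1_ref) - (logr2 - logr2_ref)
}

#' Standard error of the post hoc bias metric
#'
#' Root-sum-of-squares propagation over the four independent logR estimates
#' entering [ddlogr_posthoc()] (independence is reasonable for the standard
#' post hoc analysis, where each logR comes from a separate fit or a
#' block-diagonal covariance).
#'
#' @param se1,se1_ref,se2,se2_ref Standard errors (>= 0) of the four logR
#'   estimates.
#' @return Propagated standard error.
#' @export
se_posthoc <- function(se1, se1_ref, se2, se2_ref) {
  ses <- c(se1, se1_ref, se2, se2_ref)
  if (any(ses < 0)) stop("standard errors must be >= 0", call. = FALSE)
  sqrt(se1^2 + se1_ref^2 + se2^2 + se2_ref^2)
}

#' Ligand preference profile between two pathways
#'
#' The un-normalised between-pathway difference
#' `logR_i:s = logR_i - logR_s` for a single ligand (e.g. inhibitory vs
#' stimulatory pathway), with root-sum-of-squares standard error.  This is
#' the intermediate quantity of the first normalisation step of a bias
#' analysis and is useful for go/no-go decisions after a single-ligand
#' experiment.
#'
#' @param logr_i,logr_s log10 transduction coefficients of the two pathways.
#' @param se_i,se_s Their standard errors.
#' @return A list of class `"preference_profile"` with `log_r_i_s`, `se` and
#'   `rse_pct`.
#' @export
preference_posthoc <- function(logr_i, logr_s, se_i = NA_real_,
                               se_s = NA_real_) {
  stopifnot(is.finite(logr_i), is.finite(logr_s))
  val <- logr_i - logr_s
  se <- sqrt(se_i^2 + se_s^2)
  structure(list(log_r_i_s = val, se = se,
                 rse_pct = if (val != 0) 100 * se / abs(val) else NA_real_),
            class = "preference_profile")
}

#' @export
print.preference_profile <- function(x, ...) {
  cat(sprintf("logR_i:s = %.3f (SE %.3f, RSE %.1f%%)\n",
              x$log_r_i_s, x$se, x$rse_pct))
  invisible(x)
}

#' Wald statistic for a single estimate
#'
#' The ratio of the squared estimate to its variance, `(estimate / se)^2`.
#'
#' @param estimate Point estimate.
#' @param se Its standard error (> 0).
#' @return Dimensionless Wald statistic.
#' @export
wald_statistic <- function(estimate, se) {
  if (any(se <= 0) || any(!is.finite(se))) {
    stop("'se' must be finite and > 0", call. = FALSE)
  }
  (estimate / se)^2
}

#' p-value of a Wald statistic
#'
#' Upper-tail probability under the chi-square distribution with 1 degree of
#' freedom (equivalent to a two-sided z test), consistent with the
#' theoretical cutoff of 3.84 at alpha = 0.05.
#'
#' @param wald Wald statistic(s), >= 0.
#' @return p-value(s) in \[0, 1\].
#' @export
wald_pvalue <- function(wald) {
  if (any(wald < 0)) stop("'wald' must be >= 0", call. = FALSE)
  stats::pchisq(wald, df = 1, lower.tail = FALSE)
}

#' Bonferroni-adjusted per-test significance level
#'
#' @param alpha Overall significance level (0 < alpha < 1).
#' @param n_tests Number of hypotheses tested (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 4)  # 0.0125
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (n_tests < 1) stop("'n_tests' must be >= 1", call. = FALSE)
  alpha / n_tests
}

#' Ligand-bias test table from a fitted model
#'
#' Builds one bias test per non-reference ligand.  For an intact fit with a
#' declared reference the bias metric and its standard error are read
#' directly from the `ddlogr[l]` parameters ("direct-intact" method).  For a
#' marginal fit they are computed post hoc from the per-pathway logR
#' estimates via [ddlogr_posthoc()] and [se_posthoc()] ("posthoc-marginal").
#' Each ligand's Wald statistic is compared against the chi-square(1)
#' quantile at the Bonferroni-adjusted level `alpha / n_tests`, or — when a
#' simulation-calibrated `cutoff` is supplied — against that empirical
#' cutoff (in which case p-values are still reported on the chi-square(1)
#' scale).
#'
#' @param fit An `"operbias_fit"` from [fit_operational()].
#' @param alpha Overall significance level before Bonferroni adjustment.
#' @param reference Reference ligand; defaults to the spec's.
#' @param cutoff Optional empirical Wald cutoff from [calibrate_cutoff()].
#' @return A data.frame of class `"bias_table"` with one row per test
#'   ligand: `ligand`, `reference`, `dd_logr`, `se`, `rse_pct`, `wald`,
#'   `p_value`, `significant`, `method`; the adjusted alpha (and any cutoff)
#'   are attached as attributes.
#' @export
bias_table <- function(fit, alpha = 0.05, reference = NULL, cutoff = NULL) {
  spec <- fit$spec
  reference <- reference %||% spec$reference
  if (is.null(reference)) {
    stop("a reference ligand is required (in the spec or as 'reference')",
         call. = FALSE)
  }
  if (!reference %in% spec$ligands) {
    stop("reference ligand '", reference, "' not in the fitted spec",
         call. = FALSE)
  }
  if (length(spec$pathways) != 2L) {
    stop("bias tables are pairwise: the fit must cover exactly 2 pathways",
         call. = FALSE)
  }
  test_ligands <- setdiff(spec$ligands, reference)
  if (!length(test_ligands)) stop("no test ligands", call. = FALSE)
  n_tests <- length(test_ligands)
  alpha_adj <- bonferroni_alpha(alpha, n_tests)
  p1 <- spec$pathways[1]; p2 <- spec$pathways[2]

  direct <- spec$variant == "intact" && !is.null(spec$reference)
  rows <- lapply(test_ligands, function(ll) {
    if (direct) {
      nm <- sprintf("ddlogr[%s]", ll)
      dd <- unname(fit$estimates[nm])
      se <- unname(fit$se[nm])
      method <- "direct-intact"
    } else if (spec$variant == "marginal") {
      g <- function(l, p) unname(fit$estimates[sprintf("logr[%s,%s]", l, p)])
      gs <- function(l, p) unname(fit$se[sprintf("logr[%s,%s]", l, p)])
      dd <- ddlogr_posthoc(g(ll, p1), g(reference, p1), g(ll, p2),
                           g(reference, p2))
      se <- se_posthoc(gs(ll, p1), gs(reference, p1), gs(ll, p2),
                       gs(reference, p2))
      method <- "posthoc-marginal"
    } else {
      stop("bias_table supports marginal and intact fits", call. = FALSE)
    }
    w <- if (is.finite(se) && se > 0) wald_statistic(dd, se) else NA_real_
    p <- if (is.finite(w)) wald_pvalue(w) else NA_real_
    sig <- if (!is.finite(w)) NA
           else if (!is.null(cutoff)) w > cutoff
           else p < alpha_adj
    data.frame(ligand = ll, reference = reference,
               pathway_1 = p1, pathway_2 = p2,
               dd_logr = dd, se = se,
               rse_pct = if (is.finite(dd) && dd != 0) 100 * se / abs(dd)
                         else NA_real_,
               wald = w, p_value = p, significant = sig, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("bias_table", "data.frame"),
            alpha = alpha, alpha_adjusted = alpha_adj, cutoff = cutoff)
}

#' @export
print.bias_table <- function(x, digits = 3, ...) {
  cutoff <- attr(x, "cutoff")
  cat(sprintf("Ligand bias tests (%s) | overall alpha %.3g, adjusted %.4g%s\n",
              x$method[1], attr(x, "alpha"), attr(x, "alpha_adjusted"),
              if (!is.null(cutoff))
                sprintf(" | calibrated Wald cutoff %.3f", cutoff) else ""))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a bias table as delimited text
#'
#' Mirrors the usual published layout (ligand, bias metric, SE, RSE%, Wald,
#' p, significance call) with the adjusted alpha recorded in the metadata
#' header.
#'
#' @param x A [bias_table()].
#' @param path Output path.
#' @param meta Extra named metadata values for the `#` header.
#' @return `path`, invisibly.
#' @export
write_bias_table <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# operbias bias report", con)
  writeLines(sprintf("# alpha: %g", attr(x, "alpha")), con)
  writeLines(sprintf("# alpha_adjusted: %g", attr(x, "alpha_adjusted")), con)
  if (!is.null(attr(x, "cutoff"))) {
    writeLines(sprintf("# calibrated_cutoff: %g", attr(x, "cutoff")), con)
  }
  if (length(meta)) writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}
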
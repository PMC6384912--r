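#' Declare a model to be fitted to a concentration-response dataset
#'
#' A `model_spec` names the model variant, the pathways and ligands it
#' covers, which ligand is the reference for bias estimation, and which
#' parameters are fixed rather than estimated.
#'
#' Parameter naming conventions (used in `fix`, in fit output and in reports):
#' \itemize{
#'   \item per-pathway system parameters `em[p]`, `basal[p]`, `n[p]` and
#'     residual-error parameters `add[p]` (additive SD, response units) and
#'     `prop[p]` (proportional SD, fraction);
#'   \item marginal ligand parameters `logka[l,p]` and `logr[l,p]`;
#'   \item intact ligand parameters `logkap[l]` (shared apparent KA') and
#'     `logr[l,p]`; with a reference ligand declared, each non-reference
#'     ligand's second-pathway coefficient is replaced by the directly
#'     estimated bias parameter `ddlogr[l]`;
#'   \item opposing-variant parameters `basal`, `em_i`, `n_i`, `em_s`, `n_s`,
#'     `logka_i`/`logka_s` (marginal) or `logkap` (intact), `logr_i_low`,
#'     `logr_s_low` (marginal) or `pref_i_s` (intact), `add`, `prop`.
#' }
#'
#' @param variant One of `"marginal"`, `"intact"`, `"opposing-marginal"`,
#'   `"opposing-intact"`.
#' @param pathways Character vector of pathway identifiers (exactly 2 for the
#'   reparameterised intact model; for opposing variants these are the
#'   expression levels, default `c("low", "high")`).
#' @param ligands Character vector of ligand identifiers.
#' @param reference Reference ligand for bias metrics.  Required when
#'   `ddlogr` parameters are wanted (intact with >= 2 ligands); must be one
#'   of `ligands`.
#' @param fix Named list of parameters to fix, e.g.
#'   `list("logka[TFMPP,1]" = 0, "basal[2]" = 0)`.
#' @param hill `"fixed"` (default, at `hill_value`) or `"estimated"`.
#' @param hill_value Value of the Hill slope when fixed (default 1).
#' @param error `"estimated"` (default) or `"fixed"`; when fixed,
#'   `error_values` supplies the per-pathway SDs.
#' @param error_values List with numeric vectors `add` and `prop`, one value
#'   per pathway (recycled if scalar); required when `error = "fixed"`.
#' @param density_log_shift log10 receptor-density ratio between the two
#'   expression levels of the opposing variants (default 1).
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(variant = c("marginal", "intact",
                                   "opposing-marginal", "opposing-intact"),
                       pathways, ligands, reference = NULL,
                       fix = list(),
                       hill = c("fixed", "estimated"), hill_value = 1,
                       error = c("estimated", "fixed"), error_values = NULL,
                       density_log_shift = 1) {
  variant <- match.arg(variant)
  hill <- match.arg(hill)
  error <- match.arg(error)
  opposing <- grepl("^opposing", variant)
  if (opposing && missing(pathways)) pathways <- c("low", "high")
  if (opposing && missing(ligands)) ligands <- "ligand"
  pathways <- as.character(pathways)
  ligands <- as.character(ligands)
  if (!is.null(reference) && !reference %in% ligands) {
    stop("reference ligand '", reference, "' is not among 'ligands'",
         call. = FALSE)
  }
  if (variant == "intact" && !is.null(reference) && length(pathways) != 2L) {
    stop("direct bias estimation (ddlogr) is pairwise: declare exactly 2 ",
         "pathways or omit 'reference'", call. = FALSE)
  }
  if (error == "fixed" && is.null(error_values)) {
    stop("'error_values' required when error = \"fixed\"", call. = FALSE)
  }
  spec <- structure(list(
    variant = variant, pathways = pathways, ligands = ligands,
    reference = reference, fix = fix,
    hill = hill, hill_value = hill_value,
    error = error, error_values = error_values,
    density_log_shift = density_log_shift
  ), class = "model_spec")
  validate_fix(spec)
  spec
}

validate_fix <- function(spec) {
  if (!length(spec$fix)) return(invisible(TRUE))
  tab <- par_table(spec)
  unknown <- setdiff(names(spec$fix), tab$name)
  if (length(unknown)) {
    stop("fix refers to unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!vapply(spec$fix, function(v) is.numeric(v) && is.finite(v), TRUE))) {
    stop("every fixed parameter needs a finite numeric value", call. = FALSE)
  }
  invisible(TRUE)
}

## Full parameter table for a spec: name, transform scale for the optimiser,
## natural-scale bounds, fixed flag and fixed value.
par_table <- function(spec) {
  v <- spec$variant
  p <- spec$pathways
  l <- spec$ligands
  rows <- list()
  add_par <- function(name, scale, lower, upper, fixed = FALSE, value = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, scale = scale, lower = lower, upper = upper,
      fixed = fixed, value = value, stringsAsFactors = FALSE)
  }
  n_fixed <- spec$hill == "fixed"
  if (v %in% c("marginal", "intact")) {
    for (pp in p) {
      add_par(sprintf("em[%s]", pp), "log", 1e-8, 1e8)
      add_par(sprintf("basal[%s]", pp), "id", -1e8, 1e8)
      add_par(sprintf("n[%s]", pp), "log", 1e-2, 1e2,
              fixed = n_fixed, value = if (n_fixed) spec$hill_value else NA_real_)
    }
    if (v == "marginal") {
      for (ll in l) for (pp in p) {
        add_par(sprintf("logka[%s,%s]", ll, pp), "id", -15, 15)
      }
    } else {
      for (ll in l) add_par(sprintf("logkap[%s]", ll), "id", -15, 15)
    }
    reparam <- v == "intact" && !is.null(spec$reference)
    for (ll in l) {
      if (reparam && ll != spec$reference) {
        add_par(sprintf("logr[%s,%s]", ll, p[1]), "id", -15, 15)
        add_par(sprintf("ddlogr[%s]", ll), "id", -15, 15)
      } else {
        for (pp in p) add_par(sprintf("logr[%s,%s]", ll, pp), "id", -15, 15)
      }
    }
    err_fixed <- spec$error == "fixed"
    ev <- spec$error_values
    for (k in seq_along(p)) {
      add_par(sprintf("add[%s]", p[k]), "log", 1e-8, 1e6, fixed = err_fixed,
              value = if (err_fixed) rep(ev$add, length.out = length(p))[k] else NA_real_)
      add_par(sprintf("prop[%s]", p[k]), "log", 1e-8, 1e2, fixed = err_fixed,
              value = if (err_fixed) rep(ev$prop, length.out = length(p))[k] else NA_real_)
    }
  } else {
    add_par("basal", "id", -1e8, 1e8)
    add_par("em_i", "log", 1e-8, 1e8)
    add_par("n_i", "log", 1e-2, 1e2, fixed = n_fixed,
            value = if (n_fixed) spec$hill_value else NA_real_)
    add_par("em_s", "log", 1e-8, 1e8)
    add_par("n_s", "log", 1e-2, 1e2, fixed = n_fixed,
            value = if (n_fixed) spec$hill_value else NA_real_)
    if (v == "opposing-marginal") {
      add_par("logka_i", "id", -15, 15)
      add_par("logka_s", "id", -15, 15)
      add_par("logr_i_low", "id", -15, 15)
      add_par("logr_s_low", "id", -15, 15)
    } else {
      add_par("logkap", "id", -15, 15)
      add_par("logr_i_low", "id", -15, 15)
      add_par("pref_i_s", "id", -15, 15)
    }
    err_fixed <- spec$error == "fixed"
    ev <- spec$error_values
    add_par("add", "log", 1e-8, 1e6, fixed = err_fixed,
            value = if (err_fixed) ev$add[1] else NA_real_)
    add_par("prop", "log", 1e-8, 1e2, fixed = err_fixed,
            value = if (err_fixed) ev$prop[1] else NA_real_)
  }
  tab <- do.call(rbind, rows)
  for (nm in names(spec$fix)) {
    i <- match(nm, tab$name)
    tab$fixed[i] <- TRUE
    tab$value[i] <- spec$fix[[nm]]
  }
  tab
}

#' Fix the dissociation constant of full agonists
#'
#' The operational model cannot identify the dissociation constant of a full
#' agonist from a concentration-response curve alone (its transduction
#' coefficient absorbs the potency), so the convention is to fix that
#' parameter to 0.
#'
#' For the marginal variant, each pathway's most efficacious ligand — the
#' one with the highest mean observed response at its top concentration —
#' has `logka[l,p]` fixed to 0, unless the user already fixed a `logka` in
#' that pathway.  If that top ligand plateaus below 90\% of the system
#' maximum (a fixed `em[p]` if available, otherwise the largest
#' per-(ligand, concentration) mean in the pathway) it is treated as
#' partial: nothing is fixed and a warning is emitted.
#'
#' For the intact variant the shared apparent constant `logkap[l]` is flat
#' in the likelihood only when the ligand is a full agonist in \emph{every}
#' pathway (any partial-agonist pathway pins it down); each such ligand has
#' `logkap[l]` fixed to 0, unless the user already fixed some `logkap`.
#'
#' @param spec A marginal or intact [model_spec()].
#' @param dataset A [bias_dataset()].
#' @return The spec, possibly with added entries in `$fix`.
#' @export
apply_identifiability_conventions <- function(spec, dataset) {
  if (!spec$variant %in% c("marginal", "intact")) {
    stop("identifiability conventions apply to the marginal and intact ",
         "variants", call. = FALSE)
  }
  if (spec$variant == "intact") {
    return(apply_intact_conventions(spec, dataset))
  }
  for (pp in spec$pathways) {
    ka_names <- sprintf("logka[%s,%s]", spec$ligands, pp)
    tab <- par_table(spec)
    if (any(tab$fixed[match(ka_names, tab$name)])) next
    sub <- dataset[dataset$pathway == pp, ]
    plateau <- vapply(spec$ligands, function(ll) {
      d <- sub[sub$ligand == ll, ]
      if (!nrow(d)) return(NA_real_)
      mean(d$response[d$conc == max(d$conc)])
    }, 0)
    top <- spec$ligands[which.max(plateau)]
    em_name <- sprintf("em[%s]", pp)
    # noise-robust system-maximum proxy: the largest top-concentration
    # plateau (a max over all per-concentration means is biased upward)
    em_ref <- if (!is.null(spec$fix[[em_name]])) spec$fix[[em_name]]
              else max(plateau, na.rm = TRUE)
    if (is.finite(em_ref) && plateau[which.max(plateau)] < 0.9 * em_ref) {
      warning("pathway '", pp, "': most efficacious ligand ('", top,
              "') looks partial; no logKA fixed", call. = FALSE)
      next
    }
    spec$fix[[sprintf("logka[%s,%s]", top, pp)]] <- 0
    message("pathway '", pp, "': fixed logka[", top, ",", pp,
            "] = 0 (full-agonist convention)")
  }
  spec
}

apply_intact_conventions <- function(spec, dataset) {
  tab <- par_table(spec)
  kap_names <- sprintf("logkap[%s]", spec$ligands)
  if (any(tab$fixed[match(kap_names, tab$name)], na.rm = TRUE)) return(spec)
  em_proxy <- plateau <- list()
  for (pp in spec$pathways) {
    sub <- dataset[dataset$pathway == pp, ]
    plateau[[pp]] <- vapply(spec$ligands, function(ll) {
      d <- sub[sub$ligand == ll, ]
      if (!nrow(d)) return(NA_real_)
      mean(d$response[d$conc == max(d$conc)])
    }, 0)
    em_name <- sprintf("em[%s]", pp)
    em_proxy[[pp]] <- if (!is.null(spec$fix[[em_name]])) spec$fix[[em_name]]
                      else max(plateau[[pp]], na.rm = TRUE)
  }
  for (ll in spec$ligands) {
    ratios <- vapply(spec$pathways,
                     function(pp) plateau[[pp]][ll] / em_proxy[[pp]], 0)
    if (all(is.finite(ratios)) && all(ratios >= 0.9)) {
      spec$fix[[sprintf("logkap[%s]", ll)]] <- 0
      message("ligand '", ll, "' is full agonist in every pathway: fixed ",
              "logkap[", ll, "] = 0 (full-agonist convention)")
    }
  }
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s | pathways: %s | ligands: %s%s\n",
              x$variant, paste(x$pathways, collapse = ", "),
              paste(x$ligands, collapse = ", "),
              if (is.null(x$reference)) ""
              else paste0(" | reference: ", x$reference)))
  tab <- par_table(x)
  nfix <- sum(tab$fixed)
  cat(sprintf("  %d parameters (%d estimated, %d fixed)\n",
              nrow(tab), nrow(tab) - nfix, nfix))
  if (nfix) {
    f <- tab[tab$fixed, ]
    cat(sprintf("  fixed: %s\n",
                paste(sprintf("%s = %g", f$name, f$value), collapse = ", ")))
  }
  invisible(x)
}
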
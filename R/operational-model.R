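#' System parameters of an operational concentration-response curve
#'
#' Bundles the three "system" parameters of the Black-Leff operational model:
#' the system maximal response `em`, the baseline response in the absence of
#' ligand `basal`, and the Hill slope factor `n`.  These describe the
#' tissue/assay, not the ligand.
#'
#' @param em System maximal response (response units).
#' @param basal Baseline response in the absence of ligand (response units).
#'   Must differ from `em`; for stimulatory pathways `em > basal`.
#' @param n Hill slope factor (dimensionless, > 0).
#' @return An object of class `"system_params"` (a named list).
#' @examples
#' system_params(em = 100, basal = 10, n = 1)
#' @export
system_params <- function(em, basal, n = 1) {
  stopifnot(is.numeric(em), is.numeric(basal), is.numeric(n))
  if (!all(is.finite(c(em, basal, n)))) {
    stop("system parameters must be finite", call. = FALSE)
  }
  if (n <= 0) stop("Hill slope 'n' must be > 0", call. = FALSE)
  if (em == basal) stop("'em' must differ from 'basal'", call. = FALSE)
  structure(list(em = em, basal = basal, n = n), class = "system_params")
}

## Shared kernel: the operational fraction 1 / (1 + ((A/KA + 1)/(R*A))^n),
## with the A = 0 limit (0) substituted analytically so grids that include a
## blank well never divide by zero.
op_fraction <- function(conc, log_ka, log_r, n) {
  frac <- rep.int(0, length(conc))
  pos <- conc > 0
  if (any(pos)) {
    a <- conc[pos]
    ratio <- (a / 10^log_ka + 1) / (10^log_r * a)
    frac[pos] <- 1 / (1 + ratio^n)
  }
  frac
}

#' Operational model response (single pathway, marginal form)
#'
#' Evaluates the Black-Leff operational model
#' \deqn{E = Basal + \frac{E_m - Basal}{1 + \left(\frac{A/10^{logK_A} + 1}
#'   {10^{logR} \cdot A}\right)^n}}{E = Basal + (Em - Basal) /
#'   (1 + ((A/10^logKA + 1)/(10^logR * A))^n)}
#' where `A` is the molar ligand concentration, `logKA` the log10 equilibrium
#' dissociation constant and `logR` the log10 transduction coefficient
#' (R = tau / KA).  At `A = 0` the analytic limit `Basal` is returned.
#'
#' @param conc Molar ligand concentration(s), >= 0.  Vectorised.
#' @param sys A [system_params()] object (or list with `em`, `basal`, `n`).
#' @param log_ka log10 equilibrium dissociation constant (log10 molar).
#' @param log_r log10 transduction coefficient.
#' @return Predicted response(s), same length as `conc`.
#' @examples
#' sys <- system_params(100, 10, 1)
#' operational_response(1e-7, sys, log_ka = -5, log_r = 7)  # 54.776
#' @export
operational_response <- function(conc, sys, log_ka, log_r) {
  check_model_inputs(conc, sys, log_ka, log_r)
  sys$basal + (sys$em - sys$basal) * op_fraction(conc, log_ka, log_r, sys$n)
}

check_model_inputs <- function(conc, sys, ...) {
  pars <- c(sys$em, sys$basal, sys$n, ...)
  if (!all(is.finite(pars))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("'conc' must be finite and >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Intact operational model response
#'
#' Evaluates the intact operational model, in which every signalling pathway
#' of a ligand shares a single apparent equilibrium dissociation constant
#' `log_ka_prime` while keeping a pathway-specific transduction coefficient.
#' Pathway selection plays the role of the indicator functions in the joined
#' two-pathway form of the model.
#'
#' @param conc Molar ligand concentration(s), >= 0.
#' @param pathway Pathway identifier; must name an element of `sys_by_path`
#'   and of `log_r`.
#' @param sys_by_path Named list of [system_params()], one per pathway.
#' @param log_ka_prime Shared log10 apparent dissociation constant
#'   (log10 molar).
#' @param log_r Named numeric vector (or list) of log10 transduction
#'   coefficients, one per pathway.
#' @return Predicted response(s).
#' @seealso [operational_response()], [intact_response_reparam()]
#' @export
intact_response <- function(conc, pathway, sys_by_path, log_ka_prime, log_r) {
  pathway <- as.character(pathway)
  if (is.null(sys_by_path[[pathway]])) {
    stop("unknown pathway '", pathway, "' in 'sys_by_path'", call. = FALSE)
  }
  lr <- log_r[[pathway]]
  if (is.null(lr) || is.na(lr)) {
    stop("no logR declared for pathway '", pathway, "'", call. = FALSE)
  }
  operational_response(conc, sys_by_path[[pathway]],
                       log_ka = log_ka_prime, log_r = lr)
}

#' Pathway-2 transduction coefficient implied by a directly parameterised
#' ligand-bias metric
#'
#' In the reparameterised intact model the test ligand's pathway-2
#' transduction coefficient is not a free parameter; it is materialised from
#' pathway 1 and the reference ligand via
#' `logR2 = logR1 - logR1_ref + logR2_ref - dd_logr`.
#'
#' @param log_r1 Test ligand log10 transduction coefficient, pathway 1.
#' @param log_r1_ref,log_r2_ref Reference ligand log10 transduction
#'   coefficients for pathways 1 and 2.
#' @param dd_logr Ligand-bias metric (delta-delta-logR, pathway 1 minus
#'   pathway 2, both normalised to the reference ligand).
#' @return Implied log10 transduction coefficient for pathway 2.
#' @export
implied_log_r2 <- function(log_r1, log_r1_ref, log_r2_ref, dd_logr) {
  log_r1 - log_r1_ref + log_r2_ref - dd_logr
}

#' Intact model response with the bias metric as a direct parameter
#'
#' Identical to [intact_response()] except that the test ligand's pathway-2
#' transduction coefficient is derived through [implied_log_r2()], so that
#' delta-delta-logR is itself an input (and, in fitting, a directly estimated
#' parameter with a model-based standard error).
#'
#' @inheritParams intact_response
#' @param log_r1 Test ligand log10 transduction coefficient for pathway 1.
#' @param log_r1_ref,log_r2_ref Reference ligand log10 transduction
#'   coefficients.
#' @param dd_logr Ligand-bias metric.
#' @param pathway Either the first or the second element of
#'   `names(sys_by_path)`; the first uses `log_r1`, the second the implied
#'   pathway-2 coefficient.
#' @return Predicted response(s).
#' @export
intact_response_reparam <- function(conc, pathway, sys_by_path,
                                    log_ka_prime, log_r1,
                                    log_r1_ref, log_r2_ref, dd_logr) {
  paths <- names(sys_by_path)
  if (length(paths) != 2L) {
    stop("the reparameterised intact model is pairwise: exactly 2 pathways",
         call. = FALSE)
  }
  log_r <- c(log_r1, implied_log_r2(log_r1, log_r1_ref, log_r2_ref, dd_logr))
  names(log_r) <- paths
  intact_response(conc, pathway, sys_by_path, log_ka_prime, log_r)
}

#' Apparent equilibrium dissociation constant of the intact model
#'
#' The intact model integrates per-pathway dissociation constants into one
#' apparent constant, `KA' = 1 / sum(1/KA_i)` (proportional to the harmonic
#' mean of the per-pathway values).  Accepts two or more pathways.
#'
#' @param ka_values Numeric vector of per-pathway molar KA values, all > 0.
#' @return Apparent molar KA'; always <= `min(ka_values)`.
#' @examples
#' ka_prime(c(2e-5, 2e-5))  # 1e-5
#' @export
ka_prime <- function(ka_values) {
  ka_values <- as.numeric(ka_values)
  if (length(ka_values) < 1L || anyNA(ka_values) || any(ka_values <= 0)) {
    stop("'ka_values' must all be > 0", call. = FALSE)
  }
  1 / sum(1 / ka_values)
}

#' Half-maximal concentration of an operational curve
#'
#' For the operational model with unit Hill slope the half-maximal
#' concentration is `C50 = KA / (tau + 1)`; as efficacy vanishes
#' (`tau -> 0`) the C50 approaches the dissociation constant itself.
#'
#' @param ka Molar equilibrium dissociation constant (> 0).
#' @param tau Transducer ratio (dimensionless, >= 0).
#' @return Molar C50; monotone decreasing in `tau`.
#' @export
c50 <- function(ka, tau) {
  if (any(ka <= 0)) stop("'ka' must be > 0", call. = FALSE)
  if (any(tau < 0)) stop("'tau' must be >= 0", call. = FALSE)
  ka / (tau + 1)
}

#' Transducer ratio from the transduction coefficient
#'
#' The transduction coefficient is `R = tau / KA`, so
#' `tau = 10^(logR + logKA)`.  `tau` (receptor density over the coupling
#' constant) is never an independent parameter of the fitted models; it is
#' exposed only as this derived quantity.
#'
#' @param log_r log10 transduction coefficient.
#' @param log_ka log10 molar dissociation constant.
#' @return Transducer ratio (dimensionless, > 0).
#' @export
tau_from <- function(log_r, log_ka) {
  if (any(!is.finite(log_r)) || any(!is.finite(log_ka))) {
    stop("inputs must be finite", call. = FALSE)
  }
  10^(log_r + log_ka)
}

#' log10 shift in transduction coefficients between receptor-expression levels
#'
#' The transduction coefficient is proportional to total receptor density, so
#' two expression levels of the same system differ by
#' `log10(rt_high / rt_low)` on the logR scale (e.g. 10 vs 1 pmol/mg gives a
#' shift of 1).
#'
#' @param rt_high,rt_low Receptor densities (same units, e.g. pmol/mg), > 0.
#' @return Dimensionless log10 shift.
#' @export
receptor_density_shift <- function(rt_high, rt_low) {
  if (any(rt_high <= 0) || any(rt_low <= 0)) {
    stop("receptor densities must be > 0", call. = FALSE)
  }
  log10(rt_high / rt_low)
}

#' Specification of an opposing two-pathway (Gi/Gs-type) system
#'
#' Describes a system in which an inhibitory and a stimulatory pathway act on
#' the same readout (e.g. Gi-mediated inhibition and Gs-mediated stimulation
#' of adenylate cyclase), measured at a low and a high receptor-expression
#' level.  The response is `basal` minus an inhibitory operational term plus
#' a stimulatory operational term; at the high expression level both logR
#' values are incremented by `density_log_shift`.
#'
#' @param basal Baseline response, common to both pathway terms.
#' @param em_i,n_i Magnitude and Hill slope of the inhibitory term.
#' @param em_s,n_s Magnitude and Hill slope of the stimulatory term.
#' @param log_ka_i,log_ka_s Per-pathway log10 KA (marginal variant).
#' @param log_ka_prime Shared log10 apparent KA' (intact variant).
#' @param log_r_i_low log10 transduction coefficient, inhibitory pathway, low
#'   expression.
#' @param log_r_s_low log10 transduction coefficient, stimulatory pathway,
#'   low expression (marginal variant).
#' @param pref_i_s Ligand preference profile logR_i:s = logR_i - logR_s at
#'   low expression (intact variant; implies
#'   `log_r_s_low = log_r_i_low - pref_i_s`).
#' @param density_log_shift log10 receptor-density ratio between the high and
#'   low expression levels (1 for 10 vs 1 pmol/mg); see
#'   [receptor_density_shift()].
#' @return An object of class `"opposing_spec"`.
#' @export
opposing_spec <- function(basal, em_i, n_i, em_s, n_s,
                          log_ka_i = NULL, log_ka_s = NULL,
                          log_ka_prime = NULL,
                          log_r_i_low, log_r_s_low = NULL, pref_i_s = NULL,
                          density_log_shift = 1) {
  if (is.null(log_r_s_low) && is.null(pref_i_s)) {
    stop("supply either 'log_r_s_low' or 'pref_i_s'", call. = FALSE)
  }
  if (is.null(log_r_s_low)) log_r_s_low <- log_r_i_low - pref_i_s
  structure(list(
    basal = basal, em_i = em_i, n_i = n_i, em_s = em_s, n_s = n_s,
    log_ka_i = log_ka_i, log_ka_s = log_ka_s, log_ka_prime = log_ka_prime,
    log_r_i_low = log_r_i_low, log_r_s_low = log_r_s_low,
    density_log_shift = density_log_shift
  ), class = "opposing_spec")
}

#' Response of an opposing inhibitory/stimulatory two-pathway system
#'
#' @param conc Molar ligand concentration(s), >= 0.
#' @param expression_level `"low"` or `"high"`; at `"high"` both pathway logR
#'   values are shifted up by `spec$density_log_shift`.
#' @param spec An [opposing_spec()].
#' @param variant `"marginal"` (per-pathway KA) or `"intact"` (one shared
#'   apparent KA').
#' @return Predicted response(s); equals `spec$basal` at `conc = 0`.
#' @export
opposing_response <- function(conc, expression_level, spec,
                              variant = c("intact", "marginal")) {
  variant <- match.arg(variant)
  if (!expression_level %in% c("low", "high")) {
    stop("unknown expression level '", expression_level, "'", call. = FALSE)
  }
  shift <- if (expression_level == "high") spec$density_log_shift else 0
  if (variant == "intact") {
    if (is.null(spec$log_ka_prime)) {
      stop("intact variant requires 'log_ka_prime'", call. = FALSE)
    }
    ka_i <- ka_s <- spec$log_ka_prime
  } else {
    if (is.null(spec$log_ka_i) || is.null(spec$log_ka_s)) {
      stop("marginal variant requires 'log_ka_i' and 'log_ka_s'", call. = FALSE)
    }
    ka_i <- spec$log_ka_i
    ka_s <- spec$log_ka_s
  }
  spec$basal -
    spec$em_i * op_fraction(conc, ka_i, spec$log_r_i_low + shift, spec$n_i) +
    spec$em_s * op_fraction(conc, ka_s, spec$log_r_s_low + shift, spec$n_s)
}

#' Numerical C50 of any single-curve response function
#'
#' Finds the concentration at which a (monotone section of a) predicted
#' curve crosses the midpoint between its value at zero and its plateau at
#' the top of the grid.  Used as a diagnostic for exploring how far apart the
#' C50 values of two pathways sharing one apparent KA' can be pushed; the
#' package asserts no particular bound.
#'
#' @param f A function of molar concentration returning the mean response.
#' @param lower,upper log10 molar search interval.
#' @param plateau Top-of-curve response; defaults to `f(10^upper)`.  Pass the
#'   analytic plateau when high precision matters (the default proxy carries
#'   the residual slope at the top of the grid).
#' @return Molar concentration of the midpoint crossing.
#' @export
c50_numeric <- function(f, lower = -14, upper = 0, plateau = NULL) {
  e0 <- f(0)
  etop <- plateau %||% f(10^upper)
  mid <- (e0 + etop) / 2
  root <- stats::uniroot(function(la) f(10^la) - mid,
                         lower = lower, upper = upper, tol = 1e-12)
  10^root$root
}
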
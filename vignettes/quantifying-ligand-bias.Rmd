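---
title: "Quantifying ligand bias with marginal and intact operational models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ligand bias with marginal and intact operational models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operbias)
```

## The problem

A ligand acting on one G-protein-coupled receptor can activate several
downstream signalling pathways to different degrees; this *functional
selectivity* (ligand bias) matters for drug discovery because a ligand that
preferentially drives a therapeutic pathway over an adverse one is a better
starting point than an unbiased one.  The standard quantitative framework is
the Black–Leff operational model of agonism,

$$E = Basal + \frac{E_m - Basal}
      {1 + \left(\frac{A/10^{\log K_A} + 1}{10^{\log R}\,A}\right)^n},$$

where $A$ is the molar agonist concentration, $E_m$, $Basal$ and $n$ are
system parameters, $K_A$ the functional equilibrium dissociation constant,
and $R = \tau / K_A$ the *transduction coefficient* combining efficacy
($\tau$, receptor density over coupling constant) and affinity.  Fitting
this to each pathway separately (the **marginal** model) and normalising to
a reference ligand yields the familiar bias metric

$$\Delta\Delta\log R_{1-2} =
  (\log R_1 - \log R_1^{REF}) - (\log R_2 - \log R_2^{REF}),$$

whose standard error is propagated as the root-sum-of-squares of the four
component standard errors.

Treating pathways as independent discards information: the receptor
conformations are linked, and in particular a ligand's half-maximal
concentrations across pathways are naturally correlated.  The **intact**
model implements that linkage by giving each ligand a single *apparent*
dissociation constant shared by all of its pathways,
$K_A' = 1/\sum_i K_{A_i}^{-1}$ (proportional to the harmonic mean of the
per-pathway constants), while keeping pathway-specific transduction
coefficients.  All pathways are then fitted **jointly**, and — after
rewriting the second pathway's coefficient as
$\log R_2 = \log R_1 - \log R_1^{REF} + \log R_2^{REF} -
\Delta\Delta\log R_{1-2}$ — the bias metric becomes a directly estimated
parameter with a model-based standard error, avoiding the error propagation
of the post hoc route.

This package implements both models (plus opposing inhibitory/stimulatory
variants for biphasic readouts such as Gi/Gs-modulated cAMP at two
receptor-expression levels), joint maximum-likelihood estimation, Wald-based
bias testing with Bonferroni correction, and a stochastic
simulation–estimation (SSE) engine that calibrates the Wald cutoff for a
nominal type-I error rate and traces empirical power curves.

## Estimation machinery

Observations are modelled as independent Gaussians around the model
prediction $f$ with combined additive + proportional variance
$v = \sigma_{add}^2 + (\sigma_{prop} f)^2$, the standard residual-error
model of pharmacometric practice.  The objective is

$$\mathrm{OFV}(\theta) = \sum_i \left[ \frac{(y_i - f_i)^2}{v_i} +
  \log v_i \right],$$

i.e. $-2\log L$ without the constant $n\log 2\pi$, so only OFV
*differences* between models on the same data are meaningful.  Both error
SDs are estimated per pathway by default (they can be fixed).

Minimisation uses multistart `nlminb` with box constraints.  The first
start is data-driven: baseline and maximum from per-concentration means, a
per-curve log C50 from a midpoint-crossing scan, $\log R \leftarrow -\log
C_{50}$ (exact for a full agonist), $\log K_A$ (or $\log K_A'$) from the
least-potent curve's C50, which upper-bounds the dissociation constant
since $C_{50} = K_A/(\tau+1)$.  Remaining starts are jittered copies
(SD 0.5 on the optimiser scale, seed-controlled).  $E_m$, $\sigma_{add}$
and $\sigma_{prop}$ are optimised on the log scale for positivity,
$Basal$ on the natural scale (it may legitimately be 0 and is fixable),
and all log-affinity/transduction parameters are bounded to $[-15, 15]$.
Ties between starts ($\Delta\mathrm{OFV} < 10^{-6}$) go to the smaller
parameter norm.  When the returned status is "singular" or "false
convergence" — which for these ill-conditioned likelihoods usually flags a
flat approach direction rather than a failure — the fit is accepted only
if a restart does not improve it and the scaled gradient is numerically
zero; the decisive test is always the covariance step below.

Standard errors come from the inverse of the numerically evaluated
(central-difference) Hessian of $\tfrac12\mathrm{OFV}$ at the optimum — the
observed Fisher information — on the reported (natural) scale.  A fit is
`converged` only if the optimiser succeeded *and* this Hessian is positive
definite; otherwise standard errors are reported as unavailable.  We
verified on the null-calibration design that the sandwich covariance
$H^{-1} S H^{-1}$ gives materially identical Wald quantiles, so the plain
observed information is used throughout.

The marginal model's likelihood separates by pathway, so multi-pathway
marginal fits are performed pathway by pathway and reassembled with a
block-diagonal covariance; this matches how the marginal analysis is done
in practice and makes the post hoc independence assumption exact.

### Identifiability conventions

A full agonist's dissociation constant cannot be identified from a
functional concentration–response curve: its transduction coefficient
absorbs the potency.  `apply_identifiability_conventions()` therefore
fixes `logka` of each pathway's most efficacious ligand to 0 in the
marginal model (the field convention), treating a top ligand plateauing
below 90% of the system maximum as partial (nothing fixed, warning).  The
same degeneracy afflicts the intact model's shared $\log K_A'$ exactly when
a ligand is a full agonist in *every* pathway — any partial-agonist pathway
pins the shared constant down — so the convention extends to fixing that
ligand's `logkap` to 0.  This is a package design choice for a case the
conventional treatment leaves open; without it the null-calibration fits
carry an exactly flat likelihood direction and the covariance step fails in
a large fraction of replicates.

## The simulation–estimation engine

`simulation_design()` encodes the reference study conditions used for
calibration and power: log10 molar concentrations $-11$ to $-4$ in steps of
1, three replicates, two ligands $\times$ two pathways (twelve curves, 96
observations per pseudo-experiment), $E_m = 100$, $Basal = 10$, unit Hill
slope in the truth, reference $\log R = 7/7$ with $\log K_A' = -5$
($\tau = 100$, a full agonist), test $\log R_2 = 6$ with $\log K_A' = -6$
($\tau = 1$, a partial agonist), additive SD 5 and proportional SD 10% per
pathway.  The true bias enters as test $\log R_1 = 6 + \Delta\Delta\log R$.
Simulated responses are never truncated at zero.

`calibrate_cutoff()` simulates under the null, fits the candidate model,
and takes the empirical 95th percentile (linear-interpolation quantile —
the convention matters in the third decimal for the 95th of 1000) of the
converged Wald statistics.  Non-converged replicates are excluded and
counted; more than 20% aborts the calibration.  `power_at()` and
`power_curve()` repeat this under alternatives and report the fraction of
Wald statistics above the calibrated cutoff, with binomial Monte-Carlo
standard errors.  A `chisq-oracle` engine bypasses fitting and draws Wald
statistics from $\chi^2_1$ directly, validating the percentile machinery
against the theoretical 3.841 criterion.

Candidate-model conventions during SSE are a genuinely open design area,
and they move the calibrated cutoffs: we estimate $E_m$, $Basal$, both
Hill slopes and both error SDs, fix the full agonist's dissociation
constant by the convention above, and initialise from the data-driven
heuristic with a jittered-restart rescue for non-converged replicates.
Estimating the Hill slopes (rather than fixing them at the generating
value 1) follows from the candidate model being the *general* operational
form, whose slopes are not known to the analyst; fixing them at 1 produced
an intact-model cutoff indistinguishable from the marginal one, while
estimating them reproduces the characteristic inflation of the
direct-intact Wald tail.  Under these conventions the marginal cutoff
lands slightly below the theoretical 3.84 (the root-sum-of-squares
propagation ignores the positive within-pathway covariance of the logR
estimates and is mildly conservative) and the intact cutoff lands well
above it (maximum-likelihood variance components and the many jointly
estimated parameters make the model-based SE of the directly estimated
bias metric slightly anticonservative) — the qualitative pattern the
method is known for.  We also evaluated fixing the slopes, initialising at
the design truth, estimating the full agonist's $\log K_A'$ freely (with
either strict or pseudo-inverse covariance), and sandwich standard errors:
the intact 95th percentile stays in the 4.5–4.8 range in all variants, so
the reported cutoffs are robust to these choices rather than artifacts of
one of them.

Reproducibility: every stochastic routine takes one master seed and fans
it out through counter-based child seeds (one stream per
calibration/power point, one child per replicate), so identical inputs
give bit-identical datasets, cutoffs and power values regardless of
execution order.

### Problem sizes

The packaged tests run the calibration batches at 200 null replicates per
model, power spot-checks at 100 replicates per point, and the
power-dominance grid at 50 replicates per point, with stochastic
tolerances widened by $\sqrt{1000/n_{sim}}$ relative to full replication.
The acceptance script (`scripts/acceptance.R`) runs the full study: 1000
null replicates per candidate model for the cutoffs and at least 300
replicates for the power point at $\Delta\Delta\log R = 0.5$.

## What the synthetic data do and do not emulate

The generator draws from exactly the model family being fitted, with
independent combined-error noise — that is the point of a calibration
study, but it means passing tests certify the *statistical machinery*, not
robustness to real-data pathologies: no plate effects, no shared-well
correlation, no normalisation error, no model misspecification beyond
marginal-vs-intact, no non-equilibrium kinetics.  The two "shape" fixtures
emulate published systems at the level of their fitted parameter values —
an opposing Gi/Gs system whose high-expression curve is U-shaped
(inhibition dominating at low receptor density, stimulation overtaking at
10-fold higher density, both pathway terms sharing one basal level and
shifting by $\log_{10} 10 = 1$ on the logR scale), and a five-ligand,
two-pathway serotonin-receptor panel with a strongly biased ligand
(truth $\Delta\Delta\log R = -0.476$) — but they are synthetic: the
original experimental data were digitised from figures and are not
reproduced here, so the corresponding published estimate tables are
checked only at the level of curve shape and joint-fit convergence, not
numerically.

## Numerical choices and degenerate inputs

* $A = 0$ (blank wells) evaluates to the analytic limit $Basal$; no
  division by zero ever occurs on grids that include a blank.
* Concentrations are molar and all logarithms are base 10.
* `ka_prime()` accepts $k \ge 2$ pathways (the derivation generalises to
  any number of active states); the result never exceeds the smallest
  input.  $\Delta\Delta\log R$ remains pairwise.
* $\tau$, $R_t$ and $K_E$ are never independent parameters — only $\log R$
  (and the receptor-density log-shift) are estimable; $\tau$ is exposed as
  the derived quantity `tau_from(log_r, log_ka)`.
* Inhibitory responses are modelled by *subtracting* an operational term
  (opposing variants) rather than allowing $E_m < Basal$.
* If both error components could vanish, the additive SD is floored at
  $10^{-8}$ response units to keep the likelihood defined.
* The unit-scaling invariance (concentrations $\times 10$ with
  $\log K_A + 1$, $\log R - 1$) leaves every prediction and the OFV
  unchanged; it is enforced in the tests.

## Known limitations

* The shared $K_A'$ caps how far apart two pathways' C50 values can sit
  for a ligand that is partial in both; a ligand needing genuinely
  distinct functional affinities (e.g. assays run under conditions that
  break the pathway linkage) is better served by the marginal model.
  `c50_numeric()` is provided as a diagnostic for exploring this
  separation; the package deliberately asserts no specific bound (a
  ~100-fold limit has been reported for non-unity slopes, but it is not
  derivable from the model equations alone, so we do not hard-code it).
* Only fixed-effects (naive-pooled) estimation is provided: no
  mixed-effects, Bayesian or profile-likelihood machinery.
* The Wald test is the only bias test; likelihood-ratio and score
  alternatives are natural extensions.
* Published five-ligand analyses report some post hoc rows whose printed
  significance calls cannot be reconstructed from the printed logR values;
  the package reproduces only the self-consistent arithmetic and leaves
  such rows to the reader.
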
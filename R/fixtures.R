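#' Generate a synthetic fixture dataset with a truth sidecar
#'
#' Four kinds of fully synthetic datasets used for demonstration and
#' testing:
#' \describe{
#'   \item{`table1_null`}{The two-ligand, two-pathway null calibration
#'     design (96 observations, true bias 0); see [simulation_design()].}
#'   \item{`table2_power`}{The same design with a non-zero true bias
#'     (`dd_logr`, default 0.5).}
#'   \item{`example1_shape`}{A single-ligand opposing Gi/Gs system measured
#'     at two receptor-expression levels, emulating the shape of published
#'     adenylate-cyclase data (dominant inhibition at low expression; a
#'     U-shaped biphasic curve at 10-fold higher expression).  The `pathway`
#'     column holds the expression level.}
#'   \item{`example2_shape`}{Five ligands (BUF reference, DOI, LSD, QUI,
#'     TFMPP) in two pathways (IP accumulation, AA release), with generating
#'     parameters emulating a published 5-HT2C study; e.g. DOI has true bias
#'     -0.476.  These fixtures emulate the published curve shapes with
#'     synthetic noise; they are not digitised experimental data.}
#' }
#'
#' @param kind Fixture kind.
#' @param seed Integer seed for the noise draws.
#' @param dd_logr True bias for `table2_power`.
#' @return A [bias_dataset()]; the generating parameters and seed are in the
#'   `"truth"` attribute.
#' @export
make_fixture <- function(kind = c("table1_null", "table2_power",
                                  "example1_shape", "example2_shape"),
                         seed = 1L, dd_logr = 0.5) {
  kind <- match.arg(kind)
  switch(kind,
    table1_null = {
      ds <- simulate_dataset(simulation_design(), dd_logr = 0, seed = seed)
      attr(ds, "truth")$kind <- kind
      ds
    },
    table2_power = {
      ds <- simulate_dataset(simulation_design(), dd_logr = dd_logr,
                             seed = seed)
      attr(ds, "truth")$kind <- kind
      ds
    },
    example1_shape = fixture_opposing(seed),
    example2_shape = fixture_five_ligand(seed))
}

## Opposing Gi/Gs system at two expression levels.  The generating values
## give a monotone-decreasing curve at low expression and a U-shaped
## (decrease, then rise) curve at 10x expression.
fixture_opposing <- function(seed) {
  spec <- opposing_spec(basal = 103, em_i = 49.2, n_i = 1.47,
                        em_s = 59.2, n_s = 2.27, log_ka_prime = -5.32,
                        log_r_i_low = 6.90, pref_i_s = 2.28,
                        density_log_shift = 1)
  grid <- expand.grid(replicate = 1:3, log_conc = seq(-10, -3, by = 0.5),
                      pathway = c("low", "high"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  f <- numeric(nrow(grid))
  for (lev in c("low", "high")) {
    m <- grid$pathway == lev
    f[m] <- opposing_response(10^grid$log_conc[m], lev, spec, "intact")
  }
  add <- 3; prop <- 0.03
  y <- withr::with_seed(seed,
         f + stats::rnorm(nrow(grid)) * sqrt(add^2 + (prop * f)^2))
  ds <- bias_dataset(data.frame(ligand = "UK14304-like", pathway = grid$pathway,
                                conc = 10^grid$log_conc,
                                replicate = grid$replicate, response = y,
                                stringsAsFactors = FALSE))
  attr(ds, "truth") <- list(kind = "example1_shape", spec = spec,
                            add_sd = add, prop_sd = prop, seed = seed)
  ds
}

## Five 5-HT2C agonists x two pathways (1 = IP accumulation, 2 = AA
## release), intact-model truth.  Pathway-2 coefficients of the test
## ligands are materialised from the per-ligand true bias.
fixture_five_ligand <- function(seed) {
  ligands <- c("BUF", "DOI", "LSD", "QUI", "TFMPP")
  log_kap <- c(BUF = -6.05, DOI = -6.46, LSD = -7.77, QUI = -5.24,
               TFMPP = -5.97)
  log_r1 <- c(BUF = 6.50, DOI = 6.65, LSD = 7.31, QUI = 5.89, TFMPP = 6.37)
  dd <- c(BUF = 0, DOI = -0.476, LSD = -0.393, QUI = 0.167, TFMPP = 0.102)
  log_r2 <- implied_log_r2(log_r1, log_r1["BUF"], 6.11, dd)
  names(log_r2) <- ligands
  sys <- list("1" = system_params(102, 1.79, 1.53),
              "2" = system_params(126, 0, 0.80))
  grid <- expand.grid(replicate = 1:3, log_conc = -10:-4,
                      pathway = c("1", "2"), ligand = ligands,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lr <- ifelse(grid$pathway == "1", log_r1[grid$ligand], log_r2[grid$ligand])
  f <- numeric(nrow(grid))
  for (pp in c("1", "2")) {
    m <- grid$pathway == pp
    f[m] <- operational_response(10^grid$log_conc[m], sys[[pp]],
                                 log_ka = log_kap[grid$ligand[m]],
                                 log_r = lr[m])
  }
  add <- 3; prop <- 0.05
  y <- withr::with_seed(seed,
         f + stats::rnorm(nrow(grid)) * sqrt(add^2 + (prop * f)^2))
  ds <- bias_dataset(data.frame(ligand = grid$ligand, pathway = grid$pathway,
                                conc = 10^grid$log_conc,
                                replicate = grid$replicate, response = y,
                                stringsAsFactors = FALSE))
  attr(ds, "truth") <- list(kind = "example2_shape", system = sys,
                            log_ka_prime = log_kap, log_r1 = log_r1,
                            log_r2 = log_r2, dd_logr = dd,
                            reference = "BUF", add_sd = add, prop_sd = prop,
                            seed = seed)
  ds
}
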
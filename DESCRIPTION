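Package: operbias
Title: Quantifying GPCR Ligand Bias with Marginal and Intact Operational Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint maximum-likelihood fitting of multi-pathway
    concentration-response data with the Black-Leff operational model of
    agonism, in both its conventional per-pathway ("marginal") form and an
    "intact" form in which all signalling pathways share one apparent
    equilibrium dissociation constant and the ligand-bias metric
    (delta-delta-logR, the doubly normalised transduction-coefficient
    difference) is a directly estimated parameter.  Includes post hoc bias
    and ligand-preference calculations with error propagation, Wald tests
    with Bonferroni correction, opposing Gi/Gs pathway variants for biphasic
    responses at multiple receptor-expression levels, and a stochastic
    simulation-estimation engine that calibrates the Wald cutoff for a
    nominal type-I error rate and computes empirical power curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
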
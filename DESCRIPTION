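Package: growthrecovery
Title: Monte Carlo Parameter Recovery for Latent Growth and Change Score Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how well longitudinal models
    recover group-level (fixed) effects and individual differences as a
    function of the number of measurement waves. Generates cohorts whose
    latent growth factors carry exactly specified population moments, fits
    two-wave latent change score models and linear or quadratic latent curve
    models by normal-theory maximum likelihood (optionally with a
    simultaneously estimated external covariate and full-information handling
    of missing data), computes per-individual factor scores, and quantifies
    recovery with Pearson correlations and agreement intraclass correlations
    across many replications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
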
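Package: pollenFB
Title: Maize Pollen Dispersal Models with a Field-Border Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits distance-decay models of maize cross-pollination (CP) from
    per-cob CP grain counts. Eight dispersal models combine a Poisson or
    zero-inflated Poisson observation model with a compound-exponential or
    modified-Cauchy dispersal kernel, each with or without an explicit
    field-border (FB) effect for small-scale farming systems where donor and
    recipient plots are separated by an unplanted strip. Provides
    maximum-likelihood estimation with multi-start optimisation, AIC/deviance/
    R-squared fit metrics, grouped threefold cross-validation, adaptive
    random-walk Metropolis sampling with DIC and posterior-predictive credible
    bands for the CP rate versus distance, zero-excess diagnostics, and a
    seeded synthetic field-experiment generator with layout presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
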
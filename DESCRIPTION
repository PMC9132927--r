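Package: mixadd
Title: Additivity Models for Predicting Chemical Mixture Toxicity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the toxicity of chemical mixtures from the dose-response
    curves (DRCs) of their components using four additivity models:
    concentration addition (CA), independent action (IA), generalized
    concentration addition (GCA) for mixtures containing partial agonists,
    and a structure-based two-stage prediction (TSP) that clusters
    components into putative mode-of-action groups (descriptors, PCA,
    k-means; ECFP6 Tanimoto rule for binary mixtures), applies CA within
    groups and IA across groups. A Simple-CA fallback estimates a mixture
    EC50 from component summary endpoints alone. Includes a registry of 13
    monotone DRC regression models with closed-form inverses, nonlinear
    least-squares fitting, concentration unit inter-conversion (nM, uM, mM,
    ug/L, mg/L), automatic determination of the predictable effect range,
    effect-grid reports with bootstrap confidence intervals, delimited-text
    mixture templates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    cluster,
    minpack.lm,
    jsonlite,
    optparse,
    ChemmineR,
    ChemmineOB
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
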
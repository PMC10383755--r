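Package: depotpk
Title: Pharmacokinetic Analysis of Long-Acting Injectable Depot Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for plasma concentration-time data from
    long-acting injectable depot formulations exhibiting flip-flop
    pharmacokinetics. Provides the closed-form one-compartment disposition
    model with first-order depot-release input (Bateman function), per-animal
    noncompartmental analysis (Cmax, Tmax, Cmin, trapezoidal AUC) with
    lower-limit-of-quantification censoring, naive-pooled nonlinear
    least-squares estimation of apparent clearance, volume and depot-release
    rate with linearized percent relative standard errors, exact one-sided
    Mann-Whitney-Wilcoxon tests with Bonferroni correction for viral-load
    group comparisons under detection-limit censoring, and a synthetic-data
    generator reproducing multi-species intramuscular depot study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
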
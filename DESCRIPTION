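Package: rlwmlba
Title: Reinforcement Learning and Working Memory Modelling of Choice and
    Response Time by Linear Ballistic Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and fits a hybrid reinforcement-learning/working-memory
    (RLWM) model of stimulus-response learning whose action policy is
    transformed, via a Shannon-entropy uncertainty scaling, into drift rates of
    a three-alternative linear ballistic accumulator (LBA), yielding a joint
    likelihood for choices and response times. Supports a neurally informed
    variant in which a trial-wise EEG centro-parietal positivity (CPP) slope
    regresses onto the drift-rate scaling parameter, empirical-Bayes MAP
    fitting with Laplace posterior draws, and PSIS-LOO / WAIC model comparison
    by expected log predictive density. Includes a synthetic-data generator
    for the adaptive stimulus-response association task and for epoched EEG
    with drift-locked ramp components, plus single-trial mass-univariate ERP
    regression with 20% trimmed-mean group statistics, Bonferroni correction,
    corrected-ERP reconstruction, CPP-slope extraction, and quartile-based
    slope regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    sandwich,
    metafor
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
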
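Package: socialddm
Title: Drift-Diffusion Modelling of Charity Choice Under Ingroup and
    Outgroup Social Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-alternative charity-choice experiments in
    which both ingroup and outgroup donor counts are shown on every trial.
    Implements the two-boundary Wiener first-passage-time density (with
    across-trial drift variability), a 294-stimulus joint-evaluation design in
    three difficulty types, five trial-information codings that inform a
    linear drift decomposition, per-subject maximum-likelihood fitting of a
    51-model space with BIC selection, behavioural summaries, an
    ingroup-driven versus equality-driven strategy classifier, quantile
    goodness-of-fit diagnostics, a sensitivity power computation, and a
    synthetic-cohort generator for parameter- and selection-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
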
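Package: ppimeta
Title: Meta-Analysis of Positive Psychology Interventions with
    Small-Study-Bias Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for random-effects meta-analysis of intervention effects
    reported on the correlation scale, built around the replication of two
    published meta-analyses of positive psychology interventions (PPIs).
    Includes an effect-size engine converting reported summary statistics
    (means/SDs, F, t, p, Cohen's d, pre-post change scores) to d and r;
    Schmidt-Hunter composite aggregation of correlated within-study outcomes
    and of multiple intervention arms sharing a control group;
    DerSimonian-Laird random-effects pooling on the Fisher-z scale with
    Cochran's Q and I-squared; small-study-effect diagnostics and adjusted
    estimation (classical Egger regression, Duval-Tweedie trim-and-fill,
    cumulative meta-analysis, TOP10, and limit meta-analysis); interquartile
    range and deleted-residual outlier identification with sensitivity
    re-analysis; and a synthetic-data generator with a
    selection-for-significance mechanism for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
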
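Package: primingmeta
Title: Publication-Bias-Aware Meta-Analysis of Goal Priming Field Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-effects meta-analysis and a battery of publication-bias
    diagnostics and corrections for small literatures of two-group field
    experiments, applied to the 13 published field studies of achievement-goal
    priming on workplace performance. Implements REML random-effects pooling
    with heterogeneity statistics, Egger-type funnel asymmetry regression with
    the PET, PEESE and conditional PET-PEESE corrected estimators, the
    Vevea-Hedges three-parameter selection model, Duval-Tweedie trim-and-fill,
    p-curve and p-uniform estimation from the significant subset, noncentral-t
    power analysis, a synthetic-literature simulator with selective publication
    and questionable-research-practice operators, and a sensitivity pipeline
    that gates estimators on worst-case false-positive rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), metafor, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
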
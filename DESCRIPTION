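Package: swdecomp
Title: Wealth Inequality in Child Severe Wasting: Risk Differences and
    Blinder-Oaxaca Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing poor versus non-poor inequality in severe
    wasting among under-five children from household survey microdata.
    Builds asset-based wealth indices and neighbourhood socioeconomic
    disadvantage scores by principal components, computes weight-for-height
    z-scores from LMS growth references and flags severe wasting, estimates
    survey-weighted prevalences and per-country poor/non-poor risk
    differences with cluster-robust inference, pools risk differences by
    DerSimonian-Laird random-effects meta-analysis, and decomposes the
    poor/non-poor outcome gap with threefold and twofold Blinder-Oaxaca
    decompositions (identity and logit links, per-covariate detail via Yun
    weights, cluster-bootstrap uncertainty). A synthetic multi-country
    survey generator with analytically known decomposition ground truth
    supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    metafor,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
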
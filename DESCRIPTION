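Package: choltrends
Title: Hierarchical Bayesian Estimation of Population Cholesterol Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating national, regional and global trends in mean
    total, non-HDL and HDL cholesterol from heterogeneous population surveys.
    Implements record-level plausibility cleaning, survey-weighted stratum
    summaries, adjustment of means measured on range-restricted portable
    devices via BIC-selected conversion regressions, a Bayesian hierarchical
    model with linear trends and second-order random-walk smoothing over a
    country-region-super-region hierarchy, age-standardization and
    population-weighted aggregation, hold-out predictive-validity testing,
    and attributable-mortality computation for ischaemic heart disease and
    ischaemic stroke. A synthetic-world generator with known ground truth
    makes every stage testable without access to survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
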
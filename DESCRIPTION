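Package: concindex
Title: Concentration Index and Wagstaff Decomposition for Household
    Budget-Share Outcomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure and explain socioeconomic inequality in
    household budget-share outcomes such as the share of the monthly budget
    spent on tobacco. Builds an asset-based wealth index by principal
    component analysis, assigns socioeconomic quintiles and fractional
    ranks, computes concentration curves and the convenient-regression
    concentration index with heteroskedasticity-robust confidence
    intervals, performs subgroup analyses, and decomposes the index into
    covariate contributions (elasticity times covariate concentration
    index plus a residual). Includes a synthetic household
    income-expenditure survey generator with a known ground-truth
    inequality level so the full pipeline can be exercised and validated
    without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    sandwich,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
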
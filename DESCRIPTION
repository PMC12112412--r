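Package: yieldstab
Title: Temporal Yield Stability Analysis for Long-Term Experiments and Crop Model Outputs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing temporal yield stability of agronomic
    treatments from long-term field experiments (LTEs) and from crop-model
    output. Implements the Taylor power-law adjusted coefficient of
    variation, the sustainable yield index, and Finlay-Wilkinson
    regression; model-evaluation statistics (RMSE, MAE, Willmott's index
    of agreement, Welch's test); Lin's concordance correlation for
    observed-versus-predicted stability agreement; and variance-based
    global sensitivity analysis (Sobol'/LP-tau designs with Saltelli
    main- and total-effect estimators). Includes synthetic generators for
    LTE-like yield panels, daily weather series, and a toy crop-response
    function, plus a Blackman thermal-time utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
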
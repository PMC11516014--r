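Package: paleodem
Title: Multi-Proxy Archaeodemographic Time-Series Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring relative population dynamics from three
    independent archaeological proxies: radiocarbon dates (probabilistic
    calibration, summed probability distributions, bootstrap composite
    kernel density models with Monte Carlo exponential-null testing, and
    annualized growth rates), typologically dated artifact assemblages
    (aoristic sum time series), and pollen count records (PCA-based
    vegetation-openness scores aggregated to a regional grid). Includes
    cross-proxy statistics (detrending, binning, windowed Pearson
    correlation, lagged cross-correlation, SD-threshold event detection)
    and seeded synthetic-data generators for all three proxy classes so
    every pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
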
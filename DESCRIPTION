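Package: cropwater
Title: Gridded Crop Yield and Crop Water Productivity from Multi-Indicator
    Remote Sensing Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate 1-km crop yield and crop water productivity
    (CWP) rasters from 8-day composite remote-sensing indicator stacks
    (evapotranspiration, gross primary productivity, land-surface temperature,
    leaf area index) plus static soil texture. Implements phenology-windowed
    temporal aggregation, county-level zonal statistics, random-forest yield
    regression with an indicator-combination search, eddy-covariance
    energy-balance quality control with Bowen-ratio correction, CWP
    computation, and a validation suite (RMSE/rRMSE/MBE/adjusted R-squared,
    Global Moran's I on zonal residuals, multiplicative input-perturbation
    sensitivity analysis). Ships a synthetic-world generator with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
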
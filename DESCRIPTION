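Package: teanirs
Title: NIR Spectroscopy Chemometrics for Heavy Metals and Blend
    Authentication in Tea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and chemometric analysis of near-infrared (NIR)
    reflectance spectra of pure black, green, and red (Pu-erh) teas and
    their binary blends.  Provides a seeded generator of log(1/R) spectra
    on the 1100-2498 nm grid with linearly mixed heavy-metal chemistry
    (Al, Pb, As, Hg, Cu); WinISI-style spectral pretreatments (SNV, MSC,
    detrend, SNV-detrend, and 4-digit gap-segment derivative codes);
    modified partial least squares (MPLS) calibration with global-H and
    T-statistic outlier elimination, 4-group cross-validation and the
    full SEC/SECV/RPD/SEP validation statistics; and class modelling of
    pure teas versus blends (and blend-percentage classes) by SIMCA,
    OPLS-DA, and RMS-X residual classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
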
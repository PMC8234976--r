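Package: uvnitro
Title: Reagent-Free UV Spectroscopic Determination of Nitrate, Nitrite and
    Salinity in Seawater by Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multicomponent deconvolution of deep-UV (200-300 nm) absorbance
    spectra of seawater into nitrate, nitrite and salinity by partial least
    squares (PLS1/PLS2 via NIPALS), with leave-one-out cross-validated
    selection of the number of latent factors (PRESS/Q2 significance rule),
    interval-PLS wavelength-window screening and greedy boundary refinement,
    and correction for chromophoric dissolved organic matter (CDOM) by
    fitting its exponential absorption tail over 275-295 nm and subtracting
    the extrapolated background. A classical least squares (Beer-Lambert)
    baseline with a jointly fitted CDOM term is provided for comparison,
    together with model-evaluation statistics (RMSEP, R2, relative error,
    detection limit, relative standard deviation, spike recovery) and a
    Beer-Lambert forward simulator of seawater spectra for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
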
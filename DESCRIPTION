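Package: quatmix
Title: Multivariate Calibration of a Quaternary Drug/Impurity Mixture from UV-Vis Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric workflow for the simultaneous quantification of four
    severely spectrally overlapping analytes (two active drugs and two
    process-related impurities) from UV-Vis absorbance spectra. Provides a
    five-level four-factor calibration design, Beer-Lambert simulation of
    overlapping mixture spectra, principal component regression (PCR) and
    NIPALS partial least squares (PLS) with leave-one-out cross-validated
    latent-variable selection, multivariate curve resolution by alternating
    least squares (MCR-ALS) with non-negativity, unimodality and correlation
    (inner calibration) constraints, a linear feed-forward network trained by
    Levenberg-Marquardt, and a validation-statistics layer (recovery/RSD
    summaries, Dixon Q outlier rejection, regression diagnostics, elliptical
    joint confidence regions, t/F comparisons, titration equivalence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
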
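Package: atmcorr
Title: Atmospheric Absorption Correction for Infrared Spectra
Version: 0.1.0
Authors@R:
    person("atmcorr", "developers", email = "atmcorr@example.org",
           role = c("aut", "cre"))
Description: Removes fluctuating water-vapor and carbon-dioxide absorption
    features from sequences of FTIR absorbance spectra using only two
    sequentially recorded sample spectra. The difference of successive
    spectra, scaled by a factor chosen to minimize the point-to-point
    spectral length of the corrected region, is subtracted from the
    spectrum to be corrected. Includes a relative-standard-deviation
    efficacy metric across replicate series, a synthetic FTIR scene
    simulator for validation without instrument data, Savitzky-Golay
    second-derivative preprocessing, partial least-squares regression
    with PRESS F-test latent-variable selection, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
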
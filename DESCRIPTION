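Package: grasspec
Title: Grassland Aboveground Biomass Estimation from Field Spectrometer Data
Version: 0.1.0
Authors@R:
    person("GEOINCA", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemometric pipeline for estimating grassland aboveground
    biomass (total, green fraction, and percent green) from canopy
    reflectance spectra measured with a field spectroradiometer
    (350-2500 nm). Implements spectral pre-processing transformations
    (standard normal variate, multiplicative scatter correction,
    de-trending, Norris gap derivatives, normalisations, baseline offset,
    reflectance-to-absorbance), continuum removal over five absorption
    zones with the maximum band depth (MBD) and area over the minimum
    (AOM) indices, and partial least squares (NIPALS), ordinary least
    squares and linear epsilon-insensitive support vector regression
    under leave-one-out cross-validation with a 2 percent parsimony rule.
    A synthetic canopy-reflectance generator with biomass-linked
    absorption features makes the full model grid testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
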
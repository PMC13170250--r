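Package: photonheat
Title: Monte Carlo Photon Transport and Photothermal Heating in
    Nanoparticle-Loaded Turbid Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates scattering-absorption coupled photothermal heating in
    nanoparticle-loaded turbid media. Converts particle loadings (pM, volume
    percent, mass concentration) into effective bulk optical coefficients,
    runs Monte Carlo photon-packet transport through cylindrical phantoms
    with Henyey-Greenstein scattering, Fresnel boundaries and a track-length
    fluence estimator, and derives photon-density and absorption enhancement
    maps, depth profiles, transient temperature traces at virtual
    thermocouples (axisymmetric implicit conduction solver plus a lumped
    heat-balance model), synergy coefficients, sigmoidal dose-response LD50
    fits with fold-reduction, and one-at-a-time optical-parameter
    sensitivity scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
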
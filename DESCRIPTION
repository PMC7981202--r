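Package: epivox
Title: Voxel-Based Simulation of Vascular Epiphyte Community Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based model of vascular epiphyte communities in
    three-dimensional forest canopies. Yearly 1-m3 voxel grids of light,
    arboreal substrate area and substrate loss -- derived from a built-in
    synthetic forest demographic generator or supplied externally -- drive
    dispersal, recruitment, von Bertalanffy growth and four mortality
    channels (light niche, space competition, dislodgement, quarter-power
    metabolic) of individual epiphytes. Includes correlated trait sampling
    with a viability screen, a calibration grid, scenario presets for forest
    turnover, selective logging and fragment-size experiments, and community
    summary statistics (saturation, rank abundance, vertical structure,
    mortality decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    ncdf4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
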
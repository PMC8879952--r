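Package: cin2d
Title: Membrane-Interaction Screening of 2D Nanomaterials from Steered-Pulling Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates potential-of-mean-force profiles from steered-pulling
    work curves (bidirectional averaging or the Jarzynski exponential
    estimator), derives adsorption free energies of lipid head and tail
    moieties and the membrane lipid-extraction barrier, computes the CIN2D
    indicator of nanotoxicity for two-dimensional nanomaterials, classifies
    materials into four membrane-interaction regimes, and draws the
    corresponding phase diagram. Ships a one-dimensional overdamped Langevin
    pulling simulator for generating synthetic work curves with known
    ground-truth landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
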
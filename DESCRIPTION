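Package: photoheat
Title: Photothermal Therapy Simulation for Nanoparticle-Loaded Skin Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates laser photothermal therapy of a squamous cell carcinoma
    embedded in a layered skin model. Couples a Monte Carlo photon-packet
    transport engine (Henyey-Greenstein scattering, voxel traversal, Russian
    roulette) to an explicit finite-difference heat solver with harmonic-mean
    interface conductances, mixes gold-nanorod optical coefficients into the
    tumor medium, and scores treatment quality with banded thermal-damage
    metrics: the apoptosis retention ratio, the thermal hazard retention
    value, and their ratio, the effective apoptosis retention ratio. A sweep
    driver explores laser profile, radius ratio, power and nanoparticle
    volume fraction to locate optimal irradiation conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
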
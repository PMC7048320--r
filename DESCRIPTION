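Package: conjcode
Title: Conjunctive Population Codes: Reliability and Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Construction and analysis of conjunctive (nonlinear mixed
    selectivity) population codes for multi-feature discrete stimuli. Builds
    order-O codebooks over K-feature stimulus grids, derives closed-form code
    geometry (population size, representation energy, minimum distance,
    distance spectra, neighbor counts), applies energy-rescaling linear
    transforms, simulates transmission through Gaussian and Poisson noisy
    channels with maximum-likelihood decoding, and evaluates codes with
    union-bound error estimates, metabolic total-energy budgets,
    receptive-field generalizations (discrete and continuous), mutual
    information, and the rate-distortion bound.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
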
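Package: daovns
Title: Direct Aperture Optimisation for IMRT with Variable Neighbourhood Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for direct aperture optimisation (DAO) in intensity-modulated
    radiation therapy planning. Jointly optimises multi-leaf-collimator aperture
    shapes (consecutive-ones leaf intervals) and their intensities with two variable
    neighbourhood search metaheuristics (variable neighbourhood descent and reduced
    variable neighbourhood search), and provides the classical sequential baseline
    (fluence map optimisation, intensity rounding, unidirectional sweep sequencing).
    Includes a synthetic prostate-like phantom with a pencil-beam dose-deposition
    model, clinical dose-volume indicators (DVH, Dx, Vx, homogeneity index), and
    tidy comparison reports of objective value, aperture count and beam-on time.
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
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
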
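Package: triloop
Title: Stability, Oscillations and Model Discrimination for Three-Variable
    Negative-Feedback Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a generic three-variable biochemical negative-feedback
    model with a sensor, a mass-conserved transducer and an integrating
    response component. Supports input-inhibition and output-activation
    feedback wiring, nested autoinhibitory feedbacks, equilibrium computation
    and steady-state parametrization, Hurwitz coefficients and Hopf
    bifurcation detection, bifurcation curves and two-parameter stability
    region maps, enumeration of candidate model families for the yeast
    high-osmolarity glycerol (HOG) pathway and the mammalian p53-Mdm2 loop,
    weighted least-squares fitting by evolutionary programming with AICc and
    Akaike-weight ranking, Monte-Carlo steady-state robustness analysis, and
    generators for synthetic HOG-like and p53-like time-series datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    ggplot2,
    generics,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
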
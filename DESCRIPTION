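Package: agepath
Title: Biological Aging, Multimorbidity Trajectories and Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking biomarker-based biological age to
    physical-psychological-cognitive multimorbidity and mortality.  Computes
    Klemera-Doubal (KDM-BA) and phenotypic age (PhenoAge) scores and their
    aging-acceleration residuals; classifies none/single/dual/triple
    multimorbidity states from disorder-domain onset dates; fits
    cross-sectional logistic and longitudinal Cox models with restricted
    cubic spline dose-response curves; estimates an interval-censored
    continuous-time multistate Markov illness-death model by maximum
    likelihood; and derives residual life expectancy and years of life lost
    from Royston-Parmar flexible parametric survival fits on the age
    timescale.  Includes a seeded synthetic cohort generator with a shared
    latent frailty so every stage is testable without access to restricted
    cohort data, plus three-strategy multiple imputation with Rubin pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    survival,
    flexsurv,
    MASS,
    generics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    expm,
    numDeriv,
    mvtnorm,
    knitr,
    rmarkdown
Config/testthat/edition: 3
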
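Package: testletr
Title: Hierarchical and Testlet Item Response Models for Lifetime OCD
    Symptom Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling lifetime obsessive-compulsive disorder
    (OCD) symptom data from 64-item symptom checklists and 10-item
    clinician severity ratings. Compares unidimensional, correlated
    five-factor, and hierarchical bifactor latent structures for binary
    symptom endorsements by quadrature-based marginal maximum likelihood;
    fits a Bayesian testlet (random-effect) item response model by
    Metropolis-within-Gibbs sampling with Gelman-Rubin convergence
    checking, yielding symptom-level discrimination and severity
    parameters and person-level OCD propensity scores with posterior
    standard errors; fits a graded response model to ordinal severity
    ratings with EAP scoring; and assesses agreement between the two
    scoring routes by rank correlation and Bland-Altman analysis scaled
    by joint posterior standard errors. A synthetic-data module generates
    checklist and severity data under bifactor/testlet structures so the
    full pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
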
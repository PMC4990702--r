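Package: beepersist
Title: Dynamic Occupancy Models Linking Wild-Bee Persistence to
    Neonicotinoid-Treated Oilseed Rape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating long-term wild-bee occurrence records to
    pesticide use on oilseed rape. Implements a foliar insecticide impact
    (FII) index built from the bee component of the Environmental Impact
    Quotient, assembly of per-grid-cell annual covariates (crop cover,
    neonicotinoid seed-treatment exposure, FII) from biennial survey
    panels, conversion of opportunistic occurrence records into a
    detection dataset with list-length effort categories, a multi-species
    dynamic Bayesian occupancy-detection model with forager/non-forager
    group-level priors fitted by a marginalised-likelihood MCMC sampler,
    counterfactual no-neonicotinoid occupancy projections, and a complete
    synthetic-data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
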
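Package: cptddm
Title: EZ Drift-Diffusion Modelling of Cued Continuous Performance Task Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing go/no-go performance on the cued continuous
    performance task (CPT-AX) with the EZ drift-diffusion model. Generates
    pseudorandomised 400-trial CPT-AX sessions, simulates trial-level
    responses for synthetic two-group cohorts via a Wiener first-passage
    diffusion process, scores hit rate, commission errors and response-time
    moments, estimates drift rate, boundary separation and nondecision time
    in closed form, checks goodness of fit with group-averaged supersubject
    simulation, and runs the inferential stage: Pillai-trace MANCOVA,
    age-partialed correlations, Fisher r-to-z comparison of independent
    correlations, hierarchical stepwise regression and forced-entry
    interaction regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
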
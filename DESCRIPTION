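Package: ddiprev
Title: Population-Scale Surveillance of Co-Administered Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects per-patient co-administration episodes of drug pairs in
    longitudinal dispensation records (daily or monthly resolution), computes
    pairwise co-administration statistics (directed conditional likelihoods and
    a normalized temporal-overlap strength), gender- and age-stratified
    prevalences of co-administration and of known drug-drug interactions with
    exact-test relative risks, an age-matched polypharmacy-preserving null
    model for the expected interaction prevalence, a significance-filtered
    drug-interaction network, and a counterfactual drug-substitution
    intervention that quantifies avoidable interaction burden. Includes a
    synthetic electronic-health-record generator so the full pipeline can be
    exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
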
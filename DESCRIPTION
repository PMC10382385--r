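Package: metannot
Title: Probabilistic Annotation of Untargeted LC-MS/MS Metabolomics Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Bayesian annotation engine for untargeted LC-MS/MS metabolomics.
    Assigns probabilities to putative metabolite annotations of MS1 features
    by combining mass accuracy, retention time, isotope-fingerprint and MS2
    spectral-similarity evidence into prior probabilities, then refines them
    into posterior probabilities with a Gibbs sampler over biochemical and
    adduct/in-source-fragment connection graphs. Includes feature clustering,
    isotopologue mapping, MS2-to-feature assignment, CSV/MGF/MSP readers and
    writers, a command-line pipeline driver, and a synthetic-data generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
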
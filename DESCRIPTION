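Package: dmlfm
Title: Disease-Metabolite Association Prediction with Similarity-Completed
    Latent Factor Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts disease-related metabolites by completing a sparse
    0-1 disease-metabolite association matrix with disease-similarity and
    literature-based metabolite-similarity fills combined as a noisy-OR,
    then factorizing the completed matrix with an L2-regularized latent
    factor model trained by stochastic gradient descent.  Includes a
    disease-vocabulary builder that maps free-text disease names to
    ontology accessions via MeSH cross-references and rule-based name
    normalization, data-increment and leave-one-out validation schemes
    with per-disease AUC scoring, ablation and SVD baselines, and a
    seeded synthetic-data generator emulating all external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
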
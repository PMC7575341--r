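Package: mindlang
Title: Language Surveillance of Online Mental-Health Support Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for tracking how language changes across
    online mental-health support communities around a disruptive event.
    Extracts 90 psycholinguistic text features (category lexicons, sentiment,
    surface counts, punctuation, readability) plus TF-IDF n-grams from
    timestamped post corpora; fits time-binned trend regressions with
    Benjamini-Hochberg control and a slope-times-R-squared change score;
    trains interpretable per-group linear classifiers against balanced
    controls; performs spectral clustering with rank-sum characteristic
    features and hypergeometric enrichment; fits Dirichlet-prior topic models
    with prevalence-shift tests; and tracks linguistic convergence between
    groups with supervised 2D embeddings and directed Hausdorff distances.
    Includes a synthetic corpus generator with planted, recoverable effects
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    e1071,
    ranger,
    xgboost,
    cluster,
    mclust,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
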
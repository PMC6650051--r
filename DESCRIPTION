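Package: string2go
Title: Protein Function Prediction from PPI Networks via Deep Maxout
    Functional Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting Gene Ontology biological-process
    annotations from weighted protein-protein interaction networks.
    Generates network embeddings by random walk with restart diffusion
    states plus truncated SVD (Mashup-style) or by second-order biased
    random walks plus skip-gram (node2vec-style), trains a deep maxout
    neural network against multi-label GO targets and extracts its third
    hidden layer as a functional representation, and trains per-term
    calibrated RBF support vector machines. Includes CAFA-style
    term-centric (F1, MCC, AUPRC) and protein-centric (Fmax, F-tau)
    evaluation, Naive and PPI-homolog baselines, hold-out / temporal /
    homolog-removal split construction, and a synthetic data generator
    with planted guilt-by-association structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
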
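Package: golsa
Title: Latent Semantic Prediction of Gene Ontology Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts novel gene function annotations from an existing
    Gene Ontology (GO) annotation corpus. Builds the unfolded and pruned
    binary gene-by-term annotation matrix from an OBO ontology and a GAF
    annotation file, optionally weights it with TF-IGF schemes (NTN, NTM,
    ATN), fits three latent models -- truncated-SVD latent semantic
    indexing, a semantically improved per-cluster variant (SIM), and a
    normalized probabilistic latent semantic analysis (pLSAnorm) -- and
    ranks unobserved gene-term pairs by their reconstructed score.
    Includes windowed ROC evaluation, old-versus-updated corpus
    comparison, and a seeded synthetic data generator with planted block
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
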
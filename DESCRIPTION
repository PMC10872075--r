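Package: drpfuse
Title: Multi-Modal Drug Response Prediction with Low-Rank Fusion and
    Graph Drug Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the response of cancer cell lines to small-molecule
    drugs, summarized as the area above the dose-response curve (AAC), from
    multiple molecular profiling data types (mutation, copy number,
    expression, proteomics, miRNA, metabolomics, histone marks, RPPA).
    Per-omic autoencoders compress profiles into latent vectors, a graph
    attention network encodes drug molecules from SMILES, and low-rank
    multimodal fusion combines the latents for a regression head trained
    with a weighted root-mean-squared-error loss.  Label distribution
    smoothing counteracts the heavy right-skew of drug-response labels,
    four leakage-free cross-validation schemes (by cell line, drug
    scaffold, both, or cancer type) measure generalization, and integrated
    gradients attribute predictions to omic features and drug atoms.  A
    synthetic cohort generator with a planted interaction signal makes the
    whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
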
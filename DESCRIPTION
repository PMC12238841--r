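Package: tcrbind
Title: Peptide-Holdout Prediction of TCR Recognition of Peptide-HLA-I
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curation, simulation and evaluation tools for predicting
    alpha/beta T-cell receptor (TCR) recognition of HLA class I presented
    peptides, with emphasis on peptides unseen during training. Provides
    AIRR-style binding-record standardization with inclusion/exclusion
    filters and HLA allele imputation, reconstitution of full variable-domain
    chain sequences from V/J/CDR3 minimal descriptions against a germline
    reference, 10x-style single-cell chain pairing and UMI-threshold binding
    calls, screened mispairing simulation of non-binders, leave-one-peptide-
    out cross-validation, a small disentangled-attention sequence encoder
    with masked-language-model pretraining and binary finetuning,
    random-model null calibration of per-peptide AUC, and train/test
    tractability features (CDR3beta distance, HLA allele counts, aligned
    BLOSUM62 peptide similarity). A synthetic-data generator makes every
    pipeline stage testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
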
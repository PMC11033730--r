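Package: oncorepurpose
Title: Anti-Cancer Drug Repurposing with Message-Passing Networks and
    Interaction-Derived Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for similarity-aware curation of anti-cancer
    activity labels from a drug catalogue, compression of drug-target and
    drug-drug interaction matrices into dense per-drug features (PCA and
    logistic adjacency factorization with neighbor propagation),
    Tanimoto-nearest-neighbor imputation of missing features, a directed
    bond message-passing neural classifier with auxiliary feature blocks
    (ensembled), fingerprint baselines, balanced Bemis-Murcko scaffold
    splitting with a five-metric evaluation suite, feature-ablation
    comparisons, and whole-library candidate ranking.  A synthetic
    benchmark generator with planted structure, target and interaction
    signal makes every stage testable without licensed databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
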
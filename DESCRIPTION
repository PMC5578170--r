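Package: dtiwave
Title: Drug-Target Interaction Prediction from Wavelet, Fingerprint, and
    Network Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) with a feature-vector
    classifier. Protein targets are encoded as six-channel physicochemical
    signals (hydrophobicity, side-chain volume, polarity, polarizability,
    solvent-accessible surface area, and net charge index) and compressed by a
    four-level discrete wavelet transform into band statistics plus leading
    discrete cosine transform coefficients. Drugs are encoded as 166-bit MACCS
    substructure fingerprints and each pair additionally carries its bipartite
    interaction-profile ("net") feature. Features are ranked by SVM recursive
    feature elimination with correlation bias reduction (SVM-RFE+CBR) and
    classified by an RBF-kernel support vector machine. Includes balanced and
    imbalanced cross-validation evaluation (ACC, sensitivity, specificity,
    AUC, AUPR), novel-pair ranking, and a synthetic benchmark generator with a
    planted interaction signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    ChemmineOB,
    pROC,
    yaml,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
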
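Package: toxIPS
Title: Integrative Multi-Organ Drug-Induced Toxicity Prediction from
    Gene-Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts drug-induced liver and kidney pathological findings
    from normalized gene-expression profiles. Each finding is scored by an
    ensemble of k-nearest-neighbour classifiers trained on jackknife samples
    (all cases plus a random control subset), yielding a pathology
    prediction score (PPS). The per-finding scores are then combined through
    row-normalized Jaccard co-occurrence similarities between findings into
    integrative prediction scores (IPS), so that strongly co-occurring
    pathologies reinforce each other. Includes drug-grouped cross-validation
    with geometric-mean threshold selection and ROC/AUC evaluation, and a
    latent-mechanism simulator that generates drug-grouped datasets with
    correlated finding co-occurrence and planted expression signatures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
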
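Package: hybridGO
Title: Hybrid Machine-Learning Annotation of Gene Ontology Terms from
    Multi-Omics and Knowledge Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains and evaluates binary Gene Ontology (GO) term
    classifiers for genes from a hybrid feature space: principal-component
    embeddings of a gene-by-sample expression matrix, Fisher-transformed
    Spearman correlations between gene expression and metabolite
    abundance, and one-hot encoded categorical knowledge scores (for
    example mitochondrial-localization or transporter predictions).
    Positive gene sets are built from annotation tables with evidence-code
    filtering; balanced negative sets are drawn by bootstrap resampling of
    unannotated genes, and models (random forest, decision tree, naive
    Bayes, probabilistic SVM) are scored by five-fold cross-validation
    with AUROC, AUPRC, precision, recall, accuracy, F1 and Matthews
    correlation. Per-gene probabilities from models with different numbers
    of principal-component features are combined into mean +/- standard
    error ensembles, and a multi-classifier probability gate nominates
    candidate genes. A synthetic-data module generates factor-model
    expression data with planted metabolite associations, noisy knowledge
    scores and GO-like labels so the whole pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    rpart,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
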
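# hybridGO

Hybrid machine-learning annotation of Gene Ontology (GO) terms from
multi-omics and knowledge features.

## What problem this solves

Sequence-based function predictors cannot condition on a biological
context. When the question is "which genes are plausibly involved in,
say, mitochondrial glutathione metabolism *in cancer cells*", the signal
lives in context-specific data: co-expression structure across a tumor
or cell-line compendium, correlation between a gene's expression and the
abundance of a metabolite of interest, and curated knowledge scores
(mitochondrial-localization catalogues, transporter predictors).
hybridGO trains binary GO-term classifiers on exactly this hybrid
feature space and is aimed at computational biologists nominating
candidate genes for follow-up experiments.

## The method in brief

Per gene $g$, the feature vector concatenates:

* the gene's scores on the first $p$ principal components of the
  (filtered, k-NN-imputed, per-gene z-scored) expression matrix, with
  $p \in \{5, 14, 30, 50\}$ defining four model variants;
* one Fisher-transformed Spearman correlation
  $z = \operatorname{arctanh}(\rho)$ per metabolite, zeroed when the
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ test gives $p \ge 0.05$;
* two one-hot columns encoding a categorical knowledge score in
  $\{1, 0, -1\}$ (positive / negative / no classification, the latter
  encoded implicitly as $(0,0)$).

Positives are genes annotated to the term with accepted (experimental)
evidence codes; negatives are drawn by balanced bootstrap sampling from
the unannotated pool (100 iterations by default). Each iteration is
scored by stratified 5-fold cross-validation (random forest, decision
tree, naive Bayes, or probabilistic SVM), metrics (AUROC, AUPRC,
precision, recall, accuracy, F1, MCC) are averaged across iterations,
and per-gene probabilities are combined across the PC variants as
mean ± SE. A feature-count-matched transcriptomics-only arm (e.g. 7 PCs
vs. 5 PCs + 2 knowledge columns) isolates the contribution of the
knowledge features. Candidates are nominated by a triple gate: mean
probability > 0.80 simultaneously in the mitochondrion, transporter and
target-term classifiers, with already-annotated genes fixed at 1.0.

A synthetic-data module generates factor-model expression data with
planted metabolite associations, noisy knowledge scores and GO-like
labels, so the entire pipeline is exercised end-to-end without any
external download. See the vignette
(`vignettes/hybrid-go-annotation.Rmd`) for the full model description
and design rationale.

## Worked example

```r
library(hybridGO)

ds <- generate_dataset(synthetic_config(
  n_genes = 400, n_samples = 60, n_positive = 50,
  signal_strength = 2, knowledge_accuracy = 0.9, seed = 1))
cfg <- run_config(pc_counts = c(5L, 14L), n_bootstrap = 20L, seed = 1L)
fit <- classify_term(ds$expression, ds$positives, cfg,
                     metabolites = ds$metabolites,
                     knowledge = ds$knowledge)
fit
#> GO-term classifier fit (random_forest, hybrid): 2 variants
#>   mean AUROC 0.9031  AUPRC 0.8999  MCC 0.6477

head(rank_by_probability(fit$predictions), 3)
#>   rank  gene_id mean_prob          se           label
#> 1    1 gene0086 0.9235294 0.031764706 0.9235 (0.0318)
#> 2    2 gene0166 0.9084375 0.028437500 0.9084 (0.0284)
#> 3    3 gene0209 0.8788235 0.005882353 0.8788 (0.0059)
```

The fit line reports the cross-validated metric battery averaged over
bootstrap iterations and PC variants: AUROC 0.90 says the classifier
ranks a random positive above a random negative 90% of the time on
held-out genes. The ranking table lists unlabeled genes by ensemble mean
probability with the standard error across PC variants — `gene0086` at
0.92 ± 0.03 is this run's top novel candidate. Feature importances
(`feature_importance()`) on the same run put the two knowledge columns
and PC1 at the top, mirroring the intended division of labour between
knowledge and co-expression signal.

A thin command-line front end with `simulate`, `preprocess`, `train`,
`evaluate` and `gate` subcommands is installed at
`system.file("cli", "hybridgo", package = "hybridGO")`; every run logs
its resolved configuration and master seed.

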
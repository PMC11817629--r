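---
title: "Hybrid GO-term annotation from multi-omics and knowledge features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid GO-term annotation from multi-omics and knowledge features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridGO)
```

## The problem

Most gene-function predictors work from protein sequence alone and cannot
condition on a biological context such as a disease state. hybridGO takes
the complementary route: it predicts whether a gene belongs to a Gene
Ontology (GO) term — say *mitochondrion*, *transmembrane transporter
activity*, or *glutathione metabolic process* — from how the gene behaves
in a particular expression compendium (for example a cancer cell-line
panel), combined with categorical scores from curated knowledge sources
(a mitochondrial-localization catalogue, a transporter predictor). The
classifiers are "hybrid" in the sense that each gene's feature vector
mixes data-driven features with knowledge-based ones.

## The feature model

For a gene $g$ measured over samples $s = 1 \dots n$ the feature vector
concatenates up to three blocks:

1. **Transcriptomic PC scores.** The expression matrix is filtered
   (samples, then genes, with more than `max_missing` = 30% missing values
   or zero variance removed), completed by $k$-nearest-neighbour
   imputation ($k = 5$, Euclidean distance over co-observed coordinates,
   rescaled by the fraction of usable coordinates), each gene row is
   z-scored across samples, and PCA is run with genes as observations.
   The gene's coordinates on the first $p$ components are its features,
   with $p \in \{5, 14, 30, 50\}$ by default. Each choice of $p$ defines
   one *model variant*.
2. **Metabolite-correlation features.** For each metabolite of interest,
   the Spearman rank correlation $\rho$ between the gene's expression and
   the metabolite's abundance over shared samples is tested with
   $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom;
   non-significant values ($p \ge \alpha$, $\alpha = 0.05$) are set to 0,
   and the survivor is variance-stabilized by the Fisher transform
   $z = \operatorname{arctanh}(\rho)$.
3. **Knowledge scores.** A categorical score in $\{1, 0, -1\}$ (positive,
   negative, or no classification) is one-hot encoded as two Boolean
   columns; the no-classification state is the implicit $(0, 0)$, so no
   third column is needed. Genes absent from the score table are treated
   as unclassified.

For every hybrid model a feature-count-matched *transcriptomics-only*
comparator replaces the extra columns with additional PCs (5 PCs + 2
knowledge columns vs. 7 PCs), so hybrid-vs-transcriptomics comparisons
are never confounded by model capacity.

## Labels, negatives, and the training regime

Positive genes are those annotated to the term with an accepted evidence
code. The default whitelist is the experimental and high-throughput GO
code families (EXP, IDA, IPI, IMP, IGI, IEP, HTP, HDA, HMP, HGI, HEP);
purely computational/inferred annotations (e.g. IEA) are excluded. For
sparsely annotated terms, the sequence-similarity family (ISS, ISO, ISA,
ISM) can be admitted per term.

Because "not annotated" is not a reliable negative label, negatives are
*sampled*: each bootstrap iteration draws, without replacement, as many
unannotated genes as there are positives, giving a balanced set. The
default regime is 100 bootstrap iterations × 5-fold stratified
cross-validation; every labeled gene receives exactly one out-of-fold
probability per iteration, and headline metrics are the mean of the
per-iteration metric values (the pooled-within-iteration values are also
available, and the two are reported distinctly). A leakage audit
(`audit_leakage()`) verifies that no out-of-fold prediction came from a
model whose training rows contained that gene.

Unlabeled genes are scored by models retrained on each bootstrap's full
balanced set; a gene's average skips any bootstrap in which it was itself
drawn as a negative. Per-gene probabilities are averaged within each PC
variant and then combined across variants as mean ± SE, with
$\mathrm{SE} = \mathrm{sd}(\text{variant means}) / \sqrt{\#\text{variants}}$.
Candidate genes are nominated by the **triple gate**: a gene passes only
if its mean probability is *strictly greater than* 0.80 in all three
classifiers (mitochondrion, transporter, target term), with genes already
annotated to a term assigned probability exactly 1.0 (SE 0, flagged) on
that axis.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_missing` | 0.30 | missing fraction above which a sample/gene is dropped |
| `knn_k` | 5 | neighbours for imputation |
| `alpha` | 0.05 | significance level for zeroing metabolite correlations |
| `pc_counts` | 5, 14, 30, 50 | PC features per model variant |
| `n_bootstrap` | 100 | negative-sampling iterations |
| `n_folds` | 5 | cross-validation folds |
| `confusion_threshold` | 0.75 | cutoff for confusion matrices (closed: $\ge$) |
| `gate_threshold` | 0.80 | candidate gate (open: $>$) |
| `confident_bounds` | 0.6 / 0.4 | band outside which a prediction counts as confident for inter-classifier agreement |
| `seed` | 1 | master seed; all per-bootstrap/per-fold seeds derive from it |

The differing strictness of the two thresholds (closed at 0.75 for
confusion matrices, open at 0.80 for the gate) is intentional: each
mirrors the convention of the analysis it supports.

## The synthetic-data generator

`generate_dataset()` emits data with exactly the statistical structure
the framework assumes, so the whole pipeline is testable without any
external download:

* **Expression** follows a latent factor model
  $X = L F + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$, with
  factor score standard deviations decaying geometrically
  (`factor_decay` = 0.7). The decay gives the scree profile seen in real
  expression data and separates the leading eigenvalues, which makes the
  principal axes identifiable — with i.i.d. factors the leading PCs are
  rotationally degenerate and no subsampling-stability property could
  even be stated.
* **Class signal**: positive genes have their loading on a signal factor
  shifted by `signal_strength`. The metabolite-associated fraction
  (`metabolite_assoc_frac`) carries its shift on factor 1, which also
  generates the metabolite rows (factor-1 scores plus noise); the
  remaining positives carry theirs on factor 2. Splitting the two
  subsets across factors keeps "associated with the metabolite" and
  "class-informative in PC space" as separable properties, so the
  association fraction is a real experimental knob rather than a label.
* **Knowledge scores** agree with the truth with probability
  `knowledge_accuracy`, are flipped otherwise (symmetric errors), and
  are unclassified ($-1$) with probability `1 - knowledge_coverage`.
* **Missingness** is completely at random at rate `missing_frac`.

Defaults (1000 genes × 100 samples, 5 factors, noise sd 1, 50 positives,
signal 2, accuracy 0.9, coverage 0.8, 5% missing) are a desk-scale
stand-in for a large cell-line compendium. What the generator does *not*
emulate: TPM/RSEM abundance distributions, batch and tissue structure,
informative missingness, or correlated knowledge-source errors. Passing
tests on synthetic data therefore demonstrate correctness of the
machinery and recoverability of planted signal under the stated model —
not performance on any particular real compendium.

## Numerical and design choices

* **Z-scoring axis.** Published descriptions of this kind of pipeline
  often just say "z-score normalized"; here rows (genes) are z-scored so
  PCs capture co-expression *pattern* rather than abundance scale, which
  matches using PC scores as per-gene features. (PCA itself then centers
  the sample-space columns, as usual.)
* **Spearman test df.** The t-approximation uses $n-2$ degrees of
  freedom, the standard choice. A fixed `df` argument exists for
  reproducing published analyses that state an unconventional value.
* **Ties** get average ranks (the conventional Spearman definition);
  $|\rho|$ is clamped to $1 - 10^{-12}$ before `arctanh` so perfectly
  monotone pairs stay finite.
* **k-NN distance** is nan-aware: squared differences are averaged over
  co-observed coordinates and rescaled to full dimension; if all $k$
  nearest rows are missing in the target column, the column mean is the
  logged fallback. Neighbour ties break by row order, deterministically.
* **PCA** uses the SVD (via `prcomp`) rather than an explicit covariance
  eigendecomposition, with a deterministic sign convention (largest
  loading positive). Component similarity uses $|\cos|$, so it is
  invariant to axis sign.
* **MCC** is defined as 0 when any confusion-table marginal is zero
  (constant predictors score 0, not NaN).
* **Agreement filter.** The 0.6/0.4 confidence filter for
  inter-classifier agreement requires confidence in *both* tables
  (intersection); requiring it in either table would let one confident
  classifier drag in genes the other is agnostic about, which inflates
  the correlation.
* **Determinism.** One master seed spawns per-bootstrap seeds, and each
  fold/full fit derives its seed from those, so any single bootstrap is
  reproducible in isolation and an identical configuration reproduces
  the prediction table byte for byte. All seeded code restores the
  caller's RNG state.

## Problem sizes used by the test-suite

The package's own calibration checks run at desk scale, chosen so the
statistical properties are sharp but the suite stays fast: null and
planted-signal pipelines use 400 genes × 60 samples with 50 positives and
20 bootstrap iterations (the planted-signal comparison is paired over 10
master seeds); gate calibration uses 10,000 genes; PC-robustness uses 600
genes × 60 samples with 3 factors and a 50% gene subsample. Oracle
equivalence (Spearman, Fisher z, MCC, AUROC, Pearson, k-NN imputation) is
checked against brute-force reimplementations on fixtures of at most 50
elements at $10^{-8}$ tolerance.

## A small worked run

```{r example, eval = FALSE}
ds <- generate_dataset(synthetic_config(
  n_genes = 400, n_samples = 60, n_positive = 50,
  signal_strength = 2, knowledge_accuracy = 0.9, seed = 1))
cfg <- run_config(pc_counts = c(5L, 14L), n_bootstrap = 20L, seed = 1L)
fit <- classify_term(ds$expression, ds$positives, cfg,
                     metabolites = ds$metabolites,
                     knowledge = ds$knowledge)
fit                       # mean AUROC/AUPRC/MCC across variants
head(rank_by_probability(fit$predictions))
```

## Known limitations

* Annotations are taken as given: there is no GO-graph propagation of
  ancestor terms, and no multiple-testing correction on the metabolite
  correlation p-values (a raw `alpha` cutoff is applied, matching common
  practice in this setting).
* Hyperparameters of the four classifier families are
  library-conventional defaults, overridable but not tuned; the
  package's claims concern the training *regime*, not tuned settings.
* The SVM wrapper's probabilities come from the underlying library's
  internal calibration and can be unstable on very small folds; the
  random forest is the recommended default, and is the best performer in
  the package's own comparisons on synthetic data.
* Negative sampling assumes unannotated genes are mostly true negatives;
  for very large terms this assumption weakens.
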
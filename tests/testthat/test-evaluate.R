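# Metric battery: oracle equivalence, threshold behaviour, TPR curves,
# feature importance and inter-classifier agreement.

test_that("AUROC matches exhaustive pair counting, ties included", {
  set.seed(51)
  for (rep in 1:5) {
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- round(runif(30), 2)       # rounding forces some ties
    r <- compute_metrics(probs, labels)
    expect_equal(r$auroc, oracle_auroc(probs, labels), tolerance = 1e-10)
  }
  # invariance under strictly monotone transforms
  labels <- c(1, 1, 0, 0, 1, 0, 1, 0)
  probs <- c(0.9, 0.8, 0.7, 0.3, 0.6, 0.2, 0.2, 0.9)
  a <- compute_metrics(probs, labels)$auroc
  b <- compute_metrics(plogis(5 * probs - 2), labels)$auroc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("perfect ranking scores 1 everywhere, MCC formula is exact", {
  labels <- rep(c(1, 0), each = 10)
  probs <- c(runif(10, 0.6, 1), runif(10, 0, 0.4))
  r <- compute_metrics(probs, labels, threshold = 0.5)
  expect_equal(r$auroc, 1)
  expect_equal(r$auprc, 1)
  expect_equal(r$mcc, 1)
  expect_equal(r$f1, 1)
  # direct formula evaluation on fixed counts
  expect_equal(oracle_mcc(50, 10, 10, 50), 2400 / 3600)
  probs2 <- c(rep(0.9, 50), rep(0.9, 10), rep(0.1, 10), rep(0.1, 50))
  labels2 <- c(rep(1, 50), rep(0, 10), rep(1, 10), rep(0, 50))
  r2 <- compute_metrics(probs2, labels2, threshold = 0.5)
  expect_equal(r2$mcc, 2400 / 3600, tolerance = 1e-12)
  expect_equal(r2$mcc, oracle_mcc(50, 10, 10, 50), tolerance = 1e-12)
})

test_that("MCC is 0 for constant predictors (zero-marginal convention)", {
  labels <- rep(c(1, 0), 10)
  r <- compute_metrics(rep(0.9, 20), labels, threshold = 0.5)
  expect_equal(r$mcc, 0)
  expect_error(compute_metrics(runif(5), rep(1, 5)), "both classes")
})

test_that("confusion counts match a hand count and sum to n", {
  probs <- c(0.9, 0.8, 0.76, 0.74, 0.5, 0.75, 0.2, 0.95, 0.6, 0.1)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  cm <- confusion_at(probs, labels, threshold = 0.75)
  expect_equal(cm, c(TP = 3L, FP = 2L, FN = 2L, TN = 3L))
  expect_equal(sum(cm), 10L)
  expect_equal(confusion_at(probs, labels, 0)[c("FN", "TN")],
               c(FN = 0L, TN = 0L))
  hi <- confusion_at(probs, labels, max(probs) + 0.01)
  expect_equal(hi[c("TP", "FP")], c(TP = 0L, FP = 0L))
})

test_that("TPR curve counts positives above threshold, non-increasing", {
  probs <- c(p1 = 0.2, p2 = 0.4, p3 = 0.6, p4 = 0.8)
  curve <- tpr_curve(probs, names(probs), thresholds = c(0.3, 0.5),
                     interval = c(0.3, 0.5))
  expect_equal(curve$tpr, c(0.75, 0.5))
  expect_equal(attr(curve, "mean_tpr"), 0.625)
  full <- tpr_curve(probs, names(probs))
  expect_equal(full$tpr[full$threshold == 0], 1)
  expect_true(all(diff(full$tpr) <= 0))
  ones <- tpr_curve(c(a = 1, b = 1), c("a", "b"))
  expect_true(all(ones$tpr == 1))
  expect_error(tpr_curve(probs, character(0)), "empty")
})

test_that("random-forest importance recovers a planted feature", {
  set.seed(61)
  first <- 0
  for (s in 1:20) {
    ds <- generate_dataset(synthetic_config(
      n_genes = 80, n_samples = 30, n_positive = 15, signal_strength = 0,
      missing_frac = 0, knowledge_accuracy = 1, knowledge_coverage = 1,
      seed = 100 + s))
    pcs <- pca_gene_features(ds$expression, n_components = 4)
    feats <- assemble_features(pcs, 4, encode_knowledge(ds$knowledge),
                               "hybrid")
    plan <- make_split_plan(ds$positives, rownames(feats), 2, 3,
                            master_seed = s)
    models <- fit_full(feats, plan, model_spec("random_forest", seed = s))
    imp <- feature_importance(models)
    if (imp$feature[1] %in% c("knowledge_pos", "knowledge_neg")) {
      first <- first + 1
    }
    # importances are normalized within the committee average
    expect_equal(sum(imp$mean_importance), 1, tolerance = 1e-9)
  }
  expect_gte(first / 20, 0.95)
  expect_error(feature_importance(list(list(algorithm = "svm"))), "random")
})

test_that("agreement filters to genes confident in both tables", {
  predsA <- data.frame(gene_id = sprintf("g%d", 1:8),
                       mean_prob = c(0.9, 0.8, 0.55, 0.2, 0.1, 0.45,
                                     0.7, 0.3))
  predsB <- data.frame(gene_id = sprintf("g%d", 1:8),
                       mean_prob = c(0.85, 0.9, 0.9, 0.3, 0.2, 0.1,
                                     0.65, 0.35))
  res <- agreement(predsA, predsB)
  keep <- c(1, 2, 4, 5, 7, 8)          # g3, g6 fall in a (0.4, 0.6) band
  expect_equal(res$n, 6)
  expect_setequal(res$genes, sprintf("g%d", keep))
  expect_equal(res$r, oracle_pearson(predsA$mean_prob[keep],
                                     predsB$mean_prob[keep]),
               tolerance = 1e-12)
  same <- agreement(predsA, predsA)
  expect_equal(same$r, 1)
  flipped <- predsA
  flipped$mean_prob <- 1 - predsA$mean_prob
  expect_equal(agreement(predsA, flipped)$r, -1)
  expect_error(agreement(predsA[1:3, ], predsB[6:8, ]), "fewer than 3")
})

test_that("bootstrap averaging reports mean-of-iterations, not pooled", {
  cv <- data.frame(
    bootstrap = rep(1:2, each = 4),
    fold = 1L,
    gene_id = rep(sprintf("g%d", 1:4), 2),
    label = rep(c(1, 1, 0, 0), 2),
    prob = c(0.9, 0.8, 0.2, 0.1,       # perfect iteration
             0.4, 0.3, 0.6, 0.7))      # fully reversed iteration
  ev <- evaluate_cv(cv)
  expect_equal(unname(ev$mean[["auroc"]]), 0.5)       # mean(1, 0)
  expect_equal(ev$per_bootstrap$auroc, c(1, 0))
  pooled <- compute_metrics(cv$prob, cv$label)$auroc
  expect_false(isTRUE(all.equal(pooled, 0.5)))
})
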
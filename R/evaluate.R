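# Evaluation battery: ranking metrics (AUROC, AUPRC), thresholded metrics
# (precision, recall, accuracy, F1, MCC), confusion matrices, TPR curves,
# random-forest feature importance and inter-classifier agreement.

#' Compute the full metric battery for one prediction set
#'
#' AUROC is computed by the rank statistic (equivalent to trapezoidal
#' integration over all distinct cut points, with tied probabilities
#' contributing 1/2); AUPRC by step integration of the precision-recall
#' curve over distinct probability values. Thresholded metrics count a
#' gene predicted positive iff `prob >= threshold`. The Matthews
#' correlation coefficient is defined as 0 when any confusion-table
#' marginal is zero.
#'
#' @param probs numeric vector of positive-class probabilities.
#' @param labels binary vector (1 = positive), aligned with `probs`.
#' @param threshold cutoff for the thresholded metrics.
#' @return Object of class `eval_report`: list with `auroc`, `auprc`,
#'   `precision`, `recall`, `accuracy`, `f1`, `mcc`, `confusion`
#'   (TP/FP/FN/TN), `n_pos`, `n_neg`, `threshold`.
#' @export
compute_metrics <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to evaluate", call. = FALSE)
  }
  auroc <- auroc_rank(probs, labels)
  auprc <- auprc_step(probs, labels)
  cm <- confusion_at(probs, labels, threshold)
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]; tn <- cm[["TN"]]
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  accuracy <- (tp + tn) / length(labels)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(
    list(auroc = auroc, auprc = auprc, precision = precision,
         recall = recall, accuracy = accuracy, f1 = f1,
         mcc = mcc_from_counts(tp, fp, fn, tn), confusion = cm,
         n_pos = n_pos, n_neg = n_neg, threshold = threshold),
    class = "eval_report"
  )
}

# Rank-based AUROC: (mean rank of positives - (n_pos + 1)/2) / n_neg.
# Average ranks give tied probabilities weight 1/2 per discordant pair.
auroc_rank <- function(probs, labels) {
  r <- rank(probs)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Step-integrated area under the precision-recall curve: walk distinct
# probability values from high to low; each recall increment contributes
# its width times the precision at that cut.
auprc_step <- function(probs, labels) {
  cuts <- sort(unique(probs), decreasing = TRUE)
  n_pos <- sum(labels == 1L)
  area <- 0
  prev_recall <- 0
  tp_cum <- 0
  n_cum <- 0
  for (cut in cuts) {
    sel <- probs == cut
    tp_cum <- tp_cum + sum(labels[sel] == 1L)
    n_cum <- n_cum + sum(sel)
    recall <- tp_cum / n_pos
    precision <- tp_cum / n_cum
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# MCC with the zero-marginal convention: 0 whenever a marginal is empty.
mcc_from_counts <- function(tp, fp, fn, tn) {
  margins <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(margins == 0)) return(0)
  (tp * tn - fp * fn) / sqrt(prod(margins))
}

#' Confusion counts at a probability threshold
#'
#' A gene is predicted positive iff its probability is greater than or
#' equal to the threshold.
#'
#' @param probs probabilities; @param labels binary labels (1 = positive).
#' @param threshold cutoff (the framework's convention for confusion
#'   matrices is 0.75).
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_at <- function(probs, labels, threshold = 0.75) {
  stopifnot(length(probs) == length(labels))
  pred <- probs >= threshold
  pos <- labels == 1L
  c(TP = sum(pred & pos), FP = sum(pred & !pos),
    FN = sum(!pred & pos), TN = sum(!pred & !pos))
}

#' Average an evaluation across bootstrap iterations
#'
#' Computes the metric battery within each bootstrap's out-of-fold
#' predictions and reports the mean of each metric across iterations (the
#' headline values), alongside the per-iteration table.
#'
#' @param cv result of [cross_validate()].
#' @param threshold cutoff passed to [compute_metrics()].
#' @return List with `mean` (named numeric vector of metric means across
#'   iterations) and `per_bootstrap` (data frame, one row per iteration).
#' @export
evaluate_cv <- function(cv, threshold = 0.5) {
  metrics <- c("auroc", "auprc", "precision", "recall", "accuracy",
               "f1", "mcc")
  rows <- lapply(split(cv, cv$bootstrap), function(d) {
    r <- compute_metrics(d$prob, d$label, threshold)
    c(bootstrap = d$bootstrap[1L], unlist(r[metrics]))
  })
  per_bootstrap <- as.data.frame(do.call(rbind, rows))
  list(mean = colMeans(per_bootstrap[, metrics, drop = FALSE]),
       per_bootstrap = per_bootstrap)
}

#' True-positive rate as a function of classification threshold
#'
#' `TPR(t)` is the fraction of positive genes whose probability is at
#' least `t`; it is non-increasing in `t` and equals 1 at `t = 0`. Used to
#' compare annotation models over a range of cut points.
#'
#' @param probs named probability vector.
#' @param positive_ids gene IDs of the true positives (must be nonempty
#'   and present in `probs`).
#' @param thresholds ascending numeric vector of cut points.
#' @param interval optional `c(lo, hi)`; if given, the mean TPR over the
#'   thresholds falling in `[lo, hi]` is attached as attribute
#'   `mean_tpr`.
#' @return Data frame with columns `threshold`, `tpr`.
#' @export
tpr_curve <- function(probs, positive_ids, thresholds = seq(0, 1, 0.05),
                      interval = NULL) {
  if (length(positive_ids) == 0L) {
    stop("positive set is empty", call. = FALSE)
  }
  if (is.unsorted(thresholds)) {
    stop("thresholds must be sorted ascending", call. = FALSE)
  }
  p <- probs[positive_ids]
  if (anyNA(p)) {
    stop("positives missing from probability table", call. = FALSE)
  }
  tpr <- vapply(thresholds, function(t) mean(p >= t), 0)
  out <- data.frame(threshold = thresholds, tpr = tpr)
  if (!is.null(interval)) {
    sel <- thresholds >= interval[1L] & thresholds <= interval[2L]
    attr(out, "mean_tpr") <- mean(tpr[sel])
  }
  out
}

#' Mean random-forest feature importance across bootstrap models
#'
#' Importance is the mean impurity (Gini) decrease across the trees of
#' each forest, normalized within each model to sum to 1, then averaged
#' over the bootstrap committee.
#'
#' @param models list of fitted models from [fit_full()]; all must be
#'   random forests.
#' @return Data frame with columns `feature`, `mean_importance`, `sd`,
#'   sorted by decreasing mean importance.
#' @export
feature_importance <- function(models) {
  if (!all(vapply(models, function(m) m$algorithm, "") ==
           "random_forest")) {
    stop("feature importance is defined for random-forest models only",
         call. = FALSE)
  }
  imp <- vapply(models, function(m) {
    v <- randomForest::importance(m$fit, type = 2L)[, 1L]
    v / sum(v)
  }, numeric(length(models[[1L]]$features)))
  if (is.null(dim(imp))) imp <- matrix(imp, nrow = 1L)
  out <- data.frame(
    feature = models[[1L]]$features,
    mean_importance = rowMeans(imp),
    sd = apply(imp, 1L, stats::sd)
  )
  out[order(-out$mean_importance), , drop = FALSE]
}

#' Inter-classifier agreement on confidently scored genes
#'
#' Restricts to genes whose mean probability is above `upper` or below
#' `lower` in both prediction tables, then reports the Pearson
#' correlation of the two probability vectors over those genes.
#'
#' @param predsA,predsB prediction tables (data frames with `gene_id`
#'   and `mean_prob`).
#' @param upper,lower confidence band bounds (defaults 0.6 and 0.4).
#' @return List with `r` (Pearson correlation), `n` (genes retained) and
#'   `genes`.
#' @export
agreement <- function(predsA, predsB, upper = 0.6, lower = 0.4) {
  shared <- intersect(predsA$gene_id, predsB$gene_id)
  a <- predsA$mean_prob[match(shared, predsA$gene_id)]
  b <- predsB$mean_prob[match(shared, predsB$gene_id)]
  conf <- (a > upper | a < lower) & (b > upper | b < lower)
  if (sum(conf) < 3L) {
    stop("fewer than 3 confidently scored shared genes", call. = FALSE)
  }
  list(r = stats::cor(a[conf], b[conf]), n = sum(conf),
       genes = shared[conf])
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("AUROC %.4f  AUPRC %.4f  precision %.4f  recall %.4f\n",
           "accuracy %.4f  F1 %.4f  MCC %.4f  (threshold %.2f, %d+/%d-)\n"),
    x$auroc, x$auprc, x$precision, x$recall, x$accuracy, x$f1, x$mcc,
    x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}
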
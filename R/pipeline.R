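# End-to-end driver: preprocessing, feature assembly, the bootstrap x CV
# training regime and the PC-variant ensemble, for one GO-term task.

# Shared preparation for one task: filter + impute the expression matrix,
# build the extra (metabolite/knowledge) feature columns, fit the PC
# embedding deep enough for the largest variant of either arm, and build
# the split plan on the feature universe.
prepare_task <- function(expression, positives, config,
                         metabolites = NULL, knowledge = NULL) {
  stopifnot(inherits(config, "run_config"))
  expr <- filter_matrix(expression, config$max_missing)
  expr <- knn_impute(expr, config$knn_k)

  extras <- NULL
  if (!is.null(metabolites)) {
    extras <- metabolite_corr_features(expr, metabolites,
                                       alpha = config$alpha)
  }
  if (!is.null(knowledge)) {
    enc <- encode_knowledge(knowledge, genes = rownames(expr))
    extras <- if (is.null(extras)) enc else cbind(extras, enc)
  }
  n_extra <- if (is.null(extras)) 0L else ncol(extras)

  max_comp <- min(max(config$pc_counts) + n_extra,
                  nrow(expr), ncol(expr))
  pcs <- pca_gene_features(expr, n_components = max_comp)

  universe <- rownames(expr)
  pos <- intersect(positives, universe)
  if (length(pos) == 0L) {
    stop("no positive genes present in the filtered expression matrix",
         call. = FALSE)
  }
  plan <- make_split_plan(pos, universe,
                          n_bootstrap = config$n_bootstrap,
                          n_folds = config$n_folds,
                          master_seed = config$seed)
  list(expr = expr, pcs = pcs, extras = extras, plan = plan,
       universe = universe, positives = pos)
}

#' Train and evaluate one GO-term classifier
#'
#' Runs the full regime for a single algorithm and feature mode: for each
#' PC-count variant, out-of-fold probabilities are collected over all
#' bootstrap iterations and folds and the metric battery is averaged
#' across iterations; full-data bootstrap models then score every
#' unlabeled gene, and the per-variant means are combined into a
#' mean +/- SE ensemble prediction table.
#'
#' @param expression gene x sample matrix (`NA` marks missing values).
#' @param positives character vector of positive (annotated) gene IDs.
#' @param config a [run_config()]; `config$hybrid` selects the feature
#'   mode and `config$algorithm` the classifier family.
#' @param metabolites optional metabolite x sample matrix; adds one
#'   Fisher-z Spearman feature per metabolite row.
#' @param knowledge optional named score vector in \{1, 0, -1\}; adds the
#'   two one-hot knowledge columns.
#' @param predict_unlabeled_genes if `FALSE`, the (slower) unlabeled-gene
#'   scoring step is skipped and only the cross-validated evaluation is
#'   returned.
#' @return Object of class `go_term_fit`: list with `eval` (mean metrics
#'   across variants), `variants` (per-variant evaluation and CV tables),
#'   `predictions` (ensemble prediction table for unlabeled genes, or
#'   `NULL`), `plan` and `config`.
#' @export
classify_term <- function(expression, positives, config,
                          metabolites = NULL, knowledge = NULL,
                          predict_unlabeled_genes = TRUE) {
  task <- prepare_task(expression, positives, config,
                       metabolites = metabolites, knowledge = knowledge)
  fit_task(task, config, predict_unlabeled_genes)
}

# Core loop over PC-count variants for one prepared task.
fit_task <- function(task, config, predict_unlabeled_genes = TRUE) {
  mode <- if (config$hybrid) "hybrid" else "transcriptomics_only"
  spec <- model_spec(config$algorithm, seed = config$seed)
  unlabeled <- setdiff(task$universe, task$positives)

  variants <- list()
  variant_means <- NULL
  for (n_pc in config$pc_counts) {
    feats <- assemble_features(task$pcs, n_pc, task$extras, mode)
    cv <- cross_validate(feats, task$plan, spec)
    ev <- evaluate_cv(cv, threshold = 0.5)
    pred <- NULL
    if (predict_unlabeled_genes) {
      models <- fit_full(feats, task$plan, spec)
      pred <- predict_unlabeled(models,
                                feats[unlabeled, , drop = FALSE],
                                plan = task$plan)
      variant_means <- cbind(variant_means, pred)
    }
    variants[[paste0("pc", n_pc)]] <-
      list(n_pc = n_pc, n_features = ncol(feats), cv = cv, eval = ev,
           unlabeled_probs = pred)
  }
  predictions <- NULL
  if (predict_unlabeled_genes) {
    colnames(variant_means) <- names(variants)
    predictions <- ensemble_predictions(variant_means)
  }
  eval_mat <- do.call(rbind, lapply(variants, function(v) v$eval$mean))
  structure(
    list(eval = colMeans(eval_mat), eval_by_variant = eval_mat,
         variants = variants, predictions = predictions,
         plan = task$plan, mode = mode, config = config),
    class = "go_term_fit"
  )
}

#' @export
print.go_term_fit <- function(x, ...) {
  cat(sprintf("GO-term classifier fit (%s, %s): %d variants\n",
              x$config$algorithm, x$mode, length(x$variants)))
  cat(sprintf("  mean AUROC %.4f  AUPRC %.4f  MCC %.4f\n",
              x$eval[["auroc"]], x$eval[["auprc"]], x$eval[["mcc"]]))
  invisible(x)
}

#' Run every algorithm x PC-count x feature-mode cell
#'
#' Trains the full comparison grid for one task — each classifier family,
#' each PC-feature count and both arms (hybrid and the feature-count
#' matched transcriptomics-only comparator) — on a shared split plan, and
#' tabulates the cross-validated metric battery per cell.
#'
#' @inheritParams classify_term
#' @param algorithms classifier families to include.
#' @return Data frame with one row per (algorithm, pc_count, mode) cell
#'   and the mean-across-bootstraps metrics as columns.
#' @export
train_matrix <- function(expression, positives, config,
                         metabolites = NULL, knowledge = NULL,
                         algorithms = ALGORITHMS) {
  task <- prepare_task(expression, positives, config,
                       metabolites = metabolites, knowledge = knowledge)
  cells <- list()
  for (alg in algorithms) {
    for (mode in c("hybrid", "transcriptomics_only")) {
      cfg <- config
      cfg$algorithm <- alg
      cfg$hybrid <- mode == "hybrid"
      fit <- fit_task(task, cfg, predict_unlabeled_genes = FALSE)
      for (v in fit$variants) {
        cells[[length(cells) + 1L]] <- data.frame(
          algorithm = alg, mode = mode, n_pc = v$n_pc,
          n_features = v$n_features, t(v$eval$mean))
      }
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}
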
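#' Run configuration for a GO-term classification task
#'
#' Collects every tunable constant of the pipeline in one validated object.
#' The defaults are the framework's canonical settings: k = 5 nearest
#' neighbours for imputation, a 30% missing-value cap, a 0.05 significance
#' level on metabolite correlations, principal-component counts of 5, 14,
#' 30 and 50, 100 bootstrap negative samples, five-fold cross-validation, a
#' 0.75 threshold for confusion matrices, a 0.80 candidate gate and a
#' 0.6/0.4 confidence band for inter-classifier agreement.
#'
#' @param term GO-term (or gene-set) identifier being classified.
#' @param algorithm one of `"random_forest"`, `"decision_tree"`,
#'   `"naive_bayes"`, `"svm"`.
#' @param pc_counts strictly increasing integer vector of
#'   principal-component feature counts, one model variant per entry.
#' @param hybrid logical; if `TRUE`, knowledge/metabolite features are
#'   appended, otherwise they are replaced by additional PCs so both arms
#'   have equally many features.
#' @param n_bootstrap number of bootstrap negative-sampling iterations.
#' @param n_folds number of cross-validation folds.
#' @param alpha significance level for zeroing metabolite correlations.
#' @param knn_k neighbour count for k-NN imputation.
#' @param max_missing maximum tolerated missing fraction per row/column.
#' @param confusion_threshold probability cutoff for confusion matrices.
#' @param gate_threshold cutoff for the multi-classifier candidate gate.
#' @param confident_bounds numeric `c(upper, lower)`: a prediction is
#'   "confident" when above the first or below the second value.
#' @param seed master seed; all per-bootstrap and per-model seeds are
#'   derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(term = "GO:0000000", algorithm = "random_forest",
                       pc_counts = c(5L, 14L, 30L, 50L), hybrid = TRUE,
                       n_bootstrap = 100L, n_folds = 5L, alpha = 0.05,
                       knn_k = 5L, max_missing = 0.30,
                       confusion_threshold = 0.75, gate_threshold = 0.80,
                       confident_bounds = c(0.6, 0.4), seed = 1L) {
  algorithms <- c("random_forest", "decision_tree", "naive_bayes", "svm")
  if (!is.character(algorithm) || length(algorithm) != 1L ||
      !algorithm %in% algorithms) {
    stop_field("algorithm",
               paste("must be one of:", paste(algorithms, collapse = ", ")))
  }
  pc_counts <- vapply(pc_counts, check_count, 1L, field = "pc_counts")
  if (length(pc_counts) < 1L || is.unsorted(pc_counts, strictly = TRUE)) {
    stop_field("pc_counts", "must be strictly increasing")
  }
  cfg <- list(
    term = as.character(term),
    algorithm = algorithm,
    pc_counts = pc_counts,
    hybrid = isTRUE(hybrid),
    n_bootstrap = check_count(n_bootstrap, "n_bootstrap"),
    n_folds = check_count(n_folds, "n_folds", min = 2L),
    alpha = check_fraction(alpha, "alpha", open_left = TRUE,
                           open_right = TRUE),
    knn_k = check_count(knn_k, "knn_k"),
    max_missing = check_fraction(max_missing, "max_missing",
                                 open_left = TRUE, open_right = TRUE),
    confusion_threshold = check_fraction(confusion_threshold,
                                         "confusion_threshold",
                                         open_left = TRUE,
                                         open_right = TRUE),
    gate_threshold = check_fraction(gate_threshold, "gate_threshold",
                                    open_left = TRUE, open_right = TRUE),
    confident_bounds = confident_bounds,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(confident_bounds) || length(confident_bounds) != 2L ||
      any(confident_bounds <= 0) || any(confident_bounds >= 1) ||
      confident_bounds[1L] <= confident_bounds[2L]) {
    stop_field("confident_bounds",
               "must be c(upper, lower) with 0 < lower < upper < 1")
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; any unknown key is an
#' error, so typos never silently fall back to defaults.
#'
#' @param path path to the YAML file.
#' @return A `run_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("GO-term classification run configuration\n")
  cat("  term:", x$term, " algorithm:", x$algorithm,
      if (x$hybrid) "(hybrid)" else "(transcriptomics-only)", "\n")
  cat("  pc_counts:", paste(x$pc_counts, collapse = ", "), "\n")
  cat("  bootstraps:", x$n_bootstrap, " folds:", x$n_folds,
      " master seed:", x$seed, "\n")
  invisible(x)
}
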
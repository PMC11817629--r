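# Expression-matrix preprocessing: missing-value filtering, k-NN
# imputation and PCA gene embeddings.

#' Filter a matrix on missingness and zero variance
#'
#' Samples (columns) whose missing fraction exceeds `max_missing` are
#' removed first; then rows are removed if their missing fraction over the
#' remaining columns exceeds `max_missing` or their standard deviation over
#' observed entries is zero. Removing bad samples first avoids dropping
#' genes whose missingness is concentrated in a few bad samples.
#'
#' @param m numeric matrix with dimnames; `NA` marks missing.
#' @param max_missing maximum tolerated missing fraction, in (0, 1).
#' @return The filtered matrix, with a `filter_report` attribute: a data
#'   frame of removed IDs, the axis each came from and the reason.
#' @export
filter_matrix <- function(m, max_missing = 0.30) {
  stopifnot(is.matrix(m))
  max_missing <- check_fraction(max_missing, "max_missing",
                                open_left = TRUE, open_right = TRUE)
  report <- data.frame(id = character(), axis = character(),
                       reason = character())
  col_miss <- colMeans(is.na(m))
  bad_cols <- col_miss > max_missing
  if (any(bad_cols)) {
    report <- rbind(report, data.frame(
      id = colnames(m)[bad_cols], axis = "sample",
      reason = sprintf("missing fraction %.3f > %.2f",
                       col_miss[bad_cols], max_missing)))
    m <- m[, !bad_cols, drop = FALSE]
  }
  row_miss <- rowMeans(is.na(m))
  row_sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
  too_missing <- row_miss > max_missing
  zero_sd <- !too_missing & (is.na(row_sd) | row_sd == 0)
  if (any(too_missing | zero_sd)) {
    report <- rbind(
      report,
      if (any(too_missing)) data.frame(
        id = rownames(m)[too_missing], axis = "row",
        reason = sprintf("missing fraction %.3f > %.2f",
                         row_miss[too_missing], max_missing)),
      if (any(zero_sd)) data.frame(
        id = rownames(m)[zero_sd], axis = "row",
        reason = "zero standard deviation"))
    m <- m[!(too_missing | zero_sd), , drop = FALSE]
  }
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("matrix is empty after filtering", call. = FALSE)
  }
  attr(m, "filter_report") <- report
  m
}

# Pairwise nan-aware Euclidean distances from row `i` to all rows.
# Squared differences are averaged over coordinates observed in both rows
# and rescaled to the full dimension, so rows with more shared coverage are
# not artificially closer. Rows sharing no coordinate get distance Inf.
nan_euclidean <- function(m, i) {
  diffs <- sweep(m, 2L, m[i, ], "-")
  sq <- diffs^2
  shared <- rowSums(!is.na(sq))
  d2 <- rowSums(sq, na.rm = TRUE) / shared * ncol(m)
  d2[shared == 0L] <- Inf
  sqrt(d2)
}

#' Impute missing values by k nearest neighbours
#'
#' Each missing cell is replaced by the unweighted mean of that column's
#' observed values over the k rows nearest to the incomplete row, where
#' nearness is Euclidean distance computed over coordinates observed in
#' both rows and rescaled by the fraction of usable coordinates. If none of
#' the k nearest rows has an observed value in the column, the column mean
#' is used instead and the cell is recorded in the `fallback` attribute.
#'
#' @param m numeric matrix, `NA` marks missing; every row must retain at
#'   least one observed entry.
#' @param k neighbour count.
#' @return The completed matrix (no `NA`s); observed entries are untouched.
#' @export
knn_impute <- function(m, k = 5L) {
  stopifnot(is.matrix(m))
  k <- check_count(k, "k")
  if (!anyNA(m)) return(m)
  if (any(rowSums(!is.na(m)) == 0L)) {
    stop("rows with no observed entries cannot be imputed", call. = FALSE)
  }
  out <- m
  col_means <- colMeans(m, na.rm = TRUE)
  fallback <- data.frame(row = character(), col = character())
  for (i in which(rowSums(is.na(m)) > 0L)) {
    d <- nan_euclidean(m, i)
    d[i] <- Inf
    # stable order: distance, then row index
    nn <- order(d, seq_along(d))[seq_len(min(k, nrow(m) - 1L))]
    for (j in which(is.na(m[i, ]))) {
      vals <- m[nn, j]
      vals <- vals[!is.na(vals)]
      if (length(vals) > 0L) {
        out[i, j] <- mean(vals)
      } else {
        out[i, j] <- col_means[j]
        fallback <- rbind(fallback, data.frame(row = rownames(m)[i],
                                               col = colnames(m)[j]))
      }
    }
  }
  attr(out, "fallback") <- fallback
  out
}

#' Principal-component gene embedding
#'
#' Z-scores every gene (row) across samples, then runs PCA with genes as
#' observations and samples as variables. The per-gene PC scores are the
#' transcriptomic feature vectors used by the classifiers. A deterministic
#' sign convention is applied: each component's largest-magnitude loading
#' is positive.
#'
#' @param m complete numeric matrix (genes x samples), no `NA`s, no
#'   zero-variance rows.
#' @param n_components number of components to retain; default all.
#' @param variance_target if given (in (0, 1)), the smallest component
#'   count whose cumulative explained variance reaches the target is
#'   retained instead of `n_components`.
#' @return An object of class `pc_model`: list with `scores` (genes x
#'   components), `loadings` (samples x components), `var_explained`,
#'   `cum_var`, `center`, and fit metadata.
#' @export
pca_gene_features <- function(m, n_components = NULL,
                              variance_target = NULL) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("matrix must be complete; impute first", call. = FALSE)
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance rows present; filter first", call. = FALSE)
  }
  z <- (m - rowMeans(m)) / sds
  fit <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  var_explained <- fit$sdev^2 / sum(fit$sdev^2)
  cum_var <- cumsum(var_explained)
  max_comp <- length(fit$sdev)
  if (!is.null(variance_target)) {
    if (variance_target >= 1 || variance_target <= 0) {
      stop_field("variance_target", "must lie in (0, 1)")
    }
    if (max(cum_var) < variance_target) {
      stop_field("variance_target", "unattainable with available components")
    }
    n_components <- which(cum_var >= variance_target)[1L]
  }
  if (is.null(n_components)) n_components <- max_comp
  n_components <- check_count(n_components, "n_components")
  if (n_components > max_comp) {
    stop_field("n_components", "exceeds available components")
  }
  idx <- seq_len(n_components)
  scores <- fit$x[, idx, drop = FALSE]
  loadings <- fit$rotation[, idx, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in idx) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, loadings = loadings,
         var_explained = var_explained[idx], cum_var = cum_var[idx],
         var_explained_all = var_explained,
         n_genes = nrow(m), n_samples = ncol(m),
         normalization = "per-gene z-score"),
    class = "pc_model"
  )
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf(
    "PC gene embedding: %d genes x %d samples, %d components (%.1f%% var)\n",
    x$n_genes, x$n_samples, ncol(x$scores), 100 * max(x$cum_var)))
  invisible(x)
}

#' Absolute cosine similarity between two sets of principal components
#'
#' Compares the loading vectors of two PC models over their shared
#' variables (sample IDs). The absolute value makes the comparison
#' invariant to the arbitrary sign of a principal axis. Used to check that
#' components are stable under gene subsampling or sample selection.
#'
#' @param a,b `pc_model` objects (or plain loading matrices with rownames).
#' @return Matrix of |cosine| similarities, components of `a` by
#'   components of `b`, entries in `[0, 1]`.
#' @export
component_similarity <- function(a, b) {
  la <- if (inherits(a, "pc_model")) a$loadings else a
  lb <- if (inherits(b, "pc_model")) b$loadings else b
  stopifnot(is.matrix(la), is.matrix(lb))
  shared <- intersect(rownames(la), rownames(lb))
  if (length(shared) < 2L) {
    stop("fewer than 2 shared variables between the two models",
         call. = FALSE)
  }
  la <- la[shared, , drop = FALSE]
  lb <- lb[shared, , drop = FALSE]
  la <- sweep(la, 2L, sqrt(colSums(la^2)), "/")
  lb <- sweep(lb, 2L, sqrt(colSums(lb^2)), "/")
  abs(crossprod(la, lb))
}
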
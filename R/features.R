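# Hybrid feature assembly: metabolite-correlation features, one-hot
# knowledge encodings and PC-score tables with feature-count equalization
# for the transcriptomics-only comparator.

#' Fisher-transformed Spearman correlation features
#'
#' For each gene and each metabolite row, computes the Spearman rank
#' correlation over the samples shared between the two matrices (average
#' ranks for ties), tests it with the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (two-sided), zeroes non-significant correlations (p >= `alpha`), and
#' returns the Fisher transform `z = atanh(rho)` with |rho| clamped to
#' `1 - 1e-12` so perfectly monotone pairs stay finite. Constant gene rows
#' have undefined correlation and yield a 0 feature; they are recorded in
#' the `constant_genes` attribute.
#'
#' @param expr complete gene x sample matrix.
#' @param metab metabolite x sample matrix (>= 1 row).
#' @param alpha significance level in (0, 1) used for zeroing.
#' @param df degrees of freedom for the t test; default `n - 2`. A fixed
#'   value may be supplied to reproduce non-standard published settings.
#' @return Matrix genes x metabolites of Fisher-z features, with column
#'   names `corr_<metabolite>`.
#' @export
metabolite_corr_features <- function(expr, metab, alpha = 0.05, df = NULL) {
  stopifnot(is.matrix(expr), is.matrix(metab))
  alpha <- check_fraction(alpha, "alpha", open_left = TRUE,
                          open_right = TRUE)
  shared <- intersect(colnames(expr), colnames(metab))
  n <- length(shared)
  if (n < 4L) {
    stop("need at least 4 shared samples between expression and ",
         "metabolite matrices (found ", n, ")", call. = FALSE)
  }
  e <- expr[, shared, drop = FALSE]
  mm <- metab[, shared, drop = FALSE]
  dfree <- if (is.null(df)) n - 2L else df
  # rank rows, then Pearson on ranks = Spearman with average ranks for ties
  re <- t(apply(e, 1L, rank))
  rm_ <- t(apply(mm, 1L, rank))
  const <- apply(re, 1L, function(r) stats::sd(r) == 0)
  out <- matrix(0, nrow(e), nrow(mm),
                dimnames = list(rownames(e),
                                paste0("corr_", rownames(mm))))
  if (any(!const)) {
    rho <- stats::cor(t(re[!const, , drop = FALSE]),
                      t(rm_), method = "pearson")
    rho[is.na(rho)] <- 0
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(abs(tstat), df = dfree, lower.tail = FALSE)
    rho[p >= alpha] <- 0
    rho <- pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
    out[!const, ] <- atanh(rho)
  }
  attr(out, "constant_genes") <- rownames(e)[const]
  out
}

#' One-hot encode categorical knowledge scores
#'
#' Scores take values 1 (positive classification), 0 (negative
#' classification) or -1 (no classification). They are encoded as two
#' Boolean columns for the positive and negative classes; the
#' no-classification state is implicit as (0, 0), so no third column is
#' needed. Genes in `genes` that are absent from the score table are
#' assigned -1.
#'
#' @param scores named vector with values in \{1, 0, -1\}.
#' @param genes optional character vector; if given, the encoding covers
#'   exactly these genes (missing ones scored -1).
#' @return Matrix genes x 2 with columns `knowledge_pos`, `knowledge_neg`,
#'   values in \{0, 1\}.
#' @export
encode_knowledge <- function(scores, genes = NULL) {
  if (is.null(names(scores))) {
    stop("scores must be a named vector", call. = FALSE)
  }
  bad <- !scores %in% c(1, 0, -1)
  if (any(bad)) {
    stop("knowledge scores must be in {1, 0, -1}; offending gene(s): ",
         paste(utils::head(names(scores)[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(genes)) genes <- names(scores)
  s <- scores[genes]
  s[is.na(s)] <- -1
  enc <- cbind(knowledge_pos = as.numeric(s == 1),
               knowledge_neg = as.numeric(s == 0))
  rownames(enc) <- genes
  enc
}

#' Assemble the per-gene feature table
#'
#' Combines PC scores with extra feature columns (metabolite correlations
#' and/or knowledge encodings). In `"hybrid"` mode the table holds `n_pc`
#' PC features plus the extras; in `"transcriptomics_only"` mode the
#' extras are replaced by the same number of additional PC features, so
#' both arms have `n_pc + ncol(extras)` features and comparisons are not
#' confounded by feature count (e.g. 5 PCs + 2 knowledge columns is
#' matched by a 7-PC model). Genes are aligned across sources by ID
#' intersection; dropped genes are recorded in the `dropped_genes`
#' attribute.
#'
#' @param pcs a `pc_model` (or a genes x components score matrix).
#' @param n_pc number of PC features in the hybrid arm.
#' @param extras matrix of extra feature columns with gene rownames, or
#'   `NULL`. In `transcriptomics_only` mode only its column count is used.
#' @param mode `"hybrid"` or `"transcriptomics_only"`.
#' @return A numeric gene x feature matrix with a `provenance` attribute
#'   (one of `"pc"`, `"metabolite_corr"`, `"knowledge_pos"`,
#'   `"knowledge_neg"` per column).
#' @export
assemble_features <- function(pcs, n_pc, extras = NULL,
                              mode = c("hybrid", "transcriptomics_only")) {
  mode <- match.arg(mode)
  scores <- if (inherits(pcs, "pc_model")) pcs$scores else pcs
  stopifnot(is.matrix(scores))
  n_pc <- check_count(n_pc, "n_pc")
  n_extra <- if (is.null(extras)) 0L else ncol(extras)
  total_pc <- if (mode == "hybrid") n_pc else n_pc + n_extra
  if (total_pc > ncol(scores)) {
    stop_field("n_pc", sprintf("needs %d components but only %d available",
                               total_pc, ncol(scores)))
  }
  genes <- rownames(scores)
  if (mode == "hybrid" && n_extra > 0L) {
    genes <- intersect(genes, rownames(extras))
    if (length(genes) == 0L) {
      stop("no genes shared between PC scores and extra features",
           call. = FALSE)
    }
  }
  dropped <- setdiff(rownames(scores), genes)
  tab <- scores[genes, seq_len(total_pc), drop = FALSE]
  colnames(tab) <- paste0("PC", seq_len(total_pc))
  prov <- rep("pc", total_pc)
  if (mode == "hybrid" && n_extra > 0L) {
    ex <- extras[genes, , drop = FALSE]
    tab <- cbind(tab, ex)
    prov <- c(prov, vapply(colnames(extras), function(nm) {
      if (nm == "knowledge_pos") "knowledge_pos"
      else if (nm == "knowledge_neg") "knowledge_neg"
      else "metabolite_corr"
    }, ""))
  }
  if (anyNA(tab)) stop("feature table contains missing values",
                       call. = FALSE)
  if (anyDuplicated(colnames(tab))) {
    stop("duplicate feature names", call. = FALSE)
  }
  attr(tab, "provenance") <- stats::setNames(prov, colnames(tab))
  attr(tab, "dropped_genes") <- dropped
  attr(tab, "mode") <- mode
  tab
}
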
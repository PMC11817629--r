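# Readers and writers for the pipeline's tabular artifacts. All formats are
# plain text: TSV matrices (tab primary, comma accepted on read), GMT gene
# sets, flat annotation tables and TSV prediction reports.

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a gene-by-sample (or metabolite-by-sample) matrix
#'
#' Expects a header line of sample IDs and one row per gene/metabolite with
#' the identifier in the first column. Empty cells and the literal `NA` mark
#' missing values; any other non-numeric cell is an error. The delimiter
#' (tab or comma) is sniffed from the header line.
#'
#' @param path path to the TSV/CSV file.
#' @return A numeric matrix with row and column names; `NA` entries mark
#'   missing values.
#' @export
read_omics_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  nf <- utils::count.fields(path, sep = sep, quote = "",
                            comment.char = "")
  if (length(unique(nf)) > 1L) {
    stop("ragged rows at line(s): ",
         paste(which(nf != nf[1L]), collapse = ", "), call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate row IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols)) {
    stop("duplicate sample IDs in header", call. = FALSE)
  }
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells[cells == "" | cells == "NA"] <- NA_character_
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !is.na(cells) & is.na(values)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 cells[bad][1L], ids[i[1L]], cols[i[2L]]), call. = FALSE)
  }
  dimnames(values) <- list(ids, cols)
  values
}

#' Write a matrix in the format `read_omics_matrix()` reads
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_omics_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is: set name, description, then tab-separated gene IDs.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors of gene IDs.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line(s) (need name, description, >=1 gene): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in GMT file", call. = FALSE)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat GO-annotation table
#'
#' Expects a TSV with columns `gene_id`, `term_id`, `evidence_code` (header
#' required). Records duplicated across sources are deduplicated.
#'
#' @param path path to the table.
#' @return A data frame with the three columns, deduplicated.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("gene_id", "term_id", "evidence_code")
  if (!all(need %in% colnames(df))) {
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  empty <- which(!nzchar(df$evidence_code))
  if (length(empty) > 0L) {
    stop("empty evidence_code at data line(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  unique(df)
}

#' Read a two-column knowledge-score table
#'
#' Expects columns `gene_id` and `score`, scores in \{1, 0, -1\}.
#'
#' @param path path to the table.
#' @return Named integer vector of scores.
#' @export
read_knowledge <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          comment.char = "")
  if (!all(c("gene_id", "score") %in% colnames(df))) {
    stop("knowledge table must have columns gene_id, score", call. = FALSE)
  }
  scores <- as.integer(df$score)
  if (!all(scores %in% c(1L, 0L, -1L))) {
    stop("knowledge scores must be in {1, 0, -1}", call. = FALSE)
  }
  stats::setNames(scores, as.character(df$gene_id))
}

#' Write a prediction table
#'
#' Emits the columns `gene_id`, `mean_prob`, `se`, `n_models`,
#' `class_at_threshold` as TSV, with probabilities written at full
#' precision so a round trip preserves at least 12 significant digits.
#'
#' @param preds a prediction table (see [ensemble_predictions()]).
#' @param path output path.
#' @param threshold classification threshold used for `class_at_threshold`
#'   (predicted positive iff `mean_prob >= threshold`).
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(preds, path, threshold = 0.75) {
  stopifnot(is.data.frame(preds),
            all(c("gene_id", "mean_prob", "se", "n_models") %in%
                  colnames(preds)))
  out <- data.frame(
    gene_id = preds$gene_id,
    mean_prob = sprintf("%.15g", preds$mean_prob),
    se = sprintf("%.15g", preds$se),
    n_models = preds$n_models,
    class_at_threshold = as.integer(preds$mean_prob >= threshold)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path path to the TSV.
#' @return Data frame with numeric `mean_prob` and `se`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  df$gene_id <- as.character(df$gene_id)
  df
}
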
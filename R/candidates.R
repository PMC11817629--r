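# Candidate nomination: probability ranking and the multi-classifier gate.

#' Rank genes by mean ensemble probability
#'
#' Sorts a prediction table by descending mean probability, breaking ties
#' by gene ID so the ordering is deterministic, and adds a formatted
#' `"mean (SE)"` label column.
#'
#' @param preds prediction table (data frame with `gene_id`, `mean_prob`,
#'   `se`).
#' @param gene_subset optional character vector; only these genes are
#'   ranked. Subset genes absent from the table trigger a warning listing
#'   them.
#' @return Data frame ordered by rank, with columns `rank`, `gene_id`,
#'   `mean_prob`, `se`, `label`.
#' @export
rank_by_probability <- function(preds, gene_subset = NULL) {
  stopifnot(is.data.frame(preds), nrow(preds) > 0L)
  if (!is.null(gene_subset)) {
    unknown <- setdiff(gene_subset, preds$gene_id)
    if (length(unknown) > 0L) {
      warning("subset genes absent from prediction table: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    preds <- preds[preds$gene_id %in% gene_subset, , drop = FALSE]
  }
  ord <- order(-preds$mean_prob, preds$gene_id)
  out <- preds[ord, c("gene_id", "mean_prob", "se"), drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
  out$label <- format_prob(out$mean_prob, out$se)
  out
}

#' Multi-classifier candidate gate
#'
#' A gene passes iff its mean probability is strictly greater than the
#' threshold in all three classifiers (mitochondrion, transporter and the
#' target term). Genes already annotated to one of the terms are assigned
#' probability exactly 1.0 (with SE 0 and an `annotated` flag) for that
#' axis before gating, so known genes are never excluded by their own
#' classifier.
#'
#' @param mito,transp,target prediction tables sharing one gene universe.
#' @param annotated_sets named list of character vectors keyed `mito`,
#'   `transp`, `target` (any may be empty) of already-annotated genes.
#' @param threshold gate cutoff (default 0.80, strict inequality).
#' @return Data frame with one row per gene: the three probabilities and
#'   SEs (after the annotated override), three `annotated_*` flags and
#'   `passed`; the fraction of the universe removed is attached as
#'   attribute `removed_fraction`.
#' @export
triple_gate <- function(mito, transp, target,
                        annotated_sets = list(), threshold = 0.80) {
  tables <- list(mito = mito, transp = transp, target = target)
  universe <- sort(tables[[1L]]$gene_id)
  for (nm in names(tables)) {
    ids <- sort(tables[[nm]]$gene_id)
    if (!identical(ids, universe)) {
      ndiff <- length(setdiff(ids, universe)) +
        length(setdiff(universe, ids))
      stop(sprintf(
        "gene universe mismatch ('%s' table): symmetric difference of %d",
        nm, ndiff), call. = FALSE)
    }
  }
  cols <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    prob <- tb$mean_prob[match(universe, tb$gene_id)]
    se <- tb$se[match(universe, tb$gene_id)]
    ann <- universe %in% annotated_sets[[nm]]
    prob[ann] <- 1.0
    se[ann] <- 0
    stats::setNames(data.frame(prob, se, ann),
                    paste0(nm, c("_prob", "_se", "_annotated")))
  })
  out <- cbind(data.frame(gene_id = universe), do.call(cbind, cols))
  out$passed <- out$mito_prob > threshold & out$transp_prob > threshold &
    out$target_prob > threshold
  attr(out, "removed_fraction") <- 1 - mean(out$passed)
  out
}
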
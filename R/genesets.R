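# Positive-set construction with evidence-code filtering, balanced
# negative sampling and the bootstrap x cross-validation split plan.

# GO evidence-code families. Experimental plus high-throughput codes are
# accepted by default; the sequence-similarity family (ISS etc.) can be
# allowed per term for sparsely annotated terms.
EXPERIMENTAL_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
                        "HTP", "HDA", "HMP", "HGI", "HEP")
SEQ_SIMILARITY_CODES <- c("ISS", "ISO", "ISA", "ISM")

#' Evidence policy for positive-set construction
#'
#' @param whitelist accepted evidence codes; defaults to the experimental
#'   and high-throughput GO code families.
#' @param allow_sequence_similarity if `TRUE`, the sequence-similarity
#'   family (ISS, ISO, ISA, ISM) is also accepted — useful for small terms
#'   where experimental annotations alone leave too few positives.
#' @return Object of class `evidence_policy`.
#' @export
evidence_policy <- function(whitelist = EXPERIMENTAL_CODES,
                            allow_sequence_similarity = FALSE) {
  if (length(whitelist) == 0L) {
    stop_field("whitelist", "must be nonempty")
  }
  codes <- unique(c(whitelist,
                    if (isTRUE(allow_sequence_similarity))
                      SEQ_SIMILARITY_CODES))
  structure(list(whitelist = codes,
                 allow_sequence_similarity =
                   isTRUE(allow_sequence_similarity)),
            class = "evidence_policy")
}

#' Build the positive gene set for a term
#'
#' A gene is positive iff it carries at least one annotation to `term`
#' whose evidence code is accepted by the policy; genes supported only by
#' low-confidence (e.g. purely computational, IEA) evidence are excluded.
#'
#' @param annotations data frame with columns `gene_id`, `term_id`,
#'   `evidence_code` (see [read_annotations()]).
#' @param term term identifier.
#' @param policy an [evidence_policy()].
#' @return Character vector of positive gene IDs, with a `counts`
#'   attribute giving the number of annotated genes kept and removed.
#' @export
build_positive_set <- function(annotations, term,
                               policy = evidence_policy()) {
  stopifnot(is.data.frame(annotations),
            inherits(policy, "evidence_policy"))
  rel <- annotations[annotations$term_id == term, , drop = FALSE]
  if (nrow(rel) == 0L) {
    stop("term not present in annotation table: ", term, call. = FALSE)
  }
  keep <- rel$evidence_code %in% policy$whitelist
  positives <- sort(unique(rel$gene_id[keep]))
  removed <- setdiff(unique(rel$gene_id), positives)
  if (length(positives) == 0L) {
    stop("no genes with accepted evidence for term ", term, call. = FALSE)
  }
  attr(positives, "counts") <- c(kept = length(positives),
                                 removed = length(removed))
  positives
}

#' Sample a balanced negative gene set
#'
#' Draws, without replacement, as many genes as there are positives from
#' the universe minus the positive set.
#'
#' @param universe character vector of candidate gene IDs.
#' @param positives character vector of positive gene IDs.
#' @param seed integer seed; identical seeds give identical sets.
#' @return Character vector of negatives, disjoint from `positives`.
#' @export
sample_negatives <- function(universe, positives, seed) {
  pool <- setdiff(universe, positives)
  n <- length(positives)
  if (length(pool) < n) {
    stop(sprintf(
      "negative pool too small: %d non-positive genes for %d positives",
      length(pool), n), call. = FALSE)
  }
  with_seed(seed, sample(pool, n))
}

# Stratified fold assignment: shuffle each class, deal folds round-robin
# starting from a random offset so fold sizes differ by at most one within
# each class.
assign_folds <- function(genes, n_folds) {
  shuffled <- sample(genes)
  folds <- (seq_along(shuffled) - 1L) %% n_folds + 1L
  stats::setNames(folds, shuffled)
}

#' Build the bootstrap x cross-validation split plan
#'
#' For each bootstrap iteration, an independent balanced negative set is
#' drawn and the positives and negatives are each dealt into `n_folds`
#' folds (stratified, so every fold has near-equal numbers of both
#' classes). The whole plan is a deterministic function of `master_seed`.
#'
#' @param positives character vector of positive gene IDs.
#' @param universe character vector of all eligible gene IDs.
#' @param n_bootstrap number of bootstrap iterations.
#' @param n_folds number of cross-validation folds.
#' @param master_seed master seed from which per-iteration seeds are
#'   derived.
#' @return Object of class `split_plan`: list with `positives`,
#'   `n_folds`, `master_seed` and `iterations`, each iteration holding
#'   `negatives`, a named `folds` vector over positives and negatives,
#'   and its `seed`.
#' @export
make_split_plan <- function(positives, universe, n_bootstrap = 100L,
                            n_folds = 5L, master_seed = 1L) {
  n_bootstrap <- check_count(n_bootstrap, "n_bootstrap")
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  if (length(positives) < n_folds) {
    stop(sprintf("need at least %d positives for %d folds (have %d)",
                 n_folds, n_folds, length(positives)), call. = FALSE)
  }
  seeds <- spawn_seeds(master_seed, n_bootstrap)
  iterations <- lapply(seq_len(n_bootstrap), function(b) {
    negatives <- sample_negatives(universe, positives, seeds[b])
    folds <- with_seed(seeds[b] + 1L,
                       c(assign_folds(positives, n_folds),
                         assign_folds(negatives, n_folds)))
    list(negatives = negatives, folds = folds, seed = seeds[b])
  })
  structure(list(positives = positives, n_folds = n_folds,
                 master_seed = master_seed, iterations = iterations),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "split plan: %d positives, %d bootstraps x %d folds (seed %d)\n",
    length(x$positives), length(x$iterations), x$n_folds, x$master_seed))
  invisible(x)
}
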
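#' Configuration for the synthetic multi-omics generator
#'
#' Describes a factor-model dataset that mimics the statistical structure the
#' annotation framework assumes in real data: low-rank co-expression, a
#' metabolite vector correlated with a designated subset of the positive
#' genes, noisy categorical knowledge scores, GO-like positive labels and
#' missing values. Defaults describe a desk-scale stand-in for a large
#' cell-line compendium: a moderately noisy five-factor expression matrix
#' with 5% of entries missing and knowledge scores that agree with the truth
#' 90% of the time but cover only 80% of genes.
#'
#' @param n_genes number of genes (rows of the expression matrix).
#' @param n_samples number of samples (columns).
#' @param n_factors number of latent co-expression factors; must not exceed
#'   `min(n_genes, n_samples)`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param factor_decay geometric decay of successive factor score standard
#'   deviations (factor f has score sd `factor_decay^(f-1)`); values below
#'   1 give the decaying scree seen in real expression data and make the
#'   leading principal axes well separated, hence identifiable.
#' @param n_positive number of genes labeled positive for the simulated term.
#' @param signal_strength mean shift applied to the positive genes' loadings
#'   on their signal factor; 0 gives a null dataset with exchangeable labels.
#' @param metabolite_assoc_frac fraction of positive genes whose signal sits
#'   on the metabolite-linked factor (factor 1); the remaining positives
#'   carry their shift on factor 2 and are not metabolite-associated.
#' @param knowledge_accuracy probability that a covered knowledge score
#'   agrees with the true label (otherwise it is flipped).
#' @param knowledge_coverage probability that a gene receives a knowledge
#'   score at all; uncovered genes get -1 ("no classification").
#' @param missing_frac fraction of expression entries masked at random.
#' @param n_metabolites number of metabolite rows; each is an independently
#'   noised copy of the factor-1 sample scores, so a pair emulates a
#'   reduced/oxidized metabolite couple measured on the same samples.
#' @param seed integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_dataset()]
#' @export
synthetic_config <- function(n_genes = 1000L, n_samples = 100L,
                             n_factors = 5L, noise_sd = 1,
                             factor_decay = 0.7,
                             n_positive = 50L, signal_strength = 2,
                             metabolite_assoc_frac = 0.5,
                             knowledge_accuracy = 0.9,
                             knowledge_coverage = 0.8,
                             missing_frac = 0.05,
                             n_metabolites = 1L, seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 2L),
    n_samples = check_count(n_samples, "n_samples", min = 2L),
    n_factors = check_count(n_factors, "n_factors"),
    noise_sd = noise_sd,
    factor_decay = check_fraction(factor_decay, "factor_decay",
                                  open_left = TRUE),
    n_positive = check_count(n_positive, "n_positive"),
    signal_strength = signal_strength,
    metabolite_assoc_frac = check_fraction(metabolite_assoc_frac,
                                           "metabolite_assoc_frac"),
    knowledge_accuracy = check_fraction(knowledge_accuracy,
                                        "knowledge_accuracy"),
    knowledge_coverage = check_fraction(knowledge_coverage,
                                        "knowledge_coverage"),
    missing_frac = check_fraction(missing_frac, "missing_frac"),
    n_metabolites = check_count(n_metabolites, "n_metabolites"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_field("noise_sd", "must be a single nonnegative number")
  }
  if (!is.numeric(signal_strength) || length(signal_strength) != 1L) {
    stop_field("signal_strength", "must be a single number")
  }
  if (cfg$n_positive >= cfg$n_genes) {
    stop_field("n_positive", "must be smaller than n_genes")
  }
  if (cfg$n_factors > min(cfg$n_genes, cfg$n_samples)) {
    stop_field("n_factors", "must not exceed min(n_genes, n_samples)")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic multi-omics dataset
#'
#' Draws gene loadings and sample scores for a latent factor model and emits
#' `expression = loadings %*% scores + noise`. Positive genes have their
#' loading on a signal factor shifted by `signal_strength`: the
#' metabolite-associated fraction on factor 1 (which also drives the
#' metabolite rows), the remainder on factor 2 (with a single factor, all
#' positives sit on factor 1). Metabolite rows are the factor-1 sample
#' scores plus independent noise. Knowledge scores agree with the truth with
#' probability `knowledge_accuracy`, are flipped otherwise, and are set to
#' -1 with probability `1 - knowledge_coverage`. Finally `missing_frac` of
#' expression entries are masked (`NA`) completely at random.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `expression` (gene x sample matrix, `NA` marks missing), `metabolites`
#'   (metabolite x sample matrix), `knowledge` (named vector in
#'   \{1, 0, -1\}), `truth` (named 0/1 vector), `positives` (character
#'   vector of positive gene IDs), `metabolite_associated` (IDs of the
#'   positives planted on the metabolite factor) and `config`.
#' @examples
#' ds <- generate_dataset(synthetic_config(n_genes = 50, n_samples = 20,
#'                                         n_positive = 5, seed = 42))
#' dim(ds$expression)
#' table(ds$knowledge)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  with_seed(config$seed, {
    g <- config$n_genes
    s <- config$n_samples
    f <- config$n_factors
    gene_ids <- sprintf("gene%04d", seq_len(g))
    sample_ids <- sprintf("sample%03d", seq_len(s))

    loadings <- matrix(stats::rnorm(g * f), g, f)
    scores <- matrix(stats::rnorm(f * s), f, s) *
      config$factor_decay^(seq_len(f) - 1L)

    positives <- gene_ids[seq_len(config$n_positive)]
    n_assoc <- round(config$metabolite_assoc_frac * config$n_positive)
    assoc <- positives[seq_len(n_assoc)]
    other <- setdiff(positives, assoc)
    loadings[seq_len(n_assoc), 1L] <-
      loadings[seq_len(n_assoc), 1L] + config$signal_strength
    if (length(other) > 0L) {
      fac2 <- if (f >= 2L) 2L else 1L
      idx <- match(other, gene_ids)
      loadings[idx, fac2] <- loadings[idx, fac2] + config$signal_strength
    }

    expression <- loadings %*% scores +
      matrix(stats::rnorm(g * s, sd = config$noise_sd), g, s)
    dimnames(expression) <- list(gene_ids, sample_ids)

    metabolites <- matrix(
      rep(scores[1L, ], config$n_metabolites) +
        stats::rnorm(config$n_metabolites * s, sd = config$noise_sd),
      nrow = config$n_metabolites, byrow = TRUE,
      dimnames = list(sprintf("metab%02d", seq_len(config$n_metabolites)),
                      sample_ids)
    )

    truth <- stats::setNames(as.integer(gene_ids %in% positives), gene_ids)
    agree <- stats::rbinom(g, 1L, config$knowledge_accuracy) == 1L
    knowledge <- ifelse(agree, truth, 1L - truth)
    covered <- stats::rbinom(g, 1L, config$knowledge_coverage) == 1L
    knowledge[!covered] <- -1L
    knowledge <- stats::setNames(as.integer(knowledge), gene_ids)

    if (config$missing_frac > 0) {
      n_mask <- round(config$missing_frac * g * s)
      expression[sample.int(g * s, n_mask)] <- NA_real_
    }

    structure(
      list(expression = expression, metabolites = metabolites,
           knowledge = knowledge, truth = truth, positives = positives,
           metabolite_associated = assoc, config = config),
      class = "synthetic_dataset"
    )
  })
}

#' Write a synthetic dataset to the pipeline's on-disk formats
#'
#' Emits the same plain-text artifacts the pipeline reads from real data:
#' an expression TSV and metabolite TSV (rows x samples, `NA` for missing),
#' a two-column knowledge-score table and a GMT file holding the true
#' positive gene set, so synthetic fixtures and real inputs are
#' interchangeable.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory, created if absent.
#' @param term_id set name used in the GMT file.
#' @return Invisibly, a named list of the four file paths.
#' @export
write_dataset <- function(dataset, dir, term_id = "SYNTH:0001") {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    knowledge = file.path(dir, "knowledge.tsv"),
    gene_sets = file.path(dir, "positives.gmt")
  )
  write_omics_matrix(dataset$expression, paths$expression)
  write_omics_matrix(dataset$metabolites, paths$metabolites)
  utils::write.table(
    data.frame(gene_id = names(dataset$knowledge),
               score = unname(dataset$knowledge)),
    paths$knowledge, sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_gene_sets(stats::setNames(list(dataset$positives), term_id),
                  paths$gene_sets)
  invisible(paths)
}
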
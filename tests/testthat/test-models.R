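# Classifier wrappers, the bootstrap x CV regime, leakage auditing and
# the PC-variant ensemble.

sep_dataset <- function(seed = 1) {
  generate_dataset(synthetic_config(
    n_genes = 120, n_samples = 40, n_positive = 20, signal_strength = 4,
    noise_sd = 0.2, missing_frac = 0, knowledge_accuracy = 1,
    knowledge_coverage = 1, seed = seed))
}

sep_features <- function(ds, n_pc = 5) {
  pcs <- pca_gene_features(ds$expression, n_components = n_pc)
  assemble_features(pcs, n_pc, NULL, "hybrid")
}

test_that("all four classifier families emit probabilities in [0, 1]", {
  ds <- sep_dataset()
  feats <- sep_features(ds)
  plan <- make_split_plan(ds$positives, rownames(feats), 1, 2,
                          master_seed = 1)
  for (alg in c("random_forest", "decision_tree", "naive_bayes", "svm")) {
    cv <- cross_validate(feats, plan, model_spec(alg, seed = 3))
    expect_true(all(cv$prob >= 0 & cv$prob <= 1), info = alg)
    expect_equal(nrow(cv), 40L, info = alg)   # one prob per labeled gene
  }
})

test_that("separable features give near-perfect out-of-fold AUROC", {
  # knowledge scores with perfect accuracy and coverage make the hybrid
  # table exactly separable
  ds <- sep_dataset()
  pcs <- pca_gene_features(ds$expression, n_components = 5)
  feats <- assemble_features(pcs, 5, encode_knowledge(ds$knowledge),
                             "hybrid")
  plan <- make_split_plan(ds$positives, rownames(feats), 3, 5,
                          master_seed = 2)
  cv <- cross_validate(feats, plan, model_spec("random_forest", seed = 1))
  ev <- evaluate_cv(cv)
  expect_gte(ev$mean[["auroc"]], 0.99)
})

test_that("permuted labels give chance-level AUROC", {
  ds <- generate_dataset(synthetic_config(
    n_genes = 400, n_samples = 60, n_positive = 50, signal_strength = 0,
    missing_frac = 0, seed = 21))
  feats <- sep_features(ds)
  plan <- make_split_plan(ds$positives, rownames(feats), 20, 5,
                          master_seed = 4)
  cv <- cross_validate(feats, plan, model_spec("random_forest", seed = 5))
  ev <- evaluate_cv(cv)
  expect_gt(ev$mean[["auroc"]], 0.40)
  expect_lt(ev$mean[["auroc"]], 0.60)
})

test_that("no out-of-fold prediction comes from a model that saw the gene", {
  ds <- sep_dataset(seed = 3)
  feats <- sep_features(ds)
  positives <- ds$positives[1:6]
  plan <- make_split_plan(positives, rownames(feats), 2, 2,
                          master_seed = 6)
  cv <- cross_validate(feats, plan, model_spec("decision_tree", seed = 1))
  expect_true(audit_leakage(cv))
  # exhaustive membership audit on the 12-gene toy
  members <- attr(cv, "training_members")
  for (i in seq_len(nrow(cv))) {
    key <- sprintf("%d.%d", cv$bootstrap[i], cv$fold[i])
    expect_false(cv$gene_id[i] %in% members[[key]])
    # and the training set is the complement of the test fold
    it <- plan$iterations[[cv$bootstrap[i]]]
    expect_setequal(members[[key]],
                    names(it$folds)[it$folds != cv$fold[i]])
  }
})

test_that("degenerate folds and mismatched features raise errors", {
  ds <- sep_dataset(seed = 5)
  feats <- sep_features(ds)
  plan <- make_split_plan(ds$positives, rownames(feats), 1, 5,
                          master_seed = 1)
  spec <- model_spec("random_forest", seed = 1)
  models <- fit_full(feats, plan, spec)
  wrong <- feats[, c(2, 1, 3:5)]
  expect_error(predict_unlabeled(models, wrong), "mismatch")
  bad_plan <- make_split_plan(c("nope1", "nope2"), c("nope1", "nope2",
                                                     "nope3", "nope4"),
                              1, 2, 1)
  expect_error(cross_validate(feats, bad_plan, spec), "absent")
})

test_that("ensemble mean and SE follow the variant-committee formula", {
  vm <- matrix(c(0.6, 0.8, 0.5, 0.5), nrow = 2, byrow = TRUE,
               dimnames = list(c("gA", "gB"), c("pc5", "pc14")))
  ens <- ensemble_predictions(vm)
  expect_equal(ens$mean_prob, c(0.7, 0.5))
  expect_equal(ens$se[1], stats::sd(c(0.6, 0.8)) / sqrt(2))
  expect_equal(ens$se[1], 0.1, tolerance = 1e-12)
  expect_equal(ens$se[2], 0)           # equal variant means -> SE 0
  expect_equal(ens$n_models, c(2L, 2L))
  expect_equal(format_prob(0.7716, 0.023), "0.7716 (0.0230)")
})

test_that("identical master seed reproduces byte-identical predictions", {
  ds <- sep_dataset(seed = 9)
  cfg <- run_config(pc_counts = c(3L, 5L), n_bootstrap = 2L, seed = 31L)
  run <- function() {
    classify_term(ds$expression, ds$positives, cfg,
                  knowledge = ds$knowledge)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$predictions, f2$predictions)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tsv"); p2 <- file.path(dir, "b.tsv")
  write_predictions(f1$predictions, p1)
  write_predictions(f2$predictions, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("unlabeled-gene scoring skips models trained on the gene", {
  ds <- sep_dataset(seed = 11)
  feats <- sep_features(ds)
  plan <- make_split_plan(ds$positives, rownames(feats), 4, 2,
                          master_seed = 8)
  models <- fit_full(feats, plan, model_spec("random_forest", seed = 2))
  unlabeled <- setdiff(rownames(feats), ds$positives)
  p <- predict_unlabeled(models, feats[unlabeled, , drop = FALSE],
                         plan = plan)
  expect_length(p, length(unlabeled))
  expect_true(all(is.finite(p)))
  # a gene negative in every bootstrap would have no usable model; with 4
  # bootstraps of 20 negatives from a 100-gene pool that never happens here
  neg_counts <- table(unlist(lapply(plan$iterations, `[[`, "negatives")))
  expect_lt(max(neg_counts), length(plan$iterations))
})

test_that("the full grid covers algorithms x pc-counts x modes", {
  ds <- sep_dataset(seed = 13)
  cfg <- run_config(pc_counts = c(3L, 5L), n_bootstrap = 1L, n_folds = 3L,
                    seed = 17L)
  grid <- train_matrix(ds$expression, ds$positives, cfg,
                       knowledge = ds$knowledge,
                       algorithms = c("random_forest", "naive_bayes"))
  expect_equal(nrow(grid), 2 * 2 * 2)     # 2 algorithms x 2 pcs x 2 modes
  expect_setequal(unique(grid$mode), c("hybrid", "transcriptomics_only"))
  expect_true(all(grid$auroc >= 0 & grid$auroc <= 1))
  # equal feature budget across matched arms
  for (np in c(3, 5)) {
    widths <- unique(grid$n_features[grid$n_pc == np])
    expect_length(widths, 1L)
  }
})
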
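# Metabolite-correlation features, one-hot knowledge encoding and hybrid
# feature-table assembly.

make_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  toy_matrix(rnorm(n_genes * n_samples), nrow = n_genes)
}

test_that("Spearman rho matches the direct-formula oracle exactly", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(oracle_spearman(x, y), oracle_spearman_noties(x, y))
  expr <- toy_matrix(x, nrow = 1)
  metab <- toy_matrix(y, nrow = 1, genes = "m1")
  # alpha = 0.999 so the (non-significant) rho survives zeroing and the
  # Fisher transform can be inverted back to rho
  z <- metabolite_corr_features(expr, metab, alpha = 0.999)
  expect_equal(tanh(z[1, 1]), oracle_spearman_noties(x, y),
               tolerance = 1e-12)
})

test_that("feature equals Fisher z of the oracle rho on random data", {
  set.seed(31)
  for (rep in 1:5) {
    g <- rnorm(25)
    m <- 0.8 * g + rnorm(25, sd = 0.4)   # strong, significant
    expr <- toy_matrix(g, nrow = 1)
    metab <- toy_matrix(m, nrow = 1, genes = "m1")
    z <- metabolite_corr_features(expr, metab, alpha = 0.05)
    expect_equal(z[1, 1], oracle_fisher_z(oracle_spearman(g, m)),
                 tolerance = 1e-10)
  }
})

test_that("a gene identical to the metabolite stays finite after clamping", {
  set.seed(44)
  v <- rnorm(30)
  expr <- toy_matrix(v, nrow = 1)
  metab <- toy_matrix(v, nrow = 1, genes = "m1")
  z <- metabolite_corr_features(expr, metab)
  expect_true(is.finite(z[1, 1]))
  expect_gt(z[1, 1], 13)
  expect_equal(z[1, 1], atanh(1 - 1e-12))
})

test_that("independent pairs are zeroed at about the nominal rate", {
  set.seed(77)
  n_rep <- 1000
  expr <- make_expr(n_rep, 10, seed = 77)
  metab <- toy_matrix(rnorm(10), nrow = 1, genes = "m1")
  z <- metabolite_corr_features(expr, metab, alpha = 0.05)
  zero_rate <- mean(z == 0)
  expect_gt(zero_rate, 0.92)   # ~95% expected under the null
  expect_lt(zero_rate, 0.98)
})

test_that("zeroing is threshold-consistent and the transform is odd", {
  expr <- make_expr(200, 20, seed = 13)
  metab <- toy_matrix(rnorm(20), nrow = 1, genes = "m1")
  z_loose <- metabolite_corr_features(expr, metab, alpha = 0.10)
  z_tight <- metabolite_corr_features(expr, metab, alpha = 0.01)
  expect_true(all(z_tight[z_loose == 0] == 0))
  # oddness: negating the metabolite negates surviving features
  z_neg <- metabolite_corr_features(expr, -metab, alpha = 0.10)
  expect_equal(z_neg[, 1], -z_loose[, 1], tolerance = 1e-10)
})

test_that("constant gene rows give a zero feature and are logged", {
  expr <- make_expr(5, 12, seed = 2)
  expr[3, ] <- 4
  metab <- toy_matrix(rnorm(12), nrow = 1, genes = "m1")
  z <- metabolite_corr_features(expr, metab, alpha = 0.9)
  expect_equal(unname(z[3, 1]), 0)
  expect_equal(attr(z, "constant_genes"), "g3")
})

test_that("too few shared samples is an error", {
  expr <- make_expr(3, 3, seed = 4)
  metab <- toy_matrix(rnorm(3), nrow = 1, genes = "m1")
  expect_error(metabolite_corr_features(expr, metab), "4 shared samples")
})

test_that("knowledge one-hot encoding follows the two-column scheme", {
  scores <- c(g1 = 1, g2 = 0, g3 = -1)
  enc <- encode_knowledge(scores)
  expect_equal(unname(enc["g1", ]), c(1, 0))
  expect_equal(unname(enc["g2", ]), c(0, 1))
  expect_equal(unname(enc["g3", ]), c(0, 0))
  expect_equal(ncol(enc), 2L)
  expect_equal(unname(colSums(enc)), c(1, 1))
  # unknown genes default to the no-classification state
  enc2 <- encode_knowledge(scores, genes = c("g1", "g4"))
  expect_equal(unname(enc2["g4", ]), c(0, 0))
  expect_error(encode_knowledge(c(g1 = 2)), "g1")
})

test_that("hybrid and matched transcriptomics-only tables have equal width", {
  ds <- generate_dataset(synthetic_config(n_genes = 60, n_samples = 30,
                                          n_positive = 10, missing_frac = 0,
                                          seed = 6))
  pcs <- pca_gene_features(ds$expression, n_components = 10)
  enc <- encode_knowledge(ds$knowledge)
  hybrid <- assemble_features(pcs, 5, enc, "hybrid")
  matched <- assemble_features(pcs, 5, enc, "transcriptomics_only")
  expect_equal(ncol(hybrid), 7L)
  expect_equal(ncol(matched), 7L)
  expect_true(all(attr(matched, "provenance") == "pc"))
  expect_equal(sum(attr(hybrid, "provenance") == "pc"), 5L)
  # no extras: the two arms coincide
  a <- assemble_features(pcs, 4, NULL, "hybrid")
  b <- assemble_features(pcs, 4, NULL, "transcriptomics_only")
  expect_identical(a[, ], b[, ])
})

test_that("genes missing from the knowledge table are encoded, not dropped", {
  expr <- make_expr(3, 20, seed = 8)
  pcs <- pca_gene_features(expr, n_components = 3)
  enc <- encode_knowledge(c(g1 = 1, g2 = 0), genes = rownames(expr))
  tab <- assemble_features(pcs, 1, enc, "hybrid")
  expect_equal(nrow(tab), 3L)
  expect_equal(unname(tab["g3", c("knowledge_pos", "knowledge_neg")]),
               c(0, 0))
})

test_that("planted metabolite signal survives into the features", {
  ds <- generate_dataset(synthetic_config(
    n_genes = 300, n_samples = 60, n_positive = 30, signal_strength = 2,
    metabolite_assoc_frac = 1, missing_frac = 0, seed = 10))
  z <- metabolite_corr_features(ds$expression, ds$metabolites)
  assoc <- ds$metabolite_associated
  rest <- setdiff(rownames(z), assoc)
  expect_gt(mean(abs(z[assoc, 1])), mean(abs(z[rest, 1])))
})
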
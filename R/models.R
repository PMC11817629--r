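# Classifier wrappers and the bootstrap x cross-validation training
# regime. Four families are supported behind one interface: random forest,
# decision tree, Gaussian naive Bayes and RBF SVM with probability
# calibration. The probability reported always refers to the positive
# (annotated) class.

ALGORITHMS <- c("random_forest", "decision_tree", "naive_bayes", "svm")

#' Specify a classifier
#'
#' @param algorithm one of `"random_forest"`, `"decision_tree"`,
#'   `"naive_bayes"`, `"svm"`.
#' @param hyperparameters named list passed to the underlying fitter
#'   (e.g. `ntree` for random forest, `cost`/`gamma` for SVM). Defaults
#'   are library-conventional: 100 trees with sqrt-features per split for
#'   the forest, unlimited-depth tree, Gaussian naive Bayes, RBF SVM with
#'   internal probability calibration.
#' @param seed seed used for every stochastic fit with this spec.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(algorithm = "random_forest",
                       hyperparameters = list(), seed = 1L) {
  if (!algorithm %in% ALGORITHMS) {
    stop_field("algorithm",
               paste("must be one of:", paste(ALGORITHMS, collapse = ", ")))
  }
  if (!is.list(hyperparameters)) {
    stop_field("hyperparameters", "must be a list")
  }
  structure(list(algorithm = algorithm,
                 hyperparameters = hyperparameters,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "model_spec")
}

# Fit one classifier on a feature matrix and a binary label vector
# (1 = positive). Returns an object predict_prob() understands.
fit_classifier <- function(x, y, spec) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: single class", call. = FALSE)
  }
  yf <- factor(ifelse(y == 1, "pos", "neg"), levels = c("neg", "pos"))
  hp <- spec$hyperparameters
  df <- data.frame(x, check.names = FALSE)
  default <- function(key, value) if (is.null(hp[[key]])) value else hp[[key]]
  fit <- with_seed(spec$seed, switch(
    spec$algorithm,
    random_forest = randomForest::randomForest(
      x = x, y = yf, ntree = default("ntree", 100L),
      mtry = default("mtry", floor(sqrt(ncol(x))))),
    decision_tree = rpart::rpart(
      .label ~ ., data = cbind(df, .label = yf), method = "class",
      control = default("control", rpart::rpart.control())),
    naive_bayes = e1071::naiveBayes(
      x = df, y = yf, laplace = default("laplace", 0)),
    svm = e1071::svm(
      x = x, y = yf, probability = TRUE,
      kernel = default("kernel", "radial"),
      cost = default("cost", 1),
      gamma = default("gamma", 1 / ncol(x)))
  ))
  structure(list(fit = fit, algorithm = spec$algorithm,
                 features = colnames(x)),
            class = "go_classifier")
}

# Positive-class probability for new genes.
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "go_classifier"), is.matrix(x))
  if (!identical(colnames(x), model$features)) {
    stop("feature-dimension mismatch between training and prediction ",
         "tables", call. = FALSE)
  }
  df <- data.frame(x, check.names = FALSE)
  p <- switch(
    model$algorithm,
    random_forest = stats::predict(model$fit, x, type = "prob")[, "pos"],
    decision_tree = stats::predict(model$fit, df, type = "prob")[, "pos"],
    naive_bayes = stats::predict(model$fit, df, type = "raw")[, "pos"],
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "pos"]
    }
  )
  stats::setNames(pmin(pmax(as.numeric(p), 0), 1), rownames(x))
}

#' Out-of-fold probabilities under the bootstrap x CV regime
#'
#' For every bootstrap iteration of the plan and every fold, a model is
#' trained on the other folds only and predicts the held-out genes, so
#' each labeled gene receives exactly one out-of-fold probability per
#' bootstrap. Per-fit seeds are derived from `spec$seed` and the iteration
#' seed, making the whole result deterministic.
#'
#' @param features gene x feature matrix (see [assemble_features()]).
#' @param plan a [make_split_plan()] result.
#' @param spec a [model_spec()].
#' @return Data frame with columns `bootstrap`, `fold`, `gene_id`,
#'   `label`, `prob`, plus a `training_members` attribute (list keyed
#'   `"<bootstrap>.<fold>"` of the gene IDs each fold model was trained
#'   on) used by [audit_leakage()].
#' @export
cross_validate <- function(features, plan, spec) {
  stopifnot(inherits(plan, "split_plan"), inherits(spec, "model_spec"))
  out <- vector("list", length(plan$iterations))
  members <- list()
  for (b in seq_along(plan$iterations)) {
    it <- plan$iterations[[b]]
    genes <- names(it$folds)
    miss <- setdiff(genes, rownames(features))
    if (length(miss) > 0L) {
      stop("plan genes absent from feature table: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    }
    labels <- stats::setNames(as.integer(genes %in% plan$positives), genes)
    rows <- vector("list", plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      test <- genes[it$folds == f]
      train <- genes[it$folds != f]
      if (length(unique(labels[train])) < 2L) {
        stop(sprintf("degenerate training fold: bootstrap %d, fold %d",
                     b, f), call. = FALSE)
      }
      fold_spec <- spec
      fold_spec$seed <- (spec$seed + it$seed + f) %% .Machine$integer.max
      model <- fit_classifier(features[train, , drop = FALSE],
                              labels[train], fold_spec)
      p <- predict_prob(model, features[test, , drop = FALSE])
      members[[sprintf("%d.%d", b, f)]] <- train
      rows[[f]] <- data.frame(bootstrap = b, fold = f, gene_id = test,
                              label = unname(labels[test]),
                              prob = unname(p))
    }
    out[[b]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "training_members") <- members
  res
}

#' Audit cross-validation results for train/test leakage
#'
#' Verifies that no out-of-fold prediction came from a model whose
#' training rows contained the predicted gene.
#'
#' @param cv result of [cross_validate()].
#' @return `TRUE` (invisibly) if clean; otherwise an error naming the
#'   offending bootstrap/fold.
#' @export
audit_leakage <- function(cv) {
  members <- attr(cv, "training_members")
  if (is.null(members)) {
    stop("cv result carries no training-membership record", call. = FALSE)
  }
  for (i in seq_len(nrow(cv))) {
    key <- sprintf("%d.%d", cv$bootstrap[i], cv$fold[i])
    if (cv$gene_id[i] %in% members[[key]]) {
      stop(sprintf("leakage: gene %s predicted by bootstrap %d fold %d",
                   cv$gene_id[i], cv$bootstrap[i], cv$fold[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Fit one full-data model per bootstrap iteration
#'
#' Trains on each iteration's complete balanced set (all folds pooled);
#' these are the models used to score unlabeled genes.
#'
#' @inheritParams cross_validate
#' @return List of `go_classifier` objects, one per bootstrap.
#' @export
fit_full <- function(features, plan, spec) {
  stopifnot(inherits(plan, "split_plan"), inherits(spec, "model_spec"))
  lapply(seq_along(plan$iterations), function(b) {
    it <- plan$iterations[[b]]
    genes <- names(it$folds)
    labels <- as.integer(genes %in% plan$positives)
    full_spec <- spec
    full_spec$seed <- (spec$seed + it$seed) %% .Machine$integer.max
    fit_classifier(features[genes, , drop = FALSE], labels, full_spec)
  })
}

#' Score unlabeled genes with a committee of bootstrap models
#'
#' Averages each gene's positive-class probability over the bootstrap
#' models. If the split plan is supplied, a gene's average skips any
#' bootstrap in which that gene was itself drawn as a training negative,
#' so no prediction comes from a model that saw the gene in training.
#'
#' @param models list of models from [fit_full()].
#' @param features_unlabeled gene x feature matrix for the genes to score
#'   (same feature columns as in training).
#' @param plan optional [make_split_plan()] used to exclude, per gene,
#'   models trained on it.
#' @return Named vector: per-gene probability averaged over the (retained)
#'   bootstrap models.
#' @export
predict_unlabeled <- function(models, features_unlabeled, plan = NULL) {
  probs <- vapply(models, predict_prob, numeric(nrow(features_unlabeled)),
                  x = features_unlabeled)
  if (is.null(dim(probs))) {
    probs <- matrix(probs, nrow = nrow(features_unlabeled))
  }
  if (!is.null(plan)) {
    for (b in seq_along(plan$iterations)) {
      seen <- rownames(features_unlabeled) %in%
        names(plan$iterations[[b]]$folds)
      probs[seen, b] <- NA_real_
    }
  }
  stats::setNames(rowMeans(probs, na.rm = TRUE),
                  rownames(features_unlabeled))
}

#' Combine per-variant probabilities into a mean +/- SE ensemble
#'
#' Given one mean probability per gene from each PC-count model variant,
#' reports their arithmetic mean and the standard error across variants
#' (sample standard deviation of the variant means divided by the square
#' root of the number of variants).
#'
#' @param variant_means gene x variant numeric matrix of probabilities.
#' @return Data frame (a prediction table): `gene_id`, one `prob_<v>`
#'   column per variant, `mean_prob`, `se`, `n_models`.
#' @export
ensemble_predictions <- function(variant_means) {
  stopifnot(is.matrix(variant_means), !is.null(rownames(variant_means)))
  nv <- ncol(variant_means)
  mean_prob <- rowMeans(variant_means)
  se <- if (nv > 1L) {
    apply(variant_means, 1L, stats::sd) / sqrt(nv)
  } else {
    rep(0, nrow(variant_means))
  }
  out <- data.frame(gene_id = rownames(variant_means), variant_means,
                    mean_prob = mean_prob, se = se, n_models = nv,
                    row.names = NULL, check.names = FALSE)
  vcols <- colnames(variant_means)
  if (is.null(vcols)) vcols <- paste0("variant", seq_len(nv))
  colnames(out)[1L + seq_len(nv)] <- paste0("prob_", vcols)
  out
}

#' Format an ensemble probability as "mean (SE)"
#'
#' @param mean_prob,se numeric vectors.
#' @param digits decimal places (default 4).
#' @return Character vector like `"0.7716 (0.0230)"`.
#' @export
format_prob <- function(mean_prob, se, digits = 4L) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mean_prob, se)
}
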
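# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and the vectorized base-R shortcuts they use), so a match is
# evidence of correctness rather than of shared implementation.

# Average ranks by direct counting: rank(x_i) = #{x_j < x_i} + (#ties+1)/2.
oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

# Pearson correlation from the definitional sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Spearman rho as Pearson on explicitly counted average ranks.
oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_ranks(x), oracle_ranks(y))
}

# Tie-free Spearman from the classical 1 - 6*sum(d^2)/(n(n^2-1)) identity.
oracle_spearman_noties <- function(x, y) {
  n <- length(x)
  d <- oracle_ranks(x) - oracle_ranks(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

oracle_fisher_z <- function(rho) 0.5 * log((1 + rho) / (1 - rho))

oracle_mcc <- function(tp, fp, fn, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# AUROC by exhaustive positive-negative pair enumeration, ties count 1/2.
oracle_auroc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# k-NN imputation by exhaustive distance enumeration: for every missing
# cell, list all other rows with their coverage-rescaled Euclidean
# distances, take the k nearest, and average their observed entries in the
# target column (column mean if none observed).
oracle_knn_impute <- function(m, k) {
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (!is.na(m[i, j])) next
      d <- rep(Inf, nrow(m))
      for (r in seq_len(nrow(m))) {
        if (r == i) next
        s <- 0
        used <- 0
        for (c in seq_len(ncol(m))) {
          if (!is.na(m[i, c]) && !is.na(m[r, c])) {
            s <- s + (m[i, c] - m[r, c])^2
            used <- used + 1
          }
        }
        if (used > 0) d[r] <- sqrt(s / used * ncol(m))
      }
      nn <- order(d, seq_along(d))[seq_len(min(k, nrow(m) - 1))]
      vals <- m[nn, j]
      vals <- vals[!is.na(vals)]
      out[i, j] <- if (length(vals) > 0) {
        mean(vals)
      } else {
        mean(m[, j], na.rm = TRUE)
      }
    }
  }
  out
}

# Small labeled matrix with dimnames for reader/filter tests.
toy_matrix <- function(values, nrow, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
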
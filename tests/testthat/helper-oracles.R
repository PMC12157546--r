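# Independent oracles the implementation is checked against.

# Exhaustive pair-counting ARI: classify every object pair as co-clustered
# or not in each partition, then apply the adjusted formula directly.
# O(n^2); usable only at small n, and deliberately independent of the
# contingency-table code path.
oracle_ari <- function(l1, l2) {
  n <- length(l1)
  together_both <- 0
  together_1 <- 0
  together_2 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      t1 <- l1[i] == l1[j]
      t2 <- l2[i] == l2[j]
      if (t1 && t2) together_both <- together_both + 1
      if (t1) together_1 <- together_1 + 1
      if (t2) together_2 <- together_2 + 1
    }
  }
  cn <- n * (n - 1) / 2
  expected <- together_1 * together_2 / cn
  max_index <- 0.5 * (together_1 + together_2)
  if (max_index == expected) return(0)
  (together_both - expected) / (max_index - expected)
}

# Build a ccc_partition from explicit 0-based labels.
make_partition <- function(labels) {
  categorical_partition(letters[labels + 1L])
}

# Naive all-vs-all CCC: a double loop of independent ccc_pair() calls.
naive_ccc_condensed <- function(mat, ...) {
  n <- nrow(mat)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      out <- c(out, ccc_pair(mat[i, ], mat[j, ], ...)$ccc)
    }
  }
  out
}

# Textbook direct-formula Pearson; Spearman as Pearson on midranks.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Random 0-based label vector with at least two distinct labels.
rand_labels <- function(n, kmax) {
  repeat {
    l <- sample.int(kmax, n, replace = TRUE) - 1L
    if (length(unique(l)) >= 2L) return(l)
  }
}

# Wide expression tibble from a features-by-samples matrix.
as_expr_tbl <- function(mat, ids = sprintf("G%04d", seq_len(nrow(mat)))) {
  tibble::as_tibble(cbind(
    tibble::tibble(feature_id = ids),
    stats::setNames(as.data.frame(mat), sprintf("S%04d", seq_len(ncol(mat))))
  ))
}
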
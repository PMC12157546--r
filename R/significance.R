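#' Permutation test for one CCC
#'
#' Tests the null hypothesis of no association by recomputing the CCC
#' after independently permuting the sample order of `y`, which breaks the
#' pairing while preserving both marginal distributions. Because quantile
#' and categorical partitions are permutation equivariant, the null
#' coefficients reuse the observed partitions with relabelled samples,
#' which keeps even large permutation counts cheap.
#'
#' The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never zero and
#' its smallest attainable value is `1 / (n_perm + 1)`.
#'
#' @inheritParams ccc_pair
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; the test is fully deterministic given it.
#' @return A `ccc_perm_test` object: `observed`, `p_value`, `null_values`,
#'   `n_perm`, `seed`, `n_used`. Supports [generics::tidy()],
#'   [generics::glance()] and `autoplot()`.
#' @export
ccc_perm_test <- function(x, y, n_perm = 999, seed = 1L, k_range = 2:10,
                          min_pairwise_samples = 10) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (length(x) != length(y)) {
    stop("`x` and `y` must share sample ordering and length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  n_used <- sum(ok)
  if (n_used < max(min_pairwise_samples, 2L)) {
    stop("too few complete observations to test this pair", call. = FALSE)
  }
  px <- precompute_partitions(x[ok], feature_type(x), k_range)
  py <- precompute_partitions(y[ok], feature_type(y), k_range)
  obs <- ccc_from_sets(px, py)
  if (is.na(obs$ccc)) {
    stop("pair has no valid partition combination; cannot test", call. = FALSE)
  }
  mx <- vapply(px, `[[`, integer(n_used), "labels")
  my <- vapply(py, `[[`, integer(n_used), "labels")
  null_values <- with_seed(seed, {
    perms <- vapply(
      seq_len(n_perm), function(t) sample.int(n_used) - 1L,
      integer(n_used)
    )
    ccc_perm_null_cpp(
      matrix(mx, nrow = n_used), vapply(px, `[[`, integer(1), "k"),
      vapply(px, `[[`, logical(1), "valid"),
      matrix(my, nrow = n_used), vapply(py, `[[`, integer(1), "k"),
      vapply(py, `[[`, logical(1), "valid"),
      matrix(perms, nrow = n_used)
    )
  })
  structure(
    list(
      observed = obs$ccc,
      p_value = (1 + sum(null_values >= obs$ccc)) / (1 + n_perm),
      null_values = as.numeric(null_values),
      n_perm = as.integer(n_perm),
      seed = as.integer(seed),
      n_used = n_used,
      best_k_x = obs$best_k_x,
      best_k_y = obs$best_k_y
    ),
    class = "ccc_perm_test"
  )
}

#' @export
print.ccc_perm_test <- function(x, ...) {
  cat("Permutation test for the Clustermatch Correlation Coefficient\n")
  cat(sprintf(
    "  observed CCC = %.4f (k = %d x %d, n = %d)\n",
    x$observed, x$best_k_x, x$best_k_y, x$n_used
  ))
  cat(sprintf(
    "  p = %.4g from %d permutations (seed %d)\n",
    x$p_value, x$n_perm, x$seed
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ccc_perm_test
#' @param x A `ccc_perm_test` object.
#' @param ... Unused; for generic consistency.
#' @exportS3Method generics::tidy
tidy.ccc_perm_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$observed,
    p.value = x$p_value,
    method = "CCC permutation test",
    alternative = "greater"
  )
}

#' @rdname ccc_perm_test
#' @exportS3Method generics::glance
glance.ccc_perm_test <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm, n_used = x$n_used, seed = x$seed,
    null_mean = mean(x$null_values), null_q95 = unname(
      stats::quantile(x$null_values, 0.95, type = 7)
    )
  )
}

#' Pooled permutation threshold for "high" coefficients
#'
#' Builds a dataset-level null distribution by repeatedly drawing a random
#' feature pair (uniformly, with replacement), permuting one member's
#' sample order, and recomputing the CCC; returns the `q`-quantile of the
#' pooled null. Coefficients above this threshold are unlikely under
#' independence anywhere in the dataset, making it a permutation-derived
#' alternative to percentile tiering.
#'
#' @inheritParams ccc_pairwise
#' @param n_perm Number of pooled null draws (default 500).
#' @param q Quantile level of the null used as threshold (default 0.99).
#' @param seed Integer seed; the threshold is deterministic given it.
#' @return Scalar threshold, with the pooled null draws attached as
#'   attribute `"null_values"`.
#' @export
ccc_null_threshold <- function(data, n_perm = 500, q = 0.99, seed = 1L,
                               k_range = 2:10, min_pairwise_samples = 10) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (length(q) != 1L || q <= 0 || q > 1) {
    stop("`q` must lie in (0, 1]", call. = FALSE)
  }
  feats <- parse_features(data)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(t) {
      ij <- sample.int(feats$n_features, 2L, replace = FALSE)
      x <- feats$mat[ij[1L], ]
      y <- feats$mat[ij[2L], ]
      y <- y[sample.int(length(y))]
      ccc_pair(x, y,
        k_range = k_range,
        min_pairwise_samples = min_pairwise_samples
      )$ccc
    }, numeric(1))
  })
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) == 0L) {
    stop("no computable null draws; features too degenerate", call. = FALSE)
  }
  out <- unname(stats::quantile(null_values, q, type = 7))
  attr(out, "null_values") <- null_values
  out
}
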
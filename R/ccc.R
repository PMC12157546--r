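#' Clustermatch Correlation Coefficient for one feature pair
#'
#' The CCC asks how well any coarse grouping of the samples by one feature
#' predicts a grouping by the other. Each numeric feature is partitioned by
#' empirical quantiles at every cluster count in `k_range`; a categorical
#' feature contributes the single partition its labels induce. The CCC is
#' the maximum Adjusted Rand Index over all valid partition combinations,
#' clipped below at zero, so it lies in `[0, 1]`, equals 1 for any
#' deterministic monotone relationship (and many non-monotone ones), and
#' sits near 0 for independent features. Because it only compares
#' partitions, it applies unchanged to numeric, categorical, and mixed
#' pairs.
#'
#' Samples missing in either feature are removed pairwise before
#' partitioning. Pairs with fewer than `min_pairwise_samples` complete
#' observations, or with no valid partition combination, yield `NA` rather
#' than an error so that all-vs-all scans continue past degenerate
#' features.
#'
#' @param x,y Feature vectors over the same samples: numeric, or
#'   character/factor for categorical features.
#' @param k_range Cluster counts for quantile partitioning of numeric
#'   features (default `2:10`).
#' @param min_pairwise_samples Minimum complete observations required to
#'   report a coefficient (default 10).
#' @return One-row tibble: `ccc` (the coefficient), `best_k_x` and
#'   `best_k_y` (cluster counts of the maximising partition pair, ties
#'   broken toward the smallest `k_x` then `k_y`), and `n_used` (samples
#'   after pairwise missing removal).
#' @examples
#' x <- seq_len(20)
#' ccc_pair(x, exp(x))$ccc # 1: monotone transforms preserve all partitions
#' @export
ccc_pair <- function(x, y, k_range = 2:10, min_pairwise_samples = 10) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must share sample ordering and length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  n_used <- sum(ok)
  if (n_used < max(min_pairwise_samples, 2L)) {
    return(tibble::tibble(
      ccc = NA_real_, best_k_x = NA_integer_, best_k_y = NA_integer_,
      n_used = n_used
    ))
  }
  px <- precompute_partitions(x[ok], feature_type(x), k_range)
  py <- precompute_partitions(y[ok], feature_type(y), k_range)
  res <- ccc_from_sets(px, py)
  tibble::tibble(
    ccc = res$ccc, best_k_x = res$best_k_x, best_k_y = res$best_k_y,
    n_used = n_used
  )
}

# Max-ARI over valid partition combinations, clipped at zero. Pure R path;
# loop order (ascending k_x, then k_y, strict >) fixes the argmax tie-break
# and matches the compiled kernel.
ccc_from_sets <- function(px, py) {
  best <- NA_real_
  bkx <- NA_integer_
  bky <- NA_integer_
  any_valid <- FALSE
  for (u in seq_along(px)) {
    if (!px[[u]]$valid) next
    for (v in seq_along(py)) {
      if (!py[[v]]$valid) next
      r <- ari_labels(px[[u]]$labels, py[[v]]$labels, px[[u]]$k, py[[v]]$k)
      if (!any_valid || r > best) {
        best <- r
        bkx <- px[[u]]$k
        bky <- py[[v]]$k
        any_valid <- TRUE
      }
    }
  }
  if (!any_valid) {
    list(ccc = NA_real_, best_k_x = NA_integer_, best_k_y = NA_integer_)
  } else {
    list(ccc = max(0, best), best_k_x = bkx, best_k_y = bky)
  }
}

#' All-vs-all CCC over an expression matrix
#'
#' Computes the CCC for every pair of features, reusing each feature's
#' quantile partitions across all its pairs. Rows come back in condensed
#' upper-triangle order (see [condensed_index()]): pair `(i, j)` with
#' `i < j` ordered by `i` then `j`.
#'
#' The `"parallel"` backend runs the compiled kernel over contiguous chunks
#' of condensed indices; because every cell writes only its own slot, the
#' result is bit-identical for any `chunk_size` and to the `"reference"`
#' pure-R loop. Pairs that cannot be computed (too few complete
#' observations, no valid partitions) carry `NA` instead of aborting the
#' scan. Features containing missing values fall back to per-pair
#' partitioning on pairwise-complete samples.
#'
#' @param data Expression data: wide tibble whose first column holds
#'   feature IDs and remaining (numeric) columns one sample each, or a
#'   numeric features-by-samples matrix with rownames.
#' @param k_range,min_pairwise_samples See [ccc_pair()].
#' @param backend `"parallel"` (compiled, chunked; default) or
#'   `"reference"` (plain loop of [ccc_pair()] calls).
#' @param chunk_size Number of condensed cells per kernel chunk; affects
#'   execution only, never results.
#' @return Tibble with one row per feature pair in condensed order:
#'   `feature_i`, `feature_j`, `ccc`, `best_k_x`, `best_k_y`, `n_used`.
#' @export
ccc_pairwise <- function(data, k_range = 2:10, min_pairwise_samples = 10,
                         backend = c("parallel", "reference"),
                         chunk_size = 4096L) {
  backend <- match.arg(backend)
  feats <- parse_features(data)
  n_feat <- feats$n_features
  n <- feats$n_samples
  pairs <- condensed_pairs(n_feat)
  ids_i <- feats$ids[pairs$i]
  ids_j <- feats$ids[pairs$j]

  if (backend == "reference") {
    rows <- purrr::map2(pairs$i, pairs$j, function(i, j) {
      ccc_pair(feats$mat[i, ], feats$mat[j, ],
        k_range = k_range,
        min_pairwise_samples = min_pairwise_samples
      )
    })
    out <- dplyr::bind_rows(rows)
    return(tibble::tibble(feature_i = ids_i, feature_j = ids_j, out))
  }

  has_na <- apply(feats$mat, 1L, anyNA)
  k_range <- sort(unique(as.integer(k_range)))
  part_sets <- vector("list", n_feat)
  for (f in seq_len(n_feat)) {
    if (!has_na[f]) {
      part_sets[[f]] <- precompute_partitions(feats$mat[f, ], "numeric", k_range)
    }
  }
  np <- ifelse(has_na, 0L, length(k_range))
  off <- cumsum(c(0L, np))[seq_len(n_feat)]
  clean <- which(!has_na)
  if (length(clean) > 0L) {
    labels <- matrix(0L, nrow = n, ncol = sum(np))
    part_k <- integer(sum(np))
    part_valid <- integer(sum(np))
    for (f in clean) {
      for (u in seq_along(part_sets[[f]])) {
        col <- off[f] + u
        labels[, col] <- part_sets[[f]][[u]]$labels
        part_k[col] <- part_sets[[f]][[u]]$k
        part_valid[col] <- as.integer(part_sets[[f]][[u]]$valid)
      }
    }
  } else {
    labels <- matrix(0L, nrow = n, ncol = 0L)
    part_k <- integer(0)
    part_valid <- integer(0)
  }
  if (n < max(min_pairwise_samples, 2L)) {
    # no pair can satisfy the sample threshold on complete features
    part_valid[] <- 0L
  }
  res <- ccc_condensed_cpp(
    labels, part_k, part_valid, off, np,
    pairs$i - 1L, pairs$j - 1L, as.integer(chunk_size)
  )
  out <- tibble::tibble(
    feature_i = ids_i, feature_j = ids_j,
    ccc = as.numeric(res$ccc),
    best_k_x = as.integer(res$best_k_x),
    best_k_y = as.integer(res$best_k_y),
    n_used = n
  )
  # pairs touching a feature with missing values: per-pair fallback
  redo <- which(has_na[pairs$i] | has_na[pairs$j])
  if (length(redo) > 0L) {
    for (idx in redo) {
      row <- ccc_pair(
        feats$mat[pairs$i[idx], ], feats$mat[pairs$j[idx], ],
        k_range = k_range, min_pairwise_samples = min_pairwise_samples
      )
      out$ccc[idx] <- row$ccc
      out$best_k_x[idx] <- row$best_k_x
      out$best_k_y[idx] <- row$best_k_y
      out$n_used[idx] <- row$n_used
    }
  }
  if (n < max(min_pairwise_samples, 2L)) {
    out$ccc <- NA_real_
    out$best_k_x <- NA_integer_
    out$best_k_y <- NA_integer_
  }
  out
}
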
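#' Partition a numeric feature by empirical quantiles
#'
#' Assigns each sample to one of `k` clusters by cutting the feature's
#' empirical distribution at quantile boundaries, giving clusters of
#' near-equal size. Labels are monotone in the value rank: larger values
#' never receive a smaller label. Tied values always share a label, which
#' is what makes the assignment invariant under any strictly increasing
#' transform of the data.
#'
#' The assignment rule is `label = min(floor(q * k), k - 1)` where
#' `q = (midrank - 0.5) / n` is the empirical midrank percentile of each
#' value. Under heavy ties clusters may be unequal or empty; a partition
#' with fewer than two non-empty clusters is flagged invalid.
#'
#' @param values Numeric vector with no missing values (missing samples are
#'   removed pairwise upstream, before partitioning).
#' @param k Intended number of clusters, an integer `>= 2`.
#' @return A `ccc_partition`: list with `labels` (integer vector in
#'   `0..k-1`), `k`, `n_effective` (non-empty clusters), and `valid`
#'   (`TRUE` iff `n_effective >= 2` and `k` does not exceed the sample count).
#' @examples
#' quantile_partition(c(10, 20, 30, 40), k = 2)$labels # 0 0 1 1
#' @export
quantile_partition <- function(values, k) {
  if (length(k) != 1L || is.na(k) || k < 2) {
    stop("`k` must be a single integer >= 2", call. = FALSE)
  }
  if (length(values) == 0L) {
    stop("cannot partition an empty vector", call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite and non-missing", call. = FALSE)
  }
  k <- as.integer(k)
  n <- length(values)
  q <- (rank(values, ties.method = "average") - 0.5) / n
  labels <- pmin(as.integer(floor(q * k)), k - 1L)
  new_partition(labels, k, n_max = n)
}

#' Partition samples by a categorical label
#'
#' Each distinct category becomes one cluster. The category-to-integer
#' mapping is lexicographic on the category names, so the labelling is
#' reproducible across runs and platforms.
#'
#' @param labels Character or factor vector of category labels; `NA`s must
#'   already be removed (pairwise, upstream).
#' @return A `ccc_partition` with `k` equal to the number of distinct
#'   categories; invalid when only one category is present.
#' @examples
#' categorical_partition(c("M", "F", "F", "M"))$labels # 1 0 0 1
#' @export
categorical_partition <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L || all(is.na(labels))) {
    stop("no non-missing category labels to partition", call. = FALSE)
  }
  if (anyNA(labels)) {
    stop("`labels` must be non-missing (remove NAs pairwise first)", call. = FALSE)
  }
  lev <- sort(unique(labels))
  ints <- match(labels, lev) - 1L
  new_partition(ints, k = length(lev), n_max = length(labels))
}

new_partition <- function(labels, k, n_max) {
  n_eff <- length(unique(labels))
  structure(
    list(
      labels = labels,
      k = as.integer(k),
      n_effective = n_eff,
      valid = n_eff >= 2L && k <= n_max
    ),
    class = "ccc_partition"
  )
}

#' @export
print.ccc_partition <- function(x, ...) {
  cat(sprintf(
    "<ccc_partition> k = %d, n = %d, non-empty clusters = %d, valid = %s\n",
    x$k, length(x$labels), x$n_effective, x$valid
  ))
  invisible(x)
}

#' Precompute all partitions of one feature
#'
#' Numeric features get one quantile partition per cluster count in
#' `k_range`; categorical features induce exactly one partition from their
#' labels. Partitions are computed once per feature and reused across every
#' pair the feature participates in, which is what makes all-vs-all scans
#' affordable.
#'
#' @param values Feature values: numeric vector, or character/factor for a
#'   categorical feature. Must be free of missing values.
#' @param type `"numeric"` or `"categorical"`; inferred from `values` when
#'   `NULL`.
#' @param k_range Integer vector of cluster counts (all `>= 2`); ignored for
#'   categorical features. Default `2:10`.
#' @return A list of `ccc_partition` objects (class `ccc_partition_set`).
#'   Entries with `k` exceeding the sample count are flagged invalid rather
#'   than dropped.
#' @export
precompute_partitions <- function(values, type = NULL, k_range = 2:10) {
  if (is.null(type)) {
    type <- if (is.numeric(values)) "numeric" else "categorical"
  }
  type <- match.arg(type, c("numeric", "categorical"))
  if (type == "categorical") {
    out <- list(categorical_partition(values))
  } else {
    k_range <- sort(unique(as.integer(k_range)))
    if (length(k_range) == 0L || any(k_range < 2L)) {
      stop("`k_range` must be non-empty with all entries >= 2", call. = FALSE)
    }
    out <- lapply(k_range, function(k) quantile_partition(values, k))
  }
  structure(out, class = "ccc_partition_set")
}
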
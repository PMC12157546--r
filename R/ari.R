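#' Cross-tabulate two partitions
#'
#' Builds the contingency table feeding the Adjusted Rand Index: entry
#' `(i, j)` counts the samples assigned to cluster `i` of the first
#' partition and cluster `j` of the second.
#'
#' @param p1,p2 `ccc_partition` objects (see [quantile_partition()]) of
#'   equal length.
#' @return Integer matrix of counts with `p1$k` rows and `p2$k` columns.
#' @export
contingency_table <- function(p1, p2) {
  stopifnot(inherits(p1, "ccc_partition"), inherits(p2, "ccc_partition"))
  if (length(p1$labels) != length(p2$labels)) {
    stop("partitions have different lengths", call. = FALSE)
  }
  counts_from_labels(p1$labels, p2$labels, p1$k, p2$k)
}

counts_from_labels <- function(l1, l2, k1, k2) {
  cells <- tabulate(l1 * k2 + l2 + 1L, nbins = k1 * k2)
  matrix(cells, nrow = k1, ncol = k2, byrow = TRUE)
}

#' Adjusted Rand Index from a contingency table
#'
#' Chance-corrected agreement between two partitions of the same samples:
#' the observed number of sample pairs co-clustered in both partitions,
#' minus its expectation under random labellings with the same marginals,
#' scaled so identical partitions (up to cluster relabelling) score 1 and
#' independent ones score 0 in expectation.
#'
#' When the maximum index equals the expected index (both partitions
#' effectively trivial) the statistic carries no information and 0 is
#' returned; upstream code masks such partitions as invalid before this
#' point, so the branch is defensive.
#'
#' @param table Non-negative integer matrix of co-occurrence counts, as
#'   produced by [contingency_table()].
#' @return The ARI, a real number `<= 1`.
#' @examples
#' p <- quantile_partition(1:4, 2)
#' adjusted_rand_index(contingency_table(p, p)) # 1
#' @export
adjusted_rand_index <- function(table) {
  tab <- as.matrix(table)
  n <- sum(tab)
  if (n < 2) stop("ARI needs at least two samples", call. = FALSE)
  ari_from_counts(
    cells = as.numeric(tab),
    a = as.numeric(rowSums(tab)),
    b = as.numeric(colSums(tab)),
    n = as.numeric(n)
  )
}

# Scalar ARI core. The arithmetic here (pair counts as m*(m-1)/2 on doubles,
# expected index as ca*cb/cn, max index as 0.5*(ca+cb)) is mirrored
# expression-for-expression in the compiled kernel so that the reference and
# parallel backends agree bit-for-bit: every pair-count sum is an
# integer-valued double below 2^53 and therefore exact in any order.
ari_from_counts <- function(cells, a, b, n) {
  sij <- sum(cells * (cells - 1) / 2)
  ca <- sum(a * (a - 1) / 2)
  cb <- sum(b * (b - 1) / 2)
  cn <- n * (n - 1) / 2
  expected <- ca * cb / cn
  max_index <- 0.5 * (ca + cb)
  den <- max_index - expected
  if (den == 0) return(0)
  (sij - expected) / den
}

ari_labels <- function(l1, l2, k1, k2) {
  n <- length(l1)
  a <- as.numeric(tabulate(l1 + 1L, nbins = k1))
  b <- as.numeric(tabulate(l2 + 1L, nbins = k2))
  cells <- as.numeric(tabulate(l1 * k2 + l2 + 1L, nbins = k1 * k2))
  ari_from_counts(cells, a, b, as.numeric(n))
}

#' Batched ARI over two partition sets
#'
#' Evaluates the Adjusted Rand Index for every combination of one partition
#' from `px` and one from `py`. This cross-product over cluster counts is
#' the inner loop of the CCC and the computation worth parallelising; the
#' `"parallel"` backend evaluates cells in deterministic chunks through the
#' compiled kernel and is bit-identical to the plain `"reference"` loop.
#'
#' @param px,py `ccc_partition_set` objects (see [precompute_partitions()])
#'   whose partitions all share one sample count.
#' @param backend `"reference"` (pure R loop) or `"parallel"` (compiled,
#'   chunked). Results are identical; only the execution strategy differs.
#' @return List with `values`, a `length(px) x length(py)` numeric matrix
#'   (`NA` where either partition is invalid), and `valid`, the
#'   corresponding logical mask.
#' @export
ari_batch <- function(px, py, backend = c("parallel", "reference")) {
  backend <- match.arg(backend)
  lx <- vapply(px, function(p) length(p$labels), integer(1))
  ly <- vapply(py, function(p) length(p$labels), integer(1))
  if (length(unique(c(lx, ly))) != 1L) {
    stop("all partitions must share one sample count", call. = FALSE)
  }
  vx <- vapply(px, `[[`, logical(1), "valid")
  vy <- vapply(py, `[[`, logical(1), "valid")
  valid <- outer(vx, vy, `&`)
  if (backend == "parallel") {
    mx <- vapply(px, `[[`, integer(lx[1]), "labels")
    my <- vapply(py, `[[`, integer(ly[1]), "labels")
    kx <- vapply(px, `[[`, integer(1), "k")
    ky <- vapply(py, `[[`, integer(1), "k")
    values <- ari_batch_cpp(
      matrix(mx, nrow = lx[1]), matrix(my, nrow = ly[1]),
      kx, ky, vx, vy
    )
  } else {
    values <- matrix(NA_real_, length(px), length(py))
    for (u in seq_along(px)) {
      for (v in seq_along(py)) {
        if (valid[u, v]) {
          values[u, v] <- ari_labels(
            px[[u]]$labels, py[[v]]$labels, px[[u]]$k, py[[v]]$k
          )
        }
      }
    }
  }
  list(values = values, valid = valid)
}
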
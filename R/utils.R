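`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a local RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Condensed index of a feature pair
#'
#' Maps an ordered pair `(i, j)` with `1 <= i < j <= n` to its 1-based
#' position in the condensed upper-triangle layout used by
#' [ccc_pairwise()] and [linear_coefficients()]: pairs are ordered by the
#' first feature, then the second, so `(1,2)` comes first and `(n-1, n)`
#' last. The mapping is a bijection onto `1..n(n-1)/2`.
#'
#' @param i,j Feature positions (vectors recycle); must satisfy `i < j <= n`.
#' @param n Total number of features.
#' @return Integer vector of condensed positions.
#' @examples
#' condensed_index(1, 2, 4) # 1
#' condensed_index(3, 4, 4) # 6
#' @export
condensed_index <- function(i, j, n) {
  if (any(i < 1 | j <= i | j > n)) {
    stop("need 1 <= i < j <= n", call. = FALSE)
  }
  as.integer((i - 1) * n - (i - 1) * i / 2 + (j - i))
}

# All pairs (i, j), i < j, in condensed order.
condensed_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  list(i = i, j = j)
}

# Strict upper triangle of a square matrix in condensed (row-major) order.
condensed_from_matrix <- function(m) {
  t(m)[lower.tri(m)]
}
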
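test_that("condensed index is the bijection onto 1..n(n-1)/2", {
  expect_identical(condensed_index(1, 2, 4), 1L)
  expect_identical(condensed_index(3, 4, 4), 6L)
  pairs <- expand.grid(i = 1:6, j = 1:6)
  pairs <- pairs[pairs$i < pairs$j, ]
  idx <- condensed_index(pairs$i, pairs$j, 6)
  expect_identical(sort(idx), 1:15)
  expect_error(condensed_index(3, 3, 4), "i < j")
  expect_error(condensed_index(2, 5, 4), "i < j")
})

test_that("CCC is exactly 1 for deterministic monotone relationships", {
  x <- as.numeric(1:20)
  expect_identical(ccc_pair(x, x)$ccc, 1)
  expect_identical(ccc_pair(x, exp(x))$ccc, 1)

  # numeric against the matching binary categorical split
  x12 <- as.numeric(1:12)
  y_cat <- ifelse(x12 > median(x12), "above", "below")
  res <- ccc_pair(x12, y_cat)
  expect_identical(res$ccc, 1)
  expect_identical(res$best_k_x, 2L)
})

test_that("CCC on a symmetric quadratic matches the naive per-k-pair maximum", {
  d <- simulate_pair("quadratic", n_samples = 100, noise_sd = 0.05, seed = 21)
  got <- ccc_pair(d$x, d$y)

  # naive double loop over the k grid, through the public ARI surface
  best <- -Inf
  for (kx in 2:10) {
    for (ky in 2:10) {
      px <- quantile_partition(d$x, kx)
      py <- quantile_partition(d$y, ky)
      if (px$valid && py$valid) {
        best <- max(best, adjusted_rand_index(contingency_table(px, py)))
      }
    }
  }
  expect_identical(got$ccc, max(0, best))
  expect_gt(got$ccc, abs(cor(d$x, d$y)))
})

test_that("CCC is symmetric, monotone-invariant, and joint-permutation-invariant", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      x <- runif(60)
      y <- x^2 + rnorm(60, 0, 0.1)
      v <- ccc_pair(x, y)$ccc
      expect_gte(v, 0)
      expect_lte(v, 1)
      expect_identical(ccc_pair(y, x)$ccc, v)
      expect_identical(ccc_pair(exp(x), y)$ccc, v)
      expect_identical(ccc_pair(x, y^3)$ccc, v)
      perm <- sample.int(60)
      expect_identical(ccc_pair(x[perm], y[perm])$ccc, v)
    }
  })
})

test_that("argmax bookkeeping breaks ties toward the smallest k pair", {
  x <- as.numeric(1:40)
  res <- ccc_pair(x, 2 * x + 1)
  # every k pair (k, k) scores 1; the smallest wins
  expect_identical(res$best_k_x, 2L)
  expect_identical(res$best_k_y, 2L)
})

test_that("uncomputable pairs return an NA row rather than erroring", {
  short <- ccc_pair(1:5, 5:1)
  expect_true(is.na(short$ccc))
  expect_identical(short$n_used, 5L)

  # constant feature: no valid partition at any k
  const <- ccc_pair(rep(1, 30), rnorm(30))
  expect_true(is.na(const$ccc))

  # missing values are removed pairwise
  x <- c(NA, as.numeric(1:30))
  y <- c(5, as.numeric(1:30)^3)
  res <- ccc_pair(x, y)
  expect_identical(res$n_used, 30L)
  expect_identical(res$ccc, 1)
})

test_that("pairwise engine equals the naive loop bit-exactly, for any backend and chunking", {
  mat <- withr::with_seed(44, matrix(rnorm(30 * 50), nrow = 30))
  expr <- as_expr_tbl(mat)
  par1 <- ccc_pairwise(expr, chunk_size = 1)
  par7 <- ccc_pairwise(expr, chunk_size = 7)
  par1000 <- ccc_pairwise(expr, chunk_size = 1000)
  ref <- ccc_pairwise(expr, backend = "reference")
  expect_identical(par1$ccc, par7$ccc)
  expect_identical(par1, par1000)
  expect_identical(par1$ccc, ref$ccc)
  expect_identical(par1$best_k_x, ref$best_k_x)
  expect_identical(par1$ccc, naive_ccc_condensed(mat))
  expect_identical(nrow(par1), 435L)
  expect_true(all(par1$ccc >= 0 & par1$ccc <= 1))
})

test_that("identical features give condensed entries of exactly 1", {
  x <- withr::with_seed(3, runif(25))
  expr <- as_expr_tbl(rbind(x, x, x))
  res <- ccc_pairwise(expr)
  expect_identical(res$ccc, rep(1, 3))
})

test_that("a degenerate feature yields NA sentinels without aborting the scan", {
  withr::with_seed(50, {
    mat <- matrix(rnorm(4 * 40), nrow = 4)
    mat[2, ] <- NA_real_ # all-missing feature
    expr <- as_expr_tbl(mat)
    res <- ccc_pairwise(expr)
    bad <- res$feature_i == "G0002" | res$feature_j == "G0002"
    expect_true(all(is.na(res$ccc[bad])))
    expect_true(all(!is.na(res$ccc[!bad])))

    # partial missingness: pairwise-complete fallback agrees with ccc_pair
    mat[2, ] <- rnorm(40)
    mat[2, 1:3] <- NA_real_
    expr2 <- as_expr_tbl(mat)
    res2 <- ccc_pairwise(expr2)
    direct <- ccc_pair(mat[1, ], mat[2, ])
    expect_identical(res2$ccc[1], direct$ccc)
    expect_identical(res2$n_used[1], 37L)
  })
  expect_error(ccc_pairwise(as_expr_tbl(matrix(1:10, nrow = 1))), "at least 2")
})
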
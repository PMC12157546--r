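test_that("linear coefficients match the textbook direct formulas", {
  withr::with_seed(81, {
    x <- runif(50)
    mat <- rbind(x, 2 * x + 1, exp(x), matrix(rnorm(17 * 50), nrow = 17))
    lin <- linear_coefficients(as_expr_tbl(mat))
    expect_identical(nrow(lin), 190L)

    # y = 2x + 1: both coefficients exactly 1 (up to float round-off)
    expect_equal(lin$pearson[1], 1, tolerance = 1e-12)
    expect_equal(lin$spearman[1], 1, tolerance = 1e-12)
    # y = exp(x): monotone nonlinear, spearman 1, pearson strictly below
    expect_equal(lin$spearman[2], 1, tolerance = 1e-12)
    expect_lt(lin$pearson[2], 1)

    # full 20x50 table against the direct-formula oracle
    pairs <- which(upper.tri(diag(20)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
    for (r in sample(nrow(pairs), 40)) {
      i <- pairs[r, 1]
      j <- pairs[r, 2]
      k <- condensed_index(i, j, 20)
      expect_equal(lin$pearson[k], oracle_pearson(mat[i, ], mat[j, ]),
        tolerance = 1e-12
      )
      expect_equal(lin$spearman[k], oracle_spearman(mat[i, ], mat[j, ]),
        tolerance = 1e-12
      )
    }
  })
})

test_that("constant features yield NA coefficients, not errors", {
  mat <- rbind(rep(1, 30), withr::with_seed(82, matrix(rnorm(60), nrow = 2)))
  lin <- linear_coefficients(as_expr_tbl(mat))
  expect_true(all(is.na(lin$pearson[1:2])))
  expect_false(anyNA(lin$pearson[3]))
})

test_that("percentile tiers pick the top and bottom fractions inclusively", {
  d <- tibble::tibble(ccc = as.numeric(1:10) / 10)
  out <- classify_tiers(d, ccc)
  expect_identical(
    as.character(out$ccc_tier),
    c("low", "low", "low", rep("neither", 4), "high", "high", "high")
  )

  # boundary: everything defined tiers high when high_pct = 1
  all_high <- classify_tiers(d, ccc, high_pct = 1, low_pct = 0)
  expect_true(all(all_high$ccc_tier == "high"))

  # all-equal coefficients: cutoffs coincide, high takes precedence
  same <- classify_tiers(tibble::tibble(v = rep(0.4, 6)), v)
  expect_true(all(same$v_tier == "high"))

  # missing coefficients tier neither, cutoffs use defined entries only
  with_na <- classify_tiers(tibble::tibble(v = c(1:10 / 10, NA)), v)
  expect_identical(as.character(with_na$v_tier)[11], "neither")
  expect_identical(attr(with_na$v_tier, "high_cutoff"),
                   unname(quantile(1:10 / 10, 0.7)))

  expect_error(classify_tiers(d, ccc, high_pct = 0.8, low_pct = 0.4), "high_pct")
  expect_error(classify_tiers(tibble::tibble(v = c(NA_real_, NA_real_)), v),
               "no defined")
})

test_that("permutation-mode tiers use the supplied threshold as high cutoff", {
  d <- tibble::tibble(ccc = c(0.05, 0.1, 0.4, 0.9))
  out <- classify_tiers(d, ccc, mode = "permutation", high_cutoff = 0.3)
  expect_identical(as.character(out$ccc_tier), c("low", "neither", "high", "high"))
  expect_error(classify_tiers(d, ccc, mode = "permutation"), "high_cutoff")
})

test_that("Pearson magnitude tiering treats strong negatives as high", {
  d <- tibble::tibble(pearson = c(-0.95, -0.05, 0.2, 0.9, 0.01))
  out <- classify_tiers(d, pearson, absolute = TRUE, high_pct = 0.4, low_pct = 0.4)
  expect_identical(as.character(out$pearson_tier)[1], "high")
})

test_that("intersection counts conserve pairs over the 27 tier triples", {
  withr::with_seed(83, {
    lv <- c("high", "low", "neither")
    d <- tibble::tibble(
      ccc_tier = sample(lv, 200, replace = TRUE),
      pearson_tier = sample(lv, 200, replace = TRUE),
      spearman_tier = sample(lv, 200, replace = TRUE)
    )
    tab <- intersection_counts(d)
    expect_identical(nrow(tab), 27L)
    expect_identical(sum(tab$count), 200L)
    expect_setequal(unique(tab$class), c("agreement", "disagreement", "other"))
    # exactly 2 agreement cells and 5 disagreement cells exist
    expect_identical(sum(tab$class == "agreement"), 2L)
    expect_identical(sum(tab$class == "disagreement"), 5L)
  })
})

test_that("methods that rank identically produce zero disagreement", {
  # identical coefficient rankings for the three methods: tier the same
  # 10 coefficients three times over
  d <- tibble::tibble(v = withr::with_seed(84, runif(10))) |>
    classify_tiers(v, name = "ccc_tier") |>
    classify_tiers(v, name = "pearson_tier") |>
    classify_tiers(v, name = "spearman_tier")
  tab <- intersection_counts(d)
  expect_identical(sum(tab$count[tab$class == "disagreement"]), 0L)
  # every classified pair sits in an all-high or all-low agreement cell,
  # or in the all-neither cell
  expect_identical(sum(tab$count[tab$class == "agreement"]), 6L)
  expect_identical(sum(tab$count), 10L)
})

test_that("a planted quadratic pair lands in a disagreement group at rank 1", {
  sim <- simulate_expression(
    20, 200,
    planted = list(list(features = c(1, 2), pattern = "quadratic")),
    seed = 85
  )
  cmp <- compare_methods(sim$expression)
  top <- cmp$top_disagreements
  expect_gt(nrow(top), 0L)
  expect_identical(top$feature_i[1], "G0001")
  expect_identical(top$feature_j[1], "G0002")
  expect_true(all(
    top$ccc_tier == "high" & (top$pearson_tier == "low" | top$spearman_tier == "low")
  ))
  expect_true(all(top$group %in% c(
    "P-low/S-low", "P-low/S-neither", "P-neither/S-low",
    "P-low/S-high", "P-high/S-low"
  )))
})

test_that("top-disagreement selection truncates, and breaks CCC ties by pair order", {
  d <- tibble::tibble(
    feature_i = paste0("G", 1:4), feature_j = paste0("H", 1:4),
    ccc = c(0.9, 0.9, 0.95, 0.2),
    ccc_tier = factor(c("high", "high", "high", "low")),
    pearson_tier = factor(c("low", "low", "low", "low")),
    spearman_tier = factor(c("neither", "low", "high", "low"))
  )
  top <- select_top_disagreements(d, top_k = 10)
  expect_identical(top$feature_i, c("G3", "G1", "G2")) # tie G1/G2 by row order
  expect_identical(nrow(select_top_disagreements(d, top_k = 2)), 2L)
  none <- d[d$ccc_tier == "low", ]
  expect_identical(nrow(select_top_disagreements(none, top_k = 5)), 0L)
})

test_that("gene-metadata correlation recovers a noise-free dimorphic gene exactly", {
  pair <- simulate_preset("sex_dimorphic", n_samples = 100, noise_sd = 0, seed = 86)
  md <- simulate_metadata(100, seed = 87)
  md$sex <- pair$group # the gene is driven by this sex variable
  expr <- as_expr_tbl(rbind(pair$y, pair$x), ids = c("DIMORPH", "OTHER"))
  names(expr)[-1] <- md$sample_id
  res <- gene_metadata_correlation(expr, md, genes = "DIMORPH")
  sex_row <- res[res$variable == "sex", ]
  expect_identical(sex_row$ccc, 1)
  expect_identical(sex_row$variable_type, "categorical")
  # rows are sorted by CCC descending within gene
  expect_identical(res$ccc, sort(res$ccc, decreasing = TRUE))

  # numeric-vs-categorical CCC is symmetric in its arguments
  expect_identical(ccc_pair(pair$y, md$sex)$ccc, ccc_pair(md$sex, pair$y)$ccc)
})

test_that("gene-metadata correlation flags misalignment and degenerate variables", {
  withr::with_seed(88, {
    expr <- simulate_expression(3, 30, seed = 1)$expression
    md <- simulate_metadata(30, seed = 2)
    md$bmi <- NA_real_
    expect_warning(
      res <- gene_metadata_correlation(expr, md, genes = "G0001"),
      "all-missing"
    )
    expect_false("bmi" %in% res$variable)

    md_bad <- md
    md_bad$sample_id <- paste0("X", md_bad$sample_id)
    expect_error(gene_metadata_correlation(expr, md_bad), "align")

    md_fresh <- simulate_metadata(30, seed = 4)
    md_extra <- rbind(md_fresh, md_fresh[1, ])
    md_extra$sample_id[31] <- "S9999"
    expect_warning(gene_metadata_correlation(expr, md_extra, genes = "G0001"),
                   "dropping 1 metadata")

    expect_error(gene_metadata_correlation(expr, md, genes = "NOPE"), "not in")
  })
})

test_that("a gene of pure noise correlates with nothing", {
  withr::with_seed(89, {
    gene <- rnorm(100)
    md <- simulate_metadata(100, seed = 3)
    expr <- as_expr_tbl(matrix(gene, nrow = 1), ids = "NOISE")
    names(expr)[-1] <- md$sample_id
    res <- gene_metadata_correlation(expr, md)
    expect_true(all(res$ccc < 0.15))
  })
})
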
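#' Pearson and Spearman coefficients in condensed pair order
#'
#' Computes the two conventional correlation coefficients for every feature
#' pair, using pairwise-complete observations, in exactly the condensed
#' order of [ccc_pairwise()] so the three coefficient columns can be bound
#' side by side. Pairs involving a constant feature are `NA`.
#'
#' @inheritParams ccc_pairwise
#' @return Tibble: `feature_i`, `feature_j`, `pearson`, `spearman`.
#' @export
linear_coefficients <- function(data) {
  feats <- parse_features(data)
  tm <- t(feats$mat)
  pe <- suppressWarnings(
    stats::cor(tm, use = "pairwise.complete.obs", method = "pearson")
  )
  sp <- suppressWarnings(
    stats::cor(tm, use = "pairwise.complete.obs", method = "spearman")
  )
  pairs <- condensed_pairs(feats$n_features)
  tibble::tibble(
    feature_i = feats$ids[pairs$i],
    feature_j = feats$ids[pairs$j],
    pearson = condensed_from_matrix(pe),
    spearman = condensed_from_matrix(sp)
  )
}

tier_levels <- c("high", "low", "neither")

# Vector core of tier assignment. `values` may contain NA (tier "neither").
tier_values <- function(values, high_pct = 0.30, low_pct = 0.30,
                        mode = c("percentile", "permutation"),
                        high_cutoff = NULL, low_cutoff = NULL) {
  mode <- match.arg(mode)
  defined <- values[!is.na(values)]
  if (length(defined) == 0L) {
    stop("no defined coefficients to tier", call. = FALSE)
  }
  if (mode == "percentile") {
    if (high_pct <= 0 || low_pct < 0 || high_pct + low_pct > 1) {
      stop("need 0 < high_pct, 0 <= low_pct, high_pct + low_pct <= 1",
        call. = FALSE
      )
    }
    high_cutoff <- unname(stats::quantile(defined, 1 - high_pct, type = 7))
    low_cutoff <- unname(stats::quantile(defined, low_pct, type = 7))
  } else {
    if (is.null(high_cutoff)) {
      stop("permutation mode needs `high_cutoff` (see ccc_null_threshold())",
        call. = FALSE
      )
    }
    # low tier stays percentile-based unless a cutoff is supplied
    low_cutoff <- low_cutoff %||%
      unname(stats::quantile(defined, low_pct, type = 7))
  }
  if (high_cutoff < low_cutoff) {
    stop("high cutoff fell below low cutoff", call. = FALSE)
  }
  tier <- rep("neither", length(values))
  # inclusive comparisons; "high" takes precedence when cutoffs coincide
  tier[!is.na(values) & values >= high_cutoff] <- "high"
  tier[!is.na(values) & values <= low_cutoff & tier != "high"] <- "low"
  structure(factor(tier, levels = tier_levels),
    high_cutoff = high_cutoff, low_cutoff = low_cutoff
  )
}

#' Assign high/low/neither tiers to a coefficient column
#'
#' Labels each pair `high` when its coefficient reaches the top
#' `high_pct` fraction of defined values (inclusive at the cutoff), `low`
#' when it falls in the bottom `low_pct` fraction, and `neither`
#' otherwise. Missing coefficients always tier `neither`; cutoffs are
#' computed on defined entries only. In `"permutation"` mode the high
#' cutoff is an externally supplied threshold (see
#' [ccc_null_threshold()]) instead of a percentile. When every defined
#' value is identical both cutoffs coincide and everything tiers `high`
#' (high takes precedence, deterministically).
#'
#' @param data Tibble of pairs (one row per pair).
#' @param coefficient Column holding the coefficient to tier (tidy-eval).
#' @param high_pct,low_pct Tier fractions (defaults 0.30 each, the
#'   top/bottom 30% convention).
#' @param mode `"percentile"` or `"permutation"`.
#' @param high_cutoff,low_cutoff Explicit cutoffs for permutation mode.
#' @param absolute Tier on `abs(coefficient)`; use for signed coefficients
#'   (Pearson/Spearman) so "high" means strong in either direction.
#' @param name Name of the new tier column; default
#'   `"<coefficient>_tier"`.
#' @return `data` with the added tier factor column; the cutoffs are
#'   attached to that column as attributes `high_cutoff` / `low_cutoff`.
#' @export
classify_tiers <- function(data, coefficient, high_pct = 0.30, low_pct = 0.30,
                           mode = c("percentile", "permutation"),
                           high_cutoff = NULL, low_cutoff = NULL,
                           absolute = FALSE, name = NULL) {
  col <- rlang::enquo(coefficient)
  vals <- rlang::eval_tidy(col, data)
  if (absolute) vals <- abs(vals)
  tier <- tier_values(vals,
    high_pct = high_pct, low_pct = low_pct, mode = mode,
    high_cutoff = high_cutoff, low_cutoff = low_cutoff
  )
  name <- name %||% paste0(rlang::as_name(col), "_tier")
  data[[name]] <- tier
  data
}

# The five CCC-high / other-low combinations that define a disagreement.
disagreement_groups <- function() {
  tibble::tibble(
    pearson_tier = c("low", "low", "neither", "low", "high"),
    spearman_tier = c("low", "neither", "low", "high", "low")
  )
}

classify_intersection <- function(ccc_tier, pearson_tier, spearman_tier) {
  dplyr::case_when(
    ccc_tier == "high" & pearson_tier == "high" & spearman_tier == "high" ~
      "agreement",
    ccc_tier == "low" & pearson_tier == "low" & spearman_tier == "low" ~
      "agreement",
    ccc_tier == "high" & (pearson_tier == "low" | spearman_tier == "low") ~
      "disagreement",
    .default = "other"
  )
}

#' Method agreement/disagreement intersection table
#'
#' Cross-tabulates the per-pair tiers of the three methods into the 27
#' possible (CCC, Pearson, Spearman) tier combinations — the counts behind
#' an UpSet-style comparison. Each pair lands in exactly one cell, so the
#' counts always sum to the number of pairs. Cells are classed
#' `agreement` (all three high, or all three low), `disagreement` (CCC
#' high while Pearson or Spearman is low — candidate nonlinear
#' relationships), or `other`.
#'
#' @param data Tibble of pairs carrying factor columns `ccc_tier`,
#'   `pearson_tier`, `spearman_tier` (see [classify_tiers()]).
#' @return Tibble of all 27 combinations: `ccc_tier`, `pearson_tier`,
#'   `spearman_tier`, `class`, `count`, sorted by descending count.
#' @export
intersection_counts <- function(data) {
  needed <- c("ccc_tier", "pearson_tier", "spearman_tier")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing tier columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- data |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(needed), ~ factor(.x, levels = tier_levels)
    )) |>
    dplyr::count(
      .data$ccc_tier, .data$pearson_tier, .data$spearman_tier,
      .drop = FALSE, name = "count"
    ) |>
    dplyr::mutate(class = classify_intersection(
      .data$ccc_tier, .data$pearson_tier, .data$spearman_tier
    )) |>
    dplyr::select(
      "ccc_tier", "pearson_tier", "spearman_tier", "class", "count"
    ) |>
    dplyr::arrange(dplyr::desc(.data$count))
  out
}

#' Top-ranked disagreement pairs
#'
#' Selects the pairs from the five intersection groups where CCC tiers
#' high and at least one of Pearson/Spearman tiers low — the candidates
#' for nonlinear relationships the conventional coefficients miss — and
#' returns the `top_k` with the largest CCC. Ties in CCC are broken by
#' condensed pair order (the input row order), so selection is
#' deterministic.
#'
#' @param data Tibble of pairs with `ccc` and the three tier columns, in
#'   condensed order (as produced by [compare_methods()]).
#' @param top_k Maximum number of pairs to return (default 100).
#' @return Tibble of the selected pairs, sorted by `ccc` descending, with
#'   a `group` label such as `"P-low/S-neither"`.
#' @export
select_top_disagreements <- function(data, top_k = 100) {
  if (top_k < 1) stop("`top_k` must be >= 1", call. = FALSE)
  data |>
    dplyr::mutate(.condensed_order = dplyr::row_number()) |>
    dplyr::filter(
      .data$ccc_tier == "high" &
        (.data$pearson_tier == "low" | .data$spearman_tier == "low")
    ) |>
    dplyr::mutate(group = paste0(
      "P-", .data$pearson_tier, "/S-", .data$spearman_tier
    )) |>
    dplyr::arrange(dplyr::desc(.data$ccc), .data$.condensed_order) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::select(-".condensed_order")
}

#' Full three-method comparison pipeline
#'
#' Runs the whole comparison on one expression matrix: CCC for every pair
#' ([ccc_pairwise()]), Pearson and Spearman alongside
#' ([linear_coefficients()]), per-method tier assignment
#' ([classify_tiers()]; Pearson/Spearman tiered on magnitude by default),
#' the intersection table ([intersection_counts()]) and the ranked
#' disagreement list ([select_top_disagreements()]).
#'
#' @inheritParams ccc_pairwise
#' @inheritParams classify_tiers
#' @param tier_mode `"percentile"` (top/bottom fractions) or
#'   `"permutation"` (high cutoff from a pooled permutation null).
#' @param perm_n,perm_q,seed Pooled-null parameters for
#'   `tier_mode = "permutation"` (see [ccc_null_threshold()]).
#' @param absolute Tier Pearson/Spearman on magnitude (default `TRUE`).
#' @param top_k Size of the ranked disagreement list.
#' @return A `ccc_comparison` object: list with `pairs` (per-pair
#'   coefficients and tiers), `intersections`, `top_disagreements`, and
#'   `cutoffs`.
#' @export
compare_methods <- function(data, k_range = 2:10, min_pairwise_samples = 10,
                            high_pct = 0.30, low_pct = 0.30,
                            tier_mode = c("percentile", "permutation"),
                            perm_n = 500, perm_q = 0.99, seed = 1L,
                            absolute = TRUE, top_k = 100,
                            backend = c("parallel", "reference"),
                            chunk_size = 4096L) {
  tier_mode <- match.arg(tier_mode)
  backend <- match.arg(backend)
  ccc_tbl <- ccc_pairwise(data,
    k_range = k_range,
    min_pairwise_samples = min_pairwise_samples,
    backend = backend, chunk_size = chunk_size
  )
  lin_tbl <- linear_coefficients(data)
  stopifnot(identical(ccc_tbl$feature_i, lin_tbl$feature_i))
  pairs <- dplyr::bind_cols(
    ccc_tbl,
    lin_tbl[, c("pearson", "spearman")]
  )
  high_cutoff <- NULL
  if (tier_mode == "permutation") {
    high_cutoff <- as.numeric(ccc_null_threshold(data,
      n_perm = perm_n, q = perm_q, seed = seed,
      k_range = k_range, min_pairwise_samples = min_pairwise_samples
    ))
  }
  pairs <- pairs |>
    classify_tiers(.data$ccc,
      high_pct = high_pct, low_pct = low_pct,
      mode = tier_mode, high_cutoff = high_cutoff, name = "ccc_tier"
    ) |>
    classify_tiers(.data$pearson,
      high_pct = high_pct, low_pct = low_pct,
      absolute = absolute, name = "pearson_tier"
    ) |>
    classify_tiers(.data$spearman,
      high_pct = high_pct, low_pct = low_pct,
      absolute = absolute, name = "spearman_tier"
    )
  cutoffs <- lapply(
    pairs[c("ccc_tier", "pearson_tier", "spearman_tier")],
    function(col) {
      c(
        high = attr(col, "high_cutoff"),
        low = attr(col, "low_cutoff")
      )
    }
  )
  structure(
    list(
      pairs = pairs,
      intersections = intersection_counts(pairs),
      top_disagreements = select_top_disagreements(pairs, top_k = top_k),
      cutoffs = cutoffs,
      tier_mode = tier_mode
    ),
    class = "ccc_comparison"
  )
}

#' @export
print.ccc_comparison <- function(x, ...) {
  n_pairs <- nrow(x$pairs)
  n_dis <- sum(x$intersections$count[x$intersections$class == "disagreement"])
  n_agr <- sum(x$intersections$count[x$intersections$class == "agreement"])
  cat("Three-method comparison (CCC vs Pearson vs Spearman)\n")
  cat(sprintf(
    "  %d pairs | tiers: %s | agreement %d, disagreement %d\n",
    n_pairs, x$tier_mode, n_agr, n_dis
  ))
  cat(sprintf(
    "  top disagreement pairs retained: %d\n", nrow(x$top_disagreements)
  ))
  invisible(x)
}

#' @rdname compare_methods
#' @param x A `ccc_comparison` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ccc_comparison <- function(x, ...) {
  x$pairs
}

#' @rdname compare_methods
#' @exportS3Method generics::glance
glance.ccc_comparison <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_agreement = sum(x$intersections$count[x$intersections$class == "agreement"]),
    n_disagreement = sum(
      x$intersections$count[x$intersections$class == "disagreement"]
    ),
    ccc_high_cutoff = x$cutoffs$ccc_tier[["high"]],
    tier_mode = x$tier_mode
  )
}

#' Correlate gene expression with sample metadata
#'
#' Uses the CCC's mixed-type support to score each gene against each
#' metadata variable (numeric or categorical), the step that turns an
#' unexplained nonlinear gene pair into an interpretable one (e.g. a
#' sex-dimorphic pair explained by a sex variable). Samples are matched by
#' ID; metadata-only samples are dropped with a warning, expression
#' samples without metadata enter as missing and fall out pairwise.
#'
#' @inheritParams ccc_pair
#' @param data Expression data (see [ccc_pairwise()]).
#' @param metadata Tibble whose first column holds sample IDs matching the
#'   expression sample columns; remaining columns are variables, numeric
#'   or character/factor (categorical).
#' @param genes Genes to score; defaults to all. May also be a tibble with
#'   `feature_i`/`feature_j` columns (e.g. from
#'   [select_top_disagreements()]), whose union of genes is used.
#' @return Tibble: `gene`, `variable`, `variable_type`, `ccc`, `n_used`,
#'   sorted by `ccc` descending within gene.
#' @export
gene_metadata_correlation <- function(data, metadata, genes = NULL,
                                      k_range = 2:10,
                                      min_pairwise_samples = 10) {
  feats <- parse_features(data, min_features = 1L)
  if (!is.data.frame(metadata) || ncol(metadata) < 2L) {
    stop("`metadata` needs a sample-ID column plus at least one variable",
      call. = FALSE
    )
  }
  md_ids <- as.character(metadata[[1L]])
  if (anyDuplicated(md_ids)) {
    stop("duplicate sample IDs in metadata: ",
      paste(unique(md_ids[duplicated(md_ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  hit <- match(feats$sample_ids, md_ids)
  if (all(is.na(hit))) {
    stop(
      "metadata sample IDs do not align with expression samples; offenders: ",
      paste(utils::head(feats$sample_ids, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(md_ids, feats$sample_ids)
  if (length(extra) > 0L) {
    warning(
      "dropping ", length(extra), " metadata sample(s) absent from the ",
      "expression matrix: ", paste(utils::head(extra, 5L), collapse = ", ")
    )
  }
  if (anyNA(hit)) {
    warning(
      sum(is.na(hit)), " expression sample(s) lack metadata and are ",
      "treated as missing: ",
      paste(utils::head(feats$sample_ids[is.na(hit)], 5L), collapse = ", ")
    )
  }
  if (is.data.frame(genes)) {
    genes <- unique(c(genes$feature_i, genes$feature_j))
  }
  genes <- genes %||% feats$ids
  unknown <- setdiff(genes, feats$ids)
  if (length(unknown) > 0L) {
    stop("genes not in expression data: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  vars <- names(metadata)[-1L]
  aligned <- lapply(vars, function(v) {
    col <- metadata[[v]]
    out <- col[hit] # NA where sample lacks metadata
    if (!is.numeric(out)) out <- as.character(out)
    out
  })
  names(aligned) <- vars
  usable <- vapply(aligned, function(v) !all(is.na(v)), logical(1))
  if (any(!usable)) {
    warning(
      "excluding all-missing metadata variable(s): ",
      paste(vars[!usable], collapse = ", ")
    )
  }
  vars <- vars[usable]
  rows <- purrr::map(genes, function(g) {
    gv <- feats$mat[match(g, feats$ids), ]
    purrr::map(vars, function(v) {
      res <- ccc_pair(gv, aligned[[v]],
        k_range = k_range,
        min_pairwise_samples = min_pairwise_samples
      )
      tibble::tibble(
        gene = g, variable = v,
        variable_type = feature_type(aligned[[v]]),
        ccc = res$ccc, n_used = res$n_used
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$ccc))
}
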
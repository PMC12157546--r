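ccc_patterns <- c(
  "monotone", "quadratic", "two_group_linear", "simpson_reversal",
  "masked_subset", "null"
)

#' Simulate one feature pair with a known relationship
#'
#' Seeded generators for the canonical relationship classes the CCC is
#' meant to separate from what Pearson/Spearman see:
#'
#' * `monotone` — `y = slope * x + noise`, `x` uniform on `[0, 1]`: the
#'   baseline every method detects.
#' * `quadratic` — `y = x^2 + noise` with `x` drawn sign-symmetric on
#'   `[-1, 1]` (each positive draw paired with its negative), so the
#'   linear and rank correlations are structurally zero while the
#'   relationship is deterministic.
#' * `two_group_linear` — group A follows `y = slope * x + noise`, group B
#'   is constant at zero plus noise: the sex-dimorphic pattern of a
#'   Y-chromosome gene that is expressed only in males.
#' * `simpson_reversal` — both groups have the same positive within-group
#'   slope over evenly spaced `x`, but group B is offset in `x` and given
#'   an intercept solved in closed form so the pooled least-squares slope
#'   is negative (set to the exact mirror of the within-group
#'   contribution). The reversal is guaranteed by construction, not
#'   sampled for; the pooled-coefficient methods see the wrong sign while
#'   the CCC sees the two tight linear bands.
#' * `masked_subset` — group A linear, group B independent noise over the
#'   same `x` range: a real relationship masked by an unrelated subset.
#' * `null` — independent standard normal `x` and `y`.
#'
#' Noise is additive Gaussian with standard deviation `noise_sd`. The
#' default `noise_sd = 0.02` (2% of the unit signal amplitude) emulates
#' the near-deterministic exemplar patterns these classes are drawn from;
#' pass a larger value to stress robustness.
#'
#' @param pattern One of `"monotone"`, `"quadratic"`,
#'   `"two_group_linear"`, `"simpson_reversal"`, `"masked_subset"`,
#'   `"null"`.
#' @param n_samples Number of samples (at least 20).
#' @param noise_sd Gaussian noise standard deviation (default 0.02).
#' @param group_fraction Fraction of samples in group A for the two-group
#'   patterns, in `(0, 1)` (default 0.5).
#' @param slope Within-group slope for the linear patterns (default 1).
#' @param seed Integer seed; identical specs regenerate identical data.
#' @return Tibble with `sample_id`, `x`, `y`, and `group` (`NA` for
#'   ungrouped patterns).
#' @examples
#' simulate_pair("quadratic", n_samples = 50, seed = 7)
#' @export
simulate_pair <- function(pattern, n_samples = 100, noise_sd = 0.02,
                          group_fraction = 0.5, slope = 1, seed = 1L) {
  pattern <- match.arg(pattern, ccc_patterns)
  if (n_samples < 20) stop("`n_samples` must be >= 20", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (group_fraction <= 0 || group_fraction >= 1) {
    stop("`group_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  with_seed(seed, gen_pair(pattern, n_samples, noise_sd, group_fraction, slope))
}

# Pattern generator drawing from the current RNG stream (no seed reset),
# so planted patterns inside a matrix share the matrix-level seed.
gen_pair <- function(pattern, n, noise_sd, group_fraction, slope) {
  noise <- function() stats::rnorm(n, 0, noise_sd)
  group <- rep(NA_character_, n)
  if (pattern %in% c("two_group_linear", "simpson_reversal", "masked_subset")) {
    n_a <- max(1L, min(n - 1L, round(group_fraction * n)))
    group <- rep(c("A", "B"), c(n_a, n - n_a))
  }
  switch(pattern,
    monotone = {
      x <- stats::runif(n)
      y <- slope * x + noise()
    },
    quadratic = {
      half <- n %/% 2L
      pos <- stats::runif(half)
      x <- c(pos, -pos, if (n %% 2L == 1L) 0)
      x <- x[sample.int(n)]
      y <- x^2 + noise()
    },
    two_group_linear = {
      x <- stats::runif(n, 0.5, 1.5)
      y <- ifelse(group == "A", slope * x, 0) + noise()
    },
    simpson_reversal = {
      in_a <- group == "A"
      dx <- 1.5
      x <- numeric(n)
      x[in_a] <- seq(0, 1, length.out = sum(in_a))
      x[!in_a] <- seq(0, 1, length.out = sum(!in_a)) + dx
      y0 <- numeric(n)
      y0[in_a] <- slope * x[in_a]
      y0[!in_a] <- slope * (x[!in_a] - dx)
      # intercept for group B solved so the pooled covariance flips sign:
      # cov(x, y0 + dy * 1B) = cov(x, y0) + dy * cov(x, 1B); setting the
      # target to -cov(x, y0) mirrors the within-group contribution.
      c0 <- stats::cov(x, y0)
      cb <- stats::cov(x, as.numeric(!in_a))
      dy <- -2 * c0 / cb
      y <- y0 + dy * as.numeric(!in_a) + noise()
    },
    masked_subset = {
      in_a <- group == "A"
      x <- stats::runif(n)
      y <- ifelse(in_a, slope * x, 0) +
        ifelse(in_a, 0, stats::runif(n, 0, max(slope, 1))) + noise()
    },
    null = {
      x <- stats::rnorm(n)
      y <- stats::rnorm(n)
    }
  )
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    x = x, y = y, group = group
  )
}

fixture_preset_table <- function() {
  tibble::tibble(
    preset = c("sex_dimorphic", "mortality_simpson", "masked_subset"),
    pattern = c("two_group_linear", "simpson_reversal", "masked_subset"),
    group_a = c("male", "organ_donor", "organ_donor"),
    group_b = c("female", "postmortem", "postmortem")
  )
}

#' Named presets for the exemplar relationship classes
#'
#' Thin wrappers over [simulate_pair()] with field-named group labels:
#' `"sex_dimorphic"` (linear in males only, a chrY-gene analogue),
#' `"mortality_simpson"` (pre-/post-mortem Simpson reversal), and
#' `"masked_subset"` (organ-donor linear trend masked by a flat
#' postmortem subset).
#'
#' @param preset Preset name.
#' @inheritParams simulate_pair
#' @param ... Passed on to [simulate_pair()].
#' @return As [simulate_pair()], with preset-specific group labels.
#' @export
simulate_preset <- function(preset = c(
                              "sex_dimorphic", "mortality_simpson",
                              "masked_subset"
                            ),
                            n_samples = 100, seed = 1L, ...) {
  preset <- match.arg(preset)
  spec <- fixture_preset_table()
  spec <- spec[spec$preset == preset, ]
  out <- simulate_pair(spec$pattern,
    n_samples = n_samples, seed = seed, ...
  )
  out$group <- ifelse(out$group == "A", spec$group_a, spec$group_b)
  out
}

#' Simulate an expression matrix with planted relationships
#'
#' Generates `n_features` independent-noise features and overwrites chosen
#' feature pairs with patterned pairs from [simulate_pair()]'s generators,
#' recording every planted pair in a truth table. Planted pairs must not
#' share features. All randomness flows from the single `seed`, so the
#' same call regenerates the identical dataset.
#'
#' @param n_features,n_samples Matrix dimensions.
#' @param planted List of plantings, each a list with `features` (two
#'   distinct feature indices) and `pattern`, plus optional `noise_sd`,
#'   `group_fraction`, `slope` overrides.
#' @param seed Integer seed.
#' @param noise_sd Default noise level for planted patterns (default
#'   0.02); background features are standard normal.
#' @return List with `expression` (wide tibble: `feature_id` +
#'   one column per sample) and `truth` (tibble: `feature_i`,
#'   `feature_j`, `pattern`; empty when nothing is planted).
#' @export
simulate_expression <- function(n_features, n_samples, planted = list(),
                                seed = 1L, noise_sd = 0.02) {
  if (n_features < 2) stop("`n_features` must be >= 2", call. = FALSE)
  used <- unlist(lapply(planted, `[[`, "features"))
  if (length(used) > 0L) {
    if (any(used < 1 | used > n_features)) {
      stop("planted feature indices out of range", call. = FALSE)
    }
    if (anyDuplicated(used)) {
      stop("planted pairs must not share features", call. = FALSE)
    }
  }
  ids <- sprintf("G%04d", seq_len(n_features))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  mat <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_features * n_samples), nrow = n_features)
    for (p in planted) {
      pair <- gen_pair(
        p$pattern, n_samples,
        noise_sd = p$noise_sd %||% noise_sd,
        group_fraction = p$group_fraction %||% 0.5,
        slope = p$slope %||% 1
      )
      m[p$features[1L], ] <- pair$x
      m[p$features[2L], ] <- pair$y
    }
    m
  })
  truth <- tibble::tibble(
    feature_i = ids[vapply(planted, function(p) min(p$features), numeric(1))],
    feature_j = ids[vapply(planted, function(p) max(p$features), numeric(1))],
    pattern = vapply(planted, `[[`, character(1), "pattern")
  )
  expression <- tibble::as_tibble(
    cbind(
      tibble::tibble(feature_id = ids),
      stats::setNames(as.data.frame(mat), sample_ids)
    )
  )
  list(expression = expression, truth = truth)
}

#' Simulate a sample metadata table
#'
#' Emits the variable types the gene-metadata step consumes: two binary
#' categorical variables (`sex`: male/female; `cohort`: organ-donor vs
#' postmortem) and two numeric ones (`age`, uniform 20-70; `bmi`, normal
#' around 27), aligned to `S0001`-style sample IDs. `na_fraction`
#' introduces missingness into `bmi` to exercise pairwise-complete
#' handling.
#'
#' @param n_samples Number of samples (>= 2).
#' @param seed Integer seed.
#' @param na_fraction Fraction of `bmi` values set missing (default 0).
#' @return Tibble: `sample_id`, `sex`, `cohort`, `age`, `bmi`.
#' @export
simulate_metadata <- function(n_samples, seed = 1L, na_fraction = 0) {
  if (n_samples < 2) stop("`n_samples` must be >= 2", call. = FALSE)
  with_seed(seed, {
    bmi <- stats::rnorm(n_samples, 27, 4)
    if (na_fraction > 0) {
      n_na <- floor(na_fraction * n_samples)
      if (n_na > 0) bmi[sample.int(n_samples, n_na)] <- NA_real_
    }
    tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n_samples)),
      sex = sample(c("female", "male"), n_samples, replace = TRUE),
      cohort = sample(c("organ_donor", "postmortem"), n_samples,
        replace = TRUE
      ),
      age = round(stats::runif(n_samples, 20, 70)),
      bmi = bmi
    )
  })
}
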
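#' Scatter plot of a simulated or observed feature pair
#'
#' @param data Tibble with `x`, `y` and optional `group` columns, as
#'   produced by [simulate_pair()].
#' @return A ggplot object.
#' @export
plot_pair <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y))
  if ("group" %in% names(data) && !all(is.na(data$group))) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$group),
      alpha = 0.8
    )
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::theme_minimal()
}

#' UpSet-style bar chart of method intersections
#'
#' Shows the non-empty tier combinations of the three methods as ordered
#' bars, coloured by agreement class, with the combination spelled out on
#' the axis — the tabular core of an UpSet comparison.
#'
#' @param data Intersection table from [intersection_counts()].
#' @return A ggplot object.
#' @export
plot_intersections <- function(data) {
  df <- data |>
    dplyr::filter(.data$count > 0) |>
    dplyr::mutate(
      combo = paste0(
        "C:", .data$ccc_tier, " P:", .data$pearson_tier,
        " S:", .data$spearman_tier
      ),
      combo = stats::reorder(.data$combo, -.data$count)
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$combo, y = .data$count, fill = .data$class)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "gene pairs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname ccc_perm_test
#' @param object A `ccc_perm_test` object.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.ccc_perm_test <- function(object, ...) {
  ggplot2::ggplot(
    tibble::tibble(null = object$null_values),
    ggplot2::aes(x = .data$null)
  ) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(
      xintercept = object$observed, colour = "firebrick",
      linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "CCC under permutation null", y = "count",
      subtitle = sprintf(
        "observed = %.3f, p = %.3g", object$observed, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}
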
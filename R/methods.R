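#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an index result into one long table
#'
#' One row per (country, reference year, level, id): indicator indices,
#' target indices and overall indices stacked with their audit flags —
#' the tidy export format of the pipeline.
#'
#' @param x An `h2020_index` from [compute_index_table()].
#' @param ... Unused.
#' @return A tibble with columns `country`, `reference_year`, `level`
#'   (`"indicator"`, `"target"` or `"overall"`), `id`, `index`, `n_used`,
#'   `substituted`, `floored`, `excluded`.
#' @method tidy h2020_index
#' @export
tidy.h2020_index <- function(x, ...) {
  ind <- x$indicator_indices |>
    transmute(
      country = .data$country,
      reference_year = .data$reference_year,
      level = "indicator",
      id = as.integer(.data$indicator_id),
      index = .data$index,
      n_used = NA_integer_,
      substituted = .data$substituted,
      floored = .data$floored,
      excluded = FALSE
    )
  tgt <- x$target_indices |>
    transmute(
      country = .data$country,
      reference_year = .data$reference_year,
      level = "target",
      id = as.integer(.data$target_id),
      index = .data$index,
      n_used = .data$n_indicators_used,
      substituted = NA,
      floored = NA,
      excluded = .data$excluded
    )
  ov <- x$overall_indices |>
    transmute(
      country = .data$country,
      reference_year = .data$reference_year,
      level = "overall",
      id = NA_integer_,
      index = .data$index,
      n_used = .data$n_targets_used,
      substituted = NA,
      floored = NA,
      excluded = .data$unscorable
    )
  bind_rows(ind, tgt, ov) |>
    arrange(.data$country, .data$reference_year,
            factor(.data$level, levels = c("indicator", "target", "overall")),
            .data$id)
}

#' One-row summary of an index result
#'
#' @param x An `h2020_index`.
#' @param ... Unused.
#' @return A one-row tibble: roster and inclusion counts, numbers of
#'   indicators/targets in play, and the median/min/max 2015 overall
#'   index.
#' @method glance h2020_index
#' @export
glance.h2020_index <- function(x, ...) {
  ov15 <- x$overall_indices |>
    filter(.data$reference_year == 2015, !.data$unscorable)
  tibble(
    n_countries = nrow(x$inclusion),
    n_included = sum(x$inclusion$included),
    n_excluded = sum(!x$inclusion$included),
    n_indicators = nrow(x$goalposts),
    n_targets = length(quantitative_target_ids(x$registry)),
    n_substituted = sum(x$indicator_indices$substituted),
    n_floored = sum(x$indicator_indices$floored),
    median_index_2015 = if (nrow(ov15)) stats::median(ov15$index) else NA_real_,
    min_index_2015 = if (nrow(ov15)) min(ov15$index) else NA_real_,
    max_index_2015 = if (nrow(ov15)) max(ov15$index) else NA_real_
  )
}

#' Ranked overall-index bar chart
#'
#' Countries ranked from highest to lowest overall index for one reference
#' year, coloured by quintile — the standard presentation of a composite
#' country index.
#'
#' @param object An `h2020_index`.
#' @param year Reference year to plot (default 2015).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot h2020_index
#' @export
autoplot.h2020_index <- function(object, year = 2015, ...) {
  ov <- object$overall_indices |>
    filter(.data$reference_year == year, !.data$unscorable)
  if (nrow(ov) < 5) {
    stop_validation("fewer than 5 scored countries to plot")
  }
  qs <- assign_quintiles(ov |> select("country", "index"))
  ggplot2::ggplot(qs, ggplot2::aes(
    x = stats::reorder(.data$country, .data$index),
    y = .data$index, fill = .data$quintile
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = sprintf("Overall index (%d)", year),
      fill = "Quintile",
      title = sprintf("Overall composite index, %d", year)
    ) +
    ggplot2::theme_minimal()
}

#' Trend-cell bar chart
#'
#' Average relative change per indicator and quintile, faceted by
#' indicator; positive bars mean improvement regardless of the
#' indicator's direction.
#'
#' @param object An `h2020_trends` tibble from [trend_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot h2020_trends
#' @export
autoplot.h2020_trends <- function(object, ...) {
  dat <- object |> filter(!is.na(.data$avg_relative_change))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$quintile, y = .data$avg_relative_change,
    fill = .data$quintile
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~indicator_id,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = NULL, y = "Average relative change (positive = improvement)",
      fill = "Quintile"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname autoplot.h2020_index
#' @export
plot_index_ranking <- function(object, year = 2015) {
  autoplot.h2020_index(object, year = year)
}

#' @rdname autoplot.h2020_trends
#' @export
plot_trends <- function(object) {
  autoplot.h2020_trends(object)
}
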
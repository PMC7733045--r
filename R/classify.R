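quintile_levels <- function() {
  c("high", "upper_middle", "middle", "lower_middle", "low")
}

#' Assign countries to index quintiles
#'
#' Countries are ranked on the overall index in descending order (ties
#' broken by country code, ascending) and split into five contiguous rank
#' groups — the published quintile boundaries (e.g. "high index >= 75.8")
#' are empirical descriptions of such groups, so here boundaries are an
#' *output*, retrievable with [quintile_boundaries()]. When the roster
#' size is not divisible by five the larger groups come first.
#'
#' @param data Tibble with columns `country` and `index` (one row per
#'   scored country, typically the 2015 overall indices).
#' @return A tibble of class `h2020_quintiles` with columns `country`,
#'   `index`, `rank` (1 = highest index), `quintile` (ordered factor
#'   high > ... > low), carrying the empirical per-quintile boundaries as
#'   an attribute.
#' @export
assign_quintiles <- function(data) {
  require_columns(data, c("country", "index"), "overall index table")
  data <- as_tibble(data) |>
    filter(!is.na(.data$index))
  n <- nrow(data)
  if (n < 5) {
    stop_validation(sprintf(
      "need at least 5 scored countries to form quintiles, got %d", n
    ))
  }
  if (anyDuplicated(data$country)) {
    stop_validation("duplicate country codes in quintile input")
  }
  base <- n %/% 5L
  extra <- n %% 5L
  sizes <- base + as.integer(seq_len(5L) <= extra)
  ranked <- data |>
    arrange(desc(.data$index), .data$country) |>
    mutate(
      rank = row_number(),
      quintile = factor(rep(quintile_levels(), times = sizes),
                        levels = quintile_levels(), ordered = TRUE)
    ) |>
    select("country", "index", "rank", "quintile")
  boundaries <- ranked |>
    group_by(.data$quintile) |>
    summarise(
      min_index = min(.data$index),
      max_index = max(.data$index),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$quintile)
  structure(ranked,
            boundaries = boundaries,
            class = c("h2020_quintiles", class(ranked)))
}

#' @rdname assign_quintiles
#' @param x An `h2020_quintiles` object.
#' @return `quintile_boundaries()`: a tibble with the observed
#'   `min_index`/`max_index` and size of each quintile, ordered high to
#'   low.
#' @export
quintile_boundaries <- function(x) {
  b <- attr(x, "boundaries")
  if (is.null(b)) {
    stop_validation("object carries no quintile boundaries (not created by assign_quintiles?)")
  }
  b
}

#' Direction-adjusted relative change
#'
#' Signed fractional change between a baseline value and the 2015 value in
#' the indicator's native units, oriented so that positive always means
#' health improvement: for a `lower_better` indicator (mortality falling
#' from 10 to 8) the change is +0.20.
#'
#' @param baseline,value_2015 Numeric vectors in native units.
#' @param direction `"higher_better"` or `"lower_better"` (recycled).
#' @return Numeric vector of signed fractions; `NA` (with a warning) where
#'   the baseline is zero, so such cells drop out of averages.
#' @export
relative_change <- function(baseline, value_2015, direction) {
  if (!all(direction %in% c("higher_better", "lower_better"))) {
    stop_validation("direction must be 'higher_better' or 'lower_better'")
  }
  if (any(!is.finite(baseline)) || any(!is.finite(value_2015))) {
    stop_validation("relative_change: values must be finite")
  }
  s <- ifelse(direction == "higher_better", 1, -1)
  out <- s * (value_2015 - baseline) / abs(baseline)
  zero <- baseline == 0
  if (any(zero)) {
    warn(sprintf(
      "relative_change: %d zero baseline(s); returning NA for those cells",
      sum(zero)
    ))
    out[zero] <- NA_real_
  }
  out
}

#' Average relative change per indicator per quintile
#'
#' For every quantitative indicator with a usable baseline the unweighted
#' mean of per-country relative changes between baseline and 2015, within
#' each quintile. The baseline is 2005, or 2010 for indicators first
#' observed in 2010 (the asterisked bars of published trend figures);
#' indicators observed only in 2015 produce no row. Only countries with
#' both endpoint values contribute; `n_countries` makes the attrition per
#' cell visible (`n_countries = 0` cells carry `NA`).
#'
#' Changes are computed on raw native-unit values with a direction sign —
#' not on rescaled indices — so they do not depend on the goalposts.
#'
#' @param table Resolved observation tibble
#'   ([resolve_reference_years()]).
#' @param registry An `h2020_registry`.
#' @param assignment An `h2020_quintiles` tibble ([assign_quintiles()]).
#' @return A tibble of class `h2020_trends`: `indicator_id`, `quintile`,
#'   `baseline_year`, `avg_relative_change`, `n_countries`.
#' @export
trend_table <- function(table, registry, assignment) {
  require_columns(table, c("country", "indicator_id", "reference_year",
                           "value"), "resolved observation table")
  require_columns(assignment, c("country", "quintile"),
                  "quintile assignment")

  usable <- quantitative_indicators(registry) |>
    mutate(baseline_year = purrr::map_int(
      .data$available_reference_years,
      function(y) {
        if (2005L %in% y) 2005L else if (2010L %in% y) 2010L else NA_integer_
      }
    )) |>
    filter(!is.na(.data$baseline_year)) |>
    select("indicator_id", "direction", "baseline_year")

  scored <- table |>
    filter(.data$country %in% assignment$country)
  baseline <- scored |>
    inner_join(usable, by = "indicator_id") |>
    filter(.data$reference_year == .data$baseline_year) |>
    select("country", "indicator_id", "direction", "baseline_year",
           baseline = "value")
  endpoint <- scored |>
    filter(.data$reference_year == 2015) |>
    select("country", "indicator_id", value_2015 = "value")

  pairs <- baseline |>
    inner_join(endpoint, by = c("country", "indicator_id")) |>
    mutate(change = suppressWarnings(
      relative_change(.data$baseline, .data$value_2015, .data$direction)
    )) |>
    filter(!is.na(.data$change)) |>
    inner_join(assignment |> select("country", "quintile"), by = "country")

  cells <- pairs |>
    group_by(.data$indicator_id, .data$quintile, .data$baseline_year) |>
    summarise(
      avg_relative_change = mean(.data$change),
      n_countries = dplyr::n(),
      .groups = "drop"
    )

  grid <- usable |>
    select("indicator_id", "baseline_year") |>
    tidyr::crossing(quintile = factor(quintile_levels(),
                                      levels = quintile_levels(),
                                      ordered = TRUE))
  out <- grid |>
    left_join(cells, by = c("indicator_id", "quintile", "baseline_year")) |>
    mutate(n_countries = dplyr::coalesce(.data$n_countries, 0L)) |>
    select("indicator_id", "quintile", "baseline_year",
           "avg_relative_change", "n_countries") |>
    arrange(.data$indicator_id, .data$quintile)
  structure(out, class = c("h2020_trends", class(out)))
}
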
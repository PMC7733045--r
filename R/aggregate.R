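#' Geometric mean
#'
#' Computed as the exponential of the mean log for numerical stability.
#' The geometric mean is the aggregator of choice here because normalized
#' component scores are only partially substitutable: a high score on one
#' indicator only partly compensates a low score on another, and an x%
#' change in any component moves the mean by the same factor. Inputs must
#' be strictly positive — the floor-at-1 rule upstream guarantees this for
#' indicator indices, and this function refuses rather than silently
#' repairs non-positive values.
#'
#' @param x Non-empty numeric vector of positive values.
#' @return The geometric mean, a single number in `[min(x), max(x)]`.
#' @examples
#' geometric_mean(c(4, 9))  # 6
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0) {
    stop_validation("geometric_mean: empty input")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_validation("geometric_mean: all values must be finite and > 0")
  }
  exp(mean(log(x)))
}

#' Missing-data aggregation policy
#'
#' A target is scored from whatever of its indicators are available and is
#' excluded only when fewer than `min_indicators_per_target` remain
#' (default 1: a target drops out only with *no* usable indicator). A
#' country is scorable while at least `min_targets_per_country` targets
#' survive (default 1). The defaults reproduce the published behaviour in
#' which five data-poor countries were scored on three of the five
#' quantitative targets.
#'
#' @param min_indicators_per_target Integer >= 1.
#' @param min_targets_per_country Integer >= 1.
#' @return An object of class `h2020_policy`.
#' @export
aggregation_policy <- function(min_indicators_per_target = 1,
                               min_targets_per_country = 1) {
  if (min_indicators_per_target < 1 || min_targets_per_country < 1) {
    stop_config("policy minima must be >= 1")
  }
  structure(
    list(
      min_indicators_per_target = as.integer(min_indicators_per_target),
      min_targets_per_country = as.integer(min_targets_per_country)
    ),
    class = "h2020_policy"
  )
}

#' Target indices from indicator indices
#'
#' For every (country, reference year, quantitative target) cell: the
#' geometric mean of the indicator indices mapped to that target that are
#' available for that country-year. When an indicator is missing it is
#' simply left out and `n_indicators_used` shrinks; when fewer than the
#' policy minimum remain the target is excluded (`excluded = TRUE`,
#' `index = NA`).
#'
#' @param indicator_indices Tibble with columns `country`,
#'   `indicator_id`, `reference_year`, `index`.
#' @param registry An `h2020_registry`.
#' @param policy An [aggregation_policy()].
#' @return Tibble with one row per (country, reference_year, quantitative
#'   target): `country`, `reference_year`, `target_id`, `index`,
#'   `n_indicators_used`, `excluded`.
#' @export
target_indices <- function(indicator_indices, registry,
                           policy = aggregation_policy()) {
  require_columns(indicator_indices,
                  c("country", "indicator_id", "reference_year", "index"),
                  "indicator index table")
  membership <- target_membership(registry) |>
    select("indicator_id", "target_id")
  cells <- indicator_indices |>
    inner_join(membership, by = "indicator_id",
               relationship = "many-to-many") |>
    group_by(.data$country, .data$reference_year, .data$target_id) |>
    summarise(
      n_indicators_used = dplyr::n(),
      index = geometric_mean(.data$index),
      .groups = "drop"
    )
  grid <- indicator_indices |>
    distinct(.data$country, .data$reference_year) |>
    tidyr::crossing(target_id = quantitative_target_ids(registry))
  grid |>
    left_join(cells, by = c("country", "reference_year", "target_id")) |>
    mutate(
      n_indicators_used = dplyr::coalesce(.data$n_indicators_used, 0L),
      excluded = .data$n_indicators_used < policy$min_indicators_per_target,
      index = dplyr::if_else(.data$excluded, NA_real_, .data$index)
    ) |>
    arrange(.data$country, .data$reference_year, .data$target_id)
}

#' Overall index from target indices
#'
#' The overall index of a country-year is the geometric mean of its
#' non-excluded target indices — the mean is taken by target, not by
#' indicator, because targets are treated as equally important (so an
#' indicator aligned to two targets implicitly counts twice). A country
#' with fewer than `min_targets_per_country` surviving targets is flagged
#' unscorable (`index = NA`) rather than dropped, so the attrition stays
#' visible.
#'
#' @param target_table Tibble from [target_indices()].
#' @param policy An [aggregation_policy()].
#' @return Tibble with one row per (country, reference_year): `country`,
#'   `reference_year`, `index`, `n_targets_used`, `unscorable`.
#' @export
overall_indices <- function(target_table, policy = aggregation_policy()) {
  require_columns(target_table,
                  c("country", "reference_year", "target_id", "index",
                    "excluded"),
                  "target index table")
  target_table |>
    group_by(.data$country, .data$reference_year) |>
    summarise(
      n_targets_used = sum(!.data$excluded),
      index = if (sum(!.data$excluded) >= policy$min_targets_per_country) {
        geometric_mean(.data$index[!.data$excluded])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(unscorable = is.na(.data$index)) |>
    select("country", "reference_year", "index", "n_targets_used",
           "unscorable") |>
    arrange(.data$country, .data$reference_year)
}

#' Compute the full index table for a panel
#'
#' End-to-end orchestration: resolve observations onto the reference years
#' (if not already resolved), apply the country inclusion filter on the
#' 2015 panel, compute pooled goalposts from the included countries,
#' rescale every observation to its indicator index, and aggregate to
#' target and overall indices for all three reference years. The result is
#' deterministic in the inputs and carries every audit flag (substitution,
#' flooring, per-cell n-used counts, exclusion reasons).
#'
#' @param observations Either a raw observation tibble
#'   (`country,indicator_id,year,value`) or an already-resolved tibble
#'   (with a `reference_year` column).
#' @param registry An `h2020_registry`.
#' @param policy An [aggregation_policy()].
#' @param window Substitution window in years (see
#'   [resolve_reference_years()]).
#' @param max_missing Country filter threshold (see
#'   [apply_country_filter()]).
#' @param filter_year Reference year the roster filter is evaluated on
#'   (default 2015).
#' @param goalposts Optional frozen goalposts tibble; default recomputes
#'   pooled goalposts from the included countries.
#' @return An object of class `h2020_index`: a list with tibbles
#'   `indicator_indices`, `target_indices`, `overall_indices`,
#'   `goalposts`, `inclusion`, plus the `policy` and `registry` used.
#'   Use [tidy()] for the long per-cell table and [glance()] for a
#'   one-row summary.
#' @export
compute_index_table <- function(observations, registry = default_registry(),
                                policy = aggregation_policy(), window = 2,
                                max_missing = 6, filter_year = 2015,
                                goalposts = NULL) {
  resolved <- if ("reference_year" %in% names(observations)) {
    require_columns(observations,
                    c("country", "indicator_id", "reference_year", "value"),
                    "resolved observation table")
    as_tibble(observations)
  } else {
    resolve_reference_years(observations, window = window)
  }
  if (!"substituted" %in% names(resolved)) resolved$substituted <- FALSE

  inclusion <- apply_country_filter(resolved, registry,
                                    reference_year = filter_year,
                                    max_missing = max_missing)
  included <- inclusion$country[inclusion$included]
  if (length(included) == 0) {
    stop_validation("no country passes the inclusion filter")
  }

  q_ids <- quantitative_indicators(registry)$indicator_id
  obs_inc <- resolved |>
    filter(.data$country %in% included, .data$indicator_id %in% q_ids)
  gp <- goalposts %||%
    compute_goalposts(resolved, registry, countries = included,
                      indicator_ids = sort(unique(obs_inc$indicator_id)))

  ind_idx <- obs_inc |>
    inner_join(gp |> select("indicator_id", "worst", "best"),
               by = "indicator_id") |>
    mutate(
      pre = 100 * (pmin(pmax(.data$value, pmin(.data$worst, .data$best)),
                        pmax(.data$worst, .data$best)) - .data$worst) /
        (.data$best - .data$worst),
      index = pmax(.data$pre, 1),
      floored = .data$pre < 1
    ) |>
    select(dplyr::any_of(c("country", "indicator_id", "reference_year",
                           "source_year", "value", "index", "floored",
                           "substituted"))) |>
    arrange(.data$country, .data$reference_year, .data$indicator_id)

  tgt <- target_indices(ind_idx, registry, policy)
  ov <- overall_indices(tgt, policy)

  structure(
    list(
      indicator_indices = ind_idx,
      target_indices = tgt,
      overall_indices = ov,
      goalposts = gp,
      inclusion = inclusion,
      policy = policy,
      registry = registry
    ),
    class = "h2020_index"
  )
}

#' @export
print.h2020_index <- function(x, ...) {
  ov15 <- x$overall_indices |>
    filter(.data$reference_year == 2015, !.data$unscorable)
  cat(sprintf(
    "<h2020_index> %d included / %d roster countries; %d indicator indices\n",
    sum(x$inclusion$included), nrow(x$inclusion),
    nrow(x$indicator_indices)
  ))
  if (nrow(ov15) > 0) {
    cat(sprintf("  overall index 2015: median %.1f, range %.1f-%.1f (n = %d)\n",
                stats::median(ov15$index), min(ov15$index), max(ov15$index),
                nrow(ov15)))
  }
  invisible(x)
}
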
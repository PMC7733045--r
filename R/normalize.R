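#' Pooled goalposts per indicator
#'
#' The goalposts anchoring the 1--100 rescale are the extreme raw values of
#' an indicator pooled across the three reference years and across the
#' included countries. `worst` and `best` are oriented by the indicator's
#' direction: for a `lower_better` indicator (e.g. infant mortality)
#' `worst` is the pooled maximum and `best` the pooled minimum.
#'
#' Goalposts are computed from included countries only, so that the sparse,
#' less reliable data of excluded countries never anchor the scale.
#'
#' @param table Resolved observation tibble
#'   ([resolve_reference_years()]).
#' @param registry An `h2020_registry`.
#' @param countries Optional roster restriction (typically the included
#'   countries); `NULL` pools over every country in `table`.
#' @param indicator_ids Optional subset of quantitative indicator ids;
#'   default: the quantitative indicators present in `table`.
#' @return A tibble with columns `indicator_id`, `direction`, `worst`,
#'   `best`, `n_values`.
#' @export
compute_goalposts <- function(table, registry, countries = NULL,
                              indicator_ids = NULL) {
  require_columns(table, c("country", "indicator_id", "value"),
                  "resolved observation table")
  q <- quantitative_indicators(registry)
  obs <- table |> filter(.data$indicator_id %in% q$indicator_id)
  if (!is.null(countries)) {
    obs <- obs |> filter(.data$country %in% countries)
  }
  ids <- indicator_ids %||% sort(unique(obs$indicator_id))
  bad <- setdiff(ids, q$indicator_id)
  if (length(bad) > 0) {
    stop_validation(sprintf("not (a) quantitative indicator id(s): %s",
                            paste(bad, collapse = ", ")))
  }
  purrr::map_dfr(ids, function(id) {
    vals <- obs$value[obs$indicator_id == id]
    if (length(vals) == 0) {
      stop_validation(sprintf("no data to compute goalposts for indicator %d", id))
    }
    if (diff(range(vals)) == 0) {
      stop_validation(sprintf(
        "degenerate goalposts for indicator %d: all %d value(s) equal %g",
        id, length(vals), vals[1]
      ))
    }
    dir <- q$direction[q$indicator_id == id]
    tibble(
      indicator_id = as.integer(id),
      direction = dir,
      worst = if (dir == "higher_better") min(vals) else max(vals),
      best = if (dir == "higher_better") max(vals) else min(vals),
      n_values = length(vals)
    )
  })
}

#' Rescale a raw value between goalposts onto the 1--100 index scale
#'
#' The pre-floor score is the affine map `100 * (value - worst) /
#' (best - worst)`; because `worst` and `best` are direction-oriented the
#' same formula serves both directions and a higher index always means
#' better health. Values outside the goalpost range (possible when frozen
#' goalposts meet new data) are clipped to the range first. Scores below 1
#' are floored at 1 so that downstream geometric means stay defined; the
#' `floored` flag records where this happened.
#'
#' @param value Numeric vector of raw values (indicator's native units).
#' @param worst,best Goalposts in native units (scalars or vectors recycled
#'   against `value`); `worst != best`.
#' @param detail If `TRUE`, return a tibble with `value`, `index`,
#'   `floored`; otherwise the numeric index vector.
#' @return Numeric vector in \[1, 100\], or a tibble when `detail = TRUE`.
#' @examples
#' rescale(80, worst = 40, best = 80)   # 100
#' rescale(40, worst = 40, best = 80)   # 1 (floored)
#' rescale(60, worst = 40, best = 80)   # 50
#' @export
rescale <- function(value, worst, best, detail = FALSE) {
  if (any(!is.finite(value))) {
    stop_validation("rescale: all values must be finite")
  }
  if (any(worst == best)) {
    stop_validation("rescale: degenerate goalposts (worst == best)")
  }
  lo <- pmin(worst, best)
  hi <- pmax(worst, best)
  clipped <- pmin(pmax(value, lo), hi)
  pre <- 100 * (clipped - worst) / (best - worst)
  index <- pmax(pre, 1)
  if (detail) {
    tibble(value = value, index = index, floored = pre < 1)
  } else {
    index
  }
}

#' Freeze and reload goalposts
#'
#' Exporting goalposts lets users score new data against a frozen scale
#' (e.g. the scale of an earlier run) instead of recomputing pooled
#' extremes.
#'
#' @param goalposts Tibble from [compute_goalposts()].
#' @param path CSV path (`indicator_id,worst,best,n_values`).
#' @return `path` (write) / the goalposts tibble (read).
#' @export
write_goalposts <- function(goalposts, path) {
  goalposts |>
    select("indicator_id", "worst", "best", "n_values") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_goalposts
#' @param registry Registry used to re-attach indicator directions.
#' @export
read_goalposts <- function(path, registry = default_registry()) {
  gp <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(gp, c("indicator_id", "worst", "best"), "goalposts CSV")
  if (any(gp$worst == gp$best)) {
    stop_validation("goalposts CSV contains degenerate goalposts (worst == best)")
  }
  dirs <- registry$indicators |>
    select("indicator_id", "direction")
  gp |>
    mutate(indicator_id = as.integer(.data$indicator_id)) |>
    left_join(dirs, by = "indicator_id") |>
    select("indicator_id", "direction", "worst", "best",
           dplyr::any_of("n_values"))
}
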
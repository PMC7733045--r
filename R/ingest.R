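#' Read a long-format indicator panel
#'
#' Reads a CSV with columns `country,indicator_id,year,value` (header
#' required, UTF-8). Rows for qualitative indicators are dropped with a
#' message (they are monitored but never scored); rows with unknown
#' indicator ids or non-numeric values are rejected with the offending row
#' number.
#'
#' @param file Path to the CSV, or a data frame already in that shape.
#' @param registry An `h2020_registry` (default: the packaged registry).
#' @param quiet Suppress the dropped-row message.
#' @return A tibble with columns `country` (character), `indicator_id`
#'   (integer), `year` (integer), `value` (double), restricted to
#'   quantitative indicators.
#' @export
read_observations <- function(file, registry = default_registry(),
                              quiet = FALSE) {
  if (is.data.frame(file)) {
    df <- as_tibble(file)
  } else {
    if (!file.exists(file)) {
      stop_parse(sprintf("input file not found: %s", file))
    }
    df <- tryCatch(
      readr::read_csv(
        file,
        col_types = readr::cols(
          country = readr::col_character(),
          indicator_id = readr::col_character(),
          year = readr::col_character(),
          value = readr::col_character()
        ),
        progress = FALSE
      ),
      error = function(e) stop_parse(sprintf("cannot read %s: %s", file,
                                             conditionMessage(e)))
    )
  }
  require_columns(df, c("country", "indicator_id", "year", "value"),
                  "observation table")
  if (nrow(df) == 0) {
    stop_parse("observation table has no rows")
  }

  parse_int <- function(x) suppressWarnings(as.integer(as.character(x)))
  parse_dbl <- function(x) suppressWarnings(as.numeric(as.character(x)))

  out <- tibble(
    row = seq_len(nrow(df)),
    country = as.character(df$country),
    indicator_id = parse_int(df$indicator_id),
    year = parse_int(df$year),
    value = parse_dbl(df$value)
  )

  bad <- function(cond, what, raw) {
    i <- which(cond)
    if (length(i) > 0) {
      stop_parse(sprintf("row %d: %s ('%s')", i[1], what,
                         as.character(raw)[i[1]]))
    }
  }
  bad(is.na(out$country) | out$country == "", "missing country code",
      df$country)
  bad(is.na(out$indicator_id), "indicator_id is not an integer",
      df$indicator_id)
  bad(is.na(out$year), "year is not an integer", df$year)
  bad(is.na(out$value) | !is.finite(out$value), "value is not a finite number",
      df$value)

  known <- registry$indicators$indicator_id
  unknown <- !(out$indicator_id %in% known)
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop_parse(sprintf("row %d: unknown indicator id %d", i,
                       out$indicator_id[i]))
  }
  qual <- registry$indicators$indicator_id[!registry$indicators$is_quantitative]
  n_qual <- sum(out$indicator_id %in% qual)
  if (n_qual > 0 && !quiet) {
    inform(sprintf(
      "dropped %d row(s) for qualitative indicator(s) %s (not scored)",
      n_qual, paste(intersect(qual, out$indicator_id), collapse = ", ")
    ))
  }
  out |>
    filter(!(.data$indicator_id %in% qual)) |>
    select("country", "indicator_id", "year", "value")
}

#' Resolve raw observations onto the reference years
#'
#' For each (country, indicator, reference year in 2005/2010/2015) the
#' observation at the reference year itself is used when present; otherwise
#' the closest observation within `window` years substitutes for it and is
#' flagged (`substituted = TRUE`, the asterisk of published index tables).
#' When two source years are equally close the later one is preferred.
#' A cell with no observation in the window is simply absent — missingness
#' is a legal state handled downstream.
#'
#' @param series Tibble with columns `country`, `indicator_id`, `year`,
#'   `value` (as returned by [read_observations()]).
#' @param window Non-negative integer: maximal |source year - reference
#'   year| allowed for substitution (default 2).
#' @return A tibble with columns `country`, `indicator_id`,
#'   `reference_year`, `source_year`, `value`, `substituted`, at most one
#'   row per (country, indicator, reference year).
#' @export
resolve_reference_years <- function(series, window = 2) {
  if (!is.numeric(window) || length(window) != 1 || is.na(window) ||
      window < 0) {
    stop_config("window must be a single non-negative number")
  }
  require_columns(series, c("country", "indicator_id", "year", "value"),
                  "observation series")
  purrr::map_dfr(reference_years(), function(ry) {
    series |>
      filter(abs(.data$year - ry) <= window) |>
      mutate(reference_year = ry,
             distance = abs(.data$year - ry)) |>
      group_by(.data$country, .data$indicator_id) |>
      arrange(.data$distance, desc(.data$year), .data$value,
              .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup() |>
      transmute(
        country = .data$country,
        indicator_id = .data$indicator_id,
        reference_year = .data$reference_year,
        source_year = as.integer(.data$year),
        value = .data$value,
        substituted = .data$year != ry
      )
  }) |>
    arrange(.data$country, .data$indicator_id, .data$reference_year)
}

#' Country inclusion filter
#'
#' A country is excluded from the index when data for more than
#' `max_missing` of the quantitative indicators are absent at the given
#' reference year (the published roster rule with `max_missing = 6`:
#' missing exactly six still qualifies). Indicators whose data do not exist
#' at all at that reference year (e.g. 2015-only indicators when auditing
#' 2005) are not counted against any country.
#'
#' @param table Resolved observation tibble from
#'   [resolve_reference_years()].
#' @param registry An `h2020_registry`.
#' @param reference_year One of 2005, 2010, 2015 (default 2015, the year
#'   the study-level roster is defined on).
#' @param max_missing Maximal number of missing countable indicators a
#'   country may have and still be included (default 6).
#' @param countries Optional explicit roster; defaults to every country
#'   appearing anywhere in `table`.
#' @return A tibble with one row per roster country: `country`,
#'   `n_missing`, `n_countable`, `included`, `reason` (NA when included).
#' @export
apply_country_filter <- function(table, registry, reference_year = 2015,
                                 max_missing = 6, countries = NULL) {
  if (!reference_year %in% reference_years()) {
    stop_config("reference_year must be one of 2005, 2010, 2015")
  }
  if (max_missing < 0) stop_config("max_missing must be >= 0")
  require_columns(table, c("country", "indicator_id", "reference_year"),
                  "resolved observation table")

  countable <- quantitative_indicators(registry) |>
    filter(purrr::map_lgl(.data$available_reference_years,
                          ~ reference_year %in% .x))
  n_countable <- nrow(countable)
  roster <- sort(unique(countries %||% table$country))

  present <- table |>
    filter(.data$reference_year == !!reference_year,
           .data$indicator_id %in% countable$indicator_id,
           .data$country %in% roster) |>
    distinct(.data$country, .data$indicator_id) |>
    count(.data$country, name = "n_present")

  tibble(country = roster) |>
    left_join(present, by = "country") |>
    mutate(
      n_present = dplyr::coalesce(.data$n_present, 0L),
      n_missing = n_countable - .data$n_present,
      n_countable = n_countable,
      included = .data$n_missing <= max_missing,
      reason = dplyr::if_else(
        .data$included,
        NA_character_,
        sprintf("data absent for %d of %d quantitative indicators at %d (more than %d)",
                .data$n_missing, n_countable, reference_year, as.integer(max_missing))
      )
    ) |>
    select("country", "n_missing", "n_countable", "included", "reason")
}

#' Write an inclusion report as JSON
#'
#' @param report Tibble from [apply_country_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inclusion_report <- function(report, path) {
  excl <- report |> filter(!.data$included)
  obj <- list(
    included = report$country[report$included],
    excluded = purrr::pmap(
      list(excl$country, excl$reason, excl$n_missing),
      function(country, reason, n) {
        list(country = country, reason = reason, missing_indicator_count = n)
      }
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
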
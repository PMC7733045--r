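#' The Health 2020 indicator/target registry
#'
#' The registry declares the structure of the monitoring framework: which
#' indicators exist, whether each is quantitative, its direction (whether a
#' larger raw value means better or worse health), which policy targets it
#' informs, and the reference years for which data exist at all. The default
#' registry shipped with the package encodes the published framework
#' structure: 19 indicators on 6 targets, of which 16 indicators and targets
#' 1--5 are quantitative; indicators 7, 9 and 10 sit on two targets each (as
#' does the qualitative indicator 11); indicators 2 and 14 are observed only
#' in 2015 and indicators 4 and 12 only from 2010 onward.
#'
#' The mapping is deliberately *data*, not code: it lives in a JSON file
#' (`system.file("extdata", "registry.json", package = "health2020")`) that
#' users can copy, edit and pass back through `load_registry()`, e.g. to
#' resolve the framework's ambiguities differently or to score a revised
#' indicator set.
#'
#' @param path Path to a registry JSON file (top-level keys `indicators` and
#'   `targets`), or to an indicators CSV when `targets` is also given.
#'   `NULL` (default) loads the packaged registry.
#' @param targets Optional path to a targets CSV, for the two-file CSV form.
#'   In CSV form, `target_ids` and `available_reference_years` are
#'   semicolon-separated lists (e.g. `"3;4"`).
#'
#' @return An object of class `h2020_registry`: a list with tibbles
#'   `indicators` (columns `indicator_id`, `name`, `is_quantitative`,
#'   `direction`, and list-columns `target_ids`,
#'   `available_reference_years`) and `targets` (columns `target_id`,
#'   `name`, `is_quantitative`).
#' @examples
#' reg <- default_registry()
#' nrow(reg$indicators)            # 19
#' nrow(quantitative_indicators(reg))  # 16
#' @export
load_registry <- function(path = NULL, targets = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "registry.json",
                        package = "health2020", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop_config(sprintf("registry file not found: %s", path))
  }
  if (!is.null(targets)) {
    ind <- tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
      error = function(e) stop_parse(sprintf("cannot parse indicators CSV: %s", conditionMessage(e)))
    )
    tar <- tryCatch(
      readr::read_csv(targets, show_col_types = FALSE, progress = FALSE),
      error = function(e) stop_parse(sprintf("cannot parse targets CSV: %s", conditionMessage(e)))
    )
    require_columns(ind, c("indicator_id", "name", "is_quantitative",
                           "direction", "target_ids",
                           "available_reference_years"), "indicators CSV")
    require_columns(tar, c("target_id", "name", "is_quantitative"),
                    "targets CSV")
    ind <- ind |>
      mutate(
        target_ids = purrr::map(strsplit(as.character(.data$target_ids), ";"),
                                ~ as.integer(.x)),
        available_reference_years = purrr::map(
          strsplit(as.character(.data$available_reference_years), ";"),
          ~ as.integer(.x)
        )
      )
  } else {
    raw <- tryCatch(
      jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
      error = function(e) stop_parse(sprintf("cannot parse registry JSON: %s", conditionMessage(e)))
    )
    if (!all(c("indicators", "targets") %in% names(raw))) {
      stop_parse("registry JSON must have top-level keys 'indicators' and 'targets'")
    }
    ind <- as_tibble(raw$indicators)
    tar <- as_tibble(raw$targets)
    ind$target_ids <- purrr::map(ind$target_ids, as.integer)
    ind$available_reference_years <-
      purrr::map(ind$available_reference_years, as.integer)
  }
  new_registry(ind, tar)
}

#' @rdname load_registry
#' @export
default_registry <- function() {
  load_registry(NULL)
}

new_registry <- function(indicators, targets) {
  indicators <- indicators |>
    mutate(
      indicator_id = as.integer(.data$indicator_id),
      name = as.character(.data$name),
      is_quantitative = as.logical(.data$is_quantitative),
      direction = as.character(.data$direction)
    ) |>
    select("indicator_id", "name", "is_quantitative", "direction",
           "target_ids", "available_reference_years") |>
    arrange(.data$indicator_id)
  targets <- targets |>
    mutate(
      target_id = as.integer(.data$target_id),
      name = as.character(.data$name),
      is_quantitative = as.logical(.data$is_quantitative)
    ) |>
    arrange(.data$target_id)
  reg <- structure(list(indicators = indicators, targets = targets),
                   class = "h2020_registry")
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  ind <- reg$indicators
  tar <- reg$targets

  dup <- ind$indicator_id[duplicated(ind$indicator_id)]
  if (length(dup) > 0) {
    stop_config(sprintf("duplicate indicator id(s): %s",
                        paste(unique(dup), collapse = ", ")))
  }
  dup_t <- tar$target_id[duplicated(tar$target_id)]
  if (length(dup_t) > 0) {
    stop_config(sprintf("duplicate target id(s): %s",
                        paste(unique(dup_t), collapse = ", ")))
  }
  if (any(ind$indicator_id < 1L | ind$indicator_id > 19L)) {
    stop_config("indicator ids must lie in 1..19")
  }
  if (any(tar$target_id < 1L | tar$target_id > 6L)) {
    stop_config("target ids must lie in 1..6")
  }
  if (!all(ind$direction %in% c("higher_better", "lower_better"))) {
    stop_config("indicator direction must be 'higher_better' or 'lower_better'")
  }
  empty_targets <- ind$is_quantitative & purrr::map_int(ind$target_ids, length) == 0L
  if (any(empty_targets)) {
    stop_config(sprintf(
      "quantitative indicator(s) with empty target set: %s",
      paste(ind$indicator_id[empty_targets], collapse = ", ")
    ))
  }
  referenced <- sort(unique(unlist(ind$target_ids)))
  unknown <- setdiff(referenced, tar$target_id)
  if (length(unknown) > 0) {
    stop_config(sprintf("indicator(s) reference unknown target(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  bad_years <- purrr::map_lgl(
    ind$available_reference_years,
    ~ length(.x) == 0L || !all(.x %in% reference_years())
  )
  if (any(bad_years)) {
    stop_config(sprintf(
      "available_reference_years must be a non-empty subset of {2005, 2010, 2015} (indicator(s) %s)",
      paste(ind$indicator_id[bad_years], collapse = ", ")
    ))
  }
  invisible(reg)
}

#' @export
print.h2020_registry <- function(x, ...) {
  nq <- sum(x$indicators$is_quantitative)
  cat(sprintf(
    "<h2020_registry> %d indicators (%d quantitative) on %d targets (%d quantitative)\n",
    nrow(x$indicators), nq, nrow(x$targets), sum(x$targets$is_quantitative)
  ))
  invisible(x)
}

#' Quantitative indicators of a registry
#'
#' Filters the registry down to the indicators that enter the index (the
#' qualitative ones are monitored but never scored), in stable id order.
#'
#' @param registry An `h2020_registry`.
#' @return A tibble of indicator definitions with `is_quantitative = TRUE`.
#' @export
quantitative_indicators <- function(registry) {
  stopifnot(inherits(registry, "h2020_registry"))
  registry$indicators |>
    filter(.data$is_quantitative) |>
    arrange(.data$indicator_id)
}

#' Indicators informing one quantitative target
#'
#' An indicator aligned to two targets appears in both targets' lists and
#' therefore carries relatively more weight in the overall index.
#'
#' @param registry An `h2020_registry`.
#' @param target_id Integer id of a quantitative target.
#' @return A tibble of quantitative indicator definitions whose target set
#'   contains `target_id`.
#' @export
indicators_for_target <- function(registry, target_id) {
  stopifnot(inherits(registry, "h2020_registry"))
  trow <- registry$targets |> filter(.data$target_id == !!target_id)
  if (nrow(trow) == 0) {
    stop_validation(sprintf("unknown target id: %s", target_id))
  }
  if (!trow$is_quantitative) {
    stop_validation(sprintf(
      "target %d is qualitative and has no indicator index", target_id
    ))
  }
  quantitative_indicators(registry) |>
    filter(purrr::map_lgl(.data$target_ids, ~ target_id %in% .x))
}

# quantitative indicator -> target memberships, one row per membership
target_membership <- function(registry) {
  quantitative_indicators(registry) |>
    select("indicator_id", "direction", "target_ids") |>
    tidyr::unnest_longer("target_ids", values_to = "target_id") |>
    mutate(target_id = as.integer(.data$target_id))
}

# quantitative target ids, ascending
quantitative_target_ids <- function(registry) {
  registry$targets$target_id[registry$targets$is_quantitative]
}
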
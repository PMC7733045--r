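#' @importFrom rlang %||% abort inform warn .data
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   left_join inner_join distinct n transmute row_number desc bind_rows
#'   rename count across
#' @importFrom tibble tibble as_tibble
NULL

# the three reference years every panel is resolved onto
reference_years <- function() c(2005L, 2010L, 2015L)

stop_config <- function(msg, ...) {
  abort(msg, class = "h2020_config_error", ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = "h2020_parse_error", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "h2020_validation_error", ...)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_parse(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
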
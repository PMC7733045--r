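#' Run configuration for the pipeline front end
#'
#' Bundles every tunable of a pipeline run: input/registry paths, the
#' policy parameters, the output directory and the simulation settings.
#' Round-trips unchanged through YAML or JSON via [read_run_config()].
#'
#' @param input Path to the long-format input CSV (for [run_compute()]).
#' @param registry Path to a registry JSON; `NULL` uses the packaged one.
#' @param out_dir Output directory (created if absent on run).
#' @param window Substitution window in years (default 2).
#' @param max_missing Country-filter threshold (default 6).
#' @param min_indicators_per_target,min_targets_per_country Aggregation
#'   policy minima (defaults 1).
#' @param n_countries,seed Simulation settings (defaults 50 / 1).
#' @param verbose Narrate stage counts (default TRUE).
#' @return An object of class `h2020_run_config`.
#' @export
run_config <- function(input = NULL, registry = NULL, out_dir = ".",
                       window = 2, max_missing = 6,
                       min_indicators_per_target = 1,
                       min_targets_per_country = 1,
                       n_countries = 50, seed = 1, verbose = TRUE) {
  if (window < 0) stop_config("window must be >= 0")
  if (max_missing < 0) stop_config("max_missing must be >= 0")
  if (min_indicators_per_target < 1 || min_targets_per_country < 1) {
    stop_config("policy minima must be >= 1")
  }
  if (n_countries < 1) stop_config("n_countries must be >= 1")
  structure(
    list(
      input = input, registry = registry, out_dir = out_dir,
      window = window, max_missing = max_missing,
      min_indicators_per_target = as.integer(min_indicators_per_target),
      min_targets_per_country = as.integer(min_targets_per_country),
      n_countries = as.integer(n_countries), seed = as.integer(seed),
      verbose = isTRUE(verbose)
    ),
    class = "h2020_run_config"
  )
}

#' @rdname run_config
#' @param path Path to a YAML or JSON file with `run_config()` fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  raw <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) stop_parse(sprintf("cannot parse config %s: %s",
                                           path, conditionMessage(e)))
  )
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown config field(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

config_registry <- function(config) {
  if (is.null(config$registry)) default_registry() else load_registry(config$registry)
}

config_policy <- function(config) {
  aggregation_policy(config$min_indicators_per_target,
                     config$min_targets_per_country)
}

ensure_out_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    stop_config(sprintf("cannot create output directory: %s", config$out_dir))
  }
  config$out_dir
}

say <- function(config, fmt, ...) {
  if (config$verbose) inform(sprintf(fmt, ...))
  invisible(NULL)
}

out_path <- function(config, file) file.path(config$out_dir, file)

#' Pipeline front-end commands
#'
#' `run_simulate()` writes a synthetic panel (`panel.csv`) and its ground
#' truth (`truth.json`); `run_compute()` runs ingest, normalization and
#' aggregation on an input panel, writing `observations_resolved.csv`,
#' `inclusion_report.json`, `goalposts.csv` and `index_table.csv`;
#' `run_report()` builds the presentation outputs from a compute run:
#' `quintiles.csv`, `boundaries.json`, `trends.csv`, and `ranking.csv`, a
#' ranked country summary at one-decimal display precision in which
#' substituted indicator indices carry an asterisk. All three are
#' deterministic: rerunning on the same inputs reproduces the files
#' byte for byte. A thin command-line wrapper around them ships at
#' `system.file("scripts", "h2020", package = "health2020")`.
#'
#' @param config An [run_config()] object.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "h2020_run_config"))
  ensure_out_dir(config)
  reg <- config_registry(config)
  sim <- generate_panel(
    synthetic_config(n_countries = config$n_countries, seed = config$seed),
    reg
  )
  readr::write_csv(sim$observations, out_path(config, "panel.csv"))
  jsonlite::write_json(
    list(
      config = sim$config[c("n_countries", "seed", "gradient_strength",
                            "noise_sd", "missing_rate_base",
                            "missing_rate_slope")],
      latent_capacity = stats::setNames(
        as.list(sim$truth$latent_capacity), sim$truth$country
      )
    ),
    out_path(config, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  say(config, "simulate: wrote %d observations for %d countries",
      nrow(sim$observations), nrow(sim$truth))
  invisible(config$out_dir)
}

#' @rdname run_simulate
#' @export
run_compute <- function(config) {
  stopifnot(inherits(config, "h2020_run_config"))
  if (is.null(config$input)) stop_config("config lacks an input path")
  ensure_out_dir(config)
  reg <- config_registry(config)

  series <- read_observations(config$input, reg, quiet = !config$verbose)
  say(config, "compute: read %d quantitative observation rows", nrow(series))
  resolved <- resolve_reference_years(series, window = config$window)
  say(config, "compute: resolved %d cells (%d substituted)",
      nrow(resolved), sum(resolved$substituted))

  result <- compute_index_table(
    resolved, reg, policy = config_policy(config),
    window = config$window, max_missing = config$max_missing
  )
  say(config, "compute: %d of %d countries included",
      sum(result$inclusion$included), nrow(result$inclusion))

  readr::write_csv(resolved, out_path(config, "observations_resolved.csv"))
  write_inclusion_report(result$inclusion,
                         out_path(config, "inclusion_report.json"))
  write_goalposts(result$goalposts, out_path(config, "goalposts.csv"))
  readr::write_csv(tidy(result), out_path(config, "index_table.csv"))
  invisible(config$out_dir)
}

#' @rdname run_simulate
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "h2020_run_config"))
  needed <- c("index_table.csv", "observations_resolved.csv")
  for (f in needed) {
    if (!file.exists(out_path(config, f))) {
      stop_validation(sprintf("missing compute output: %s (run run_compute first)",
                              out_path(config, f)))
    }
  }
  reg <- config_registry(config)
  idx <- readr::read_csv(out_path(config, "index_table.csv"),
                         show_col_types = FALSE, progress = FALSE)
  resolved <- readr::read_csv(out_path(config, "observations_resolved.csv"),
                              show_col_types = FALSE, progress = FALSE)

  overall15 <- idx |>
    filter(.data$level == "overall", .data$reference_year == 2015,
           !is.na(.data$index)) |>
    select("country", "index")
  qs <- assign_quintiles(overall15)
  readr::write_csv(as_tibble(qs), out_path(config, "quintiles.csv"))
  jsonlite::write_json(quintile_boundaries(qs),
                       out_path(config, "boundaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  trends <- trend_table(resolved, reg, qs)
  readr::write_csv(as_tibble(trends), out_path(config, "trends.csv"))

  ranking <- build_ranking_table(idx, qs, reg)
  readr::write_csv(ranking, out_path(config, "ranking.csv"))
  say(config, "report: ranked %d countries, %d trend cells",
      nrow(ranking), nrow(trends))
  invisible(config$out_dir)
}

# Figure-2-style ranked summary: one row per country, overall and
# per-target indices at one decimal, per-indicator cells carrying an
# asterisk where the +/-2-year substitution was used
build_ranking_table <- function(idx, assignment, registry) {
  fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  ov <- assignment |>
    as_tibble() |>
    mutate(overall_index = fmt1(.data$index)) |>
    select("country", "rank", "quintile", "overall_index")
  tgt <- idx |>
    filter(.data$level == "target", .data$reference_year == 2015) |>
    mutate(col = sprintf("target_%d", .data$id), cell = fmt1(.data$index)) |>
    select("country", "col", "cell") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
  ind <- idx |>
    filter(.data$level == "indicator", .data$reference_year == 2015) |>
    mutate(
      col = sprintf("indicator_%02d", .data$id),
      cell = paste0(fmt1(.data$index),
                    ifelse(!is.na(.data$substituted) & .data$substituted,
                           "*", ""))
    ) |>
    select("country", "col", "cell") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
  ov |>
    left_join(tgt, by = "country") |>
    left_join(ind, by = "country") |>
    arrange(.data$rank)
}
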
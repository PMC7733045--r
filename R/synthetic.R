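#' Configuration for the synthetic indicator-panel generator
#'
#' The generator emulates the structure of the WHO-European indicator
#' panel the index was designed for: ~50 countries arranged along a latent
#' capacity gradient (the published east-west gradient), 16 quantitative
#' indicators of mixed direction with per-decade drifts of mixed sign,
#' availability windows (2015-only and 2010-onward indicators produce no
#' earlier rows), and cell-level missingness concentrated in low-capacity
#' countries (mirroring weaker civil-registration systems).
#'
#' Model, for country i, indicator k, year t:
#' latent capacity `c_i = gradient_strength * position_i + N(0, noise_sd)`
#' with positions spaced on \[-1, 1\] from best (first country code) to
#' worst; raw value `v = a_k + b_k * (c_i + d_k * (t - 2005)/10 + eta)`,
#' `eta ~ N(0, noise_sd)` per cell, with the sign of `b_k` matched to the
#' indicator's direction so high capacity means better on every indicator;
#' each cell is then dropped independently with probability
#' `missing_rate_base + missing_rate_slope * (1 - rank-normalized c_i)`.
#'
#' @param n_countries Number of countries (default 50, the published
#'   roster size).
#' @param seed Integer seed; a fixed seed reproduces the panel exactly.
#' @param gradient_strength Spread of latent capacity along the country
#'   axis (default 1).
#' @param noise_sd Gaussian noise SD on the latent scale, applied both to
#'   the latent capacities and per observation cell (default 0.1).
#' @param missing_rate_base Baseline per-cell missingness probability
#'   (default 0.05).
#' @param missing_rate_slope Extra missingness for the lowest-capacity
#'   country, linearly decreasing to 0 for the highest (default 0.15).
#' @param year_trend Optional named numeric vector of per-indicator drifts
#'   per decade on the direction-adjusted latent scale (positive =
#'   improvement), named by indicator id; defaults to
#'   [default_year_trend()].
#' @return An object of class `h2020_sim_config`.
#' @export
synthetic_config <- function(n_countries = 50, seed = 1,
                             gradient_strength = 1, noise_sd = 0.1,
                             missing_rate_base = 0.05,
                             missing_rate_slope = 0.15,
                             year_trend = NULL) {
  if (n_countries < 1) stop_config("n_countries must be >= 1")
  if (gradient_strength < 0) stop_config("gradient_strength must be >= 0")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (missing_rate_base < 0 || missing_rate_base >= 1) {
    stop_config("missing_rate_base must lie in [0, 1)")
  }
  if (missing_rate_slope < 0) stop_config("missing_rate_slope must be >= 0")
  structure(
    list(
      n_countries = as.integer(n_countries),
      seed = as.integer(seed),
      gradient_strength = gradient_strength,
      noise_sd = noise_sd,
      missing_rate_base = missing_rate_base,
      missing_rate_slope = missing_rate_slope,
      year_trend = year_trend
    ),
    class = "h2020_sim_config"
  )
}

#' Default per-indicator decade drifts
#'
#' Signed drift per decade on the direction-adjusted latent scale
#' (positive = improvement), emulating the published trend pattern: clear
#' improvement on the mortality and life-expectancy indicators, a decline
#' on overweight, and flat (hence noise-dominated, quintile-varying)
#' trajectories for school enrolment and unemployment.
#'
#' @param registry An `h2020_registry`.
#' @return Named numeric vector over the quantitative indicator ids.
#' @export
default_year_trend <- function(registry = default_registry()) {
  ids <- quantitative_indicators(registry)$indicator_id
  drift <- stats::setNames(rep(0.2, length(ids)), ids)
  strong <- intersect(c(1, 6, 7, 8), ids)     # mortality / life expectancy
  drift[as.character(strong)] <- 0.5
  if ("4" %in% names(drift)) drift["4"] <- -0.3   # overweight worsens
  flat <- intersect(c(9, 10), ids)            # enrolment / unemployment
  drift[as.character(flat)] <- 0
  drift
}

#' Generate a synthetic indicator panel with known ground truth
#'
#' @param config An [synthetic_config()] object.
#' @param registry An `h2020_registry`.
#' @return An object of class `h2020_sim`: a list with `observations`
#'   (long tibble `country,indicator_id,year,value` accepted by the
#'   ingest functions), `truth` (tibble `country`, `position`,
#'   `latent_capacity`), and the `config`. Deterministic for a fixed seed.
#' @examples
#' sim <- generate_panel(synthetic_config(n_countries = 10, seed = 42))
#' head(sim$observations)
#' @export
generate_panel <- function(config, registry = default_registry()) {
  stopifnot(inherits(config, "h2020_sim_config"))
  q <- quantitative_indicators(registry)
  trend <- config$year_trend %||% default_year_trend(registry)
  missing_drift <- setdiff(as.character(q$indicator_id), names(trend))
  if (length(missing_drift) > 0) {
    stop_config(sprintf("year_trend lacks drift(s) for indicator(s): %s",
                        paste(missing_drift, collapse = ", ")))
  }

  withr::with_seed(config$seed, {
    n <- config$n_countries
    codes <- sprintf("C%02d", seq_len(n))
    position <- if (n == 1) 0 else seq(1, -1, length.out = n)
    capacity <- config$gradient_strength * position +
      stats::rnorm(n, 0, config$noise_sd)
    truth <- tibble(country = codes, position = position,
                    latent_capacity = capacity)

    # rank-normalized capacity in [0, 1]; 1 = highest capacity
    rank01 <- if (n == 1) 1 else (rank(capacity, ties.method = "first") - 1) / (n - 1)
    p_miss <- pmin(config$missing_rate_base +
                     config$missing_rate_slope * (1 - rank01), 0.95)

    obs <- purrr::map_dfr(seq_len(nrow(q)), function(j) {
      id <- q$indicator_id[j]
      s <- if (q$direction[j] == "higher_better") 1 else -1
      d <- trend[[as.character(id)]]
      years <- intersect(reference_years(), q$available_reference_years[[j]])
      purrr::map_dfr(sort(years), function(yr) {
        adj <- capacity + d * (yr - 2005) / 10 +
          stats::rnorm(n, 0, config$noise_sd)
        keep <- stats::runif(n) >= p_miss
        tibble(
          country = codes[keep],
          indicator_id = as.integer(id),
          year = as.integer(yr),
          value = 50 + s * 10 * adj[keep]
        )
      })
    }) |>
      arrange(.data$country, .data$indicator_id, .data$year)

    structure(list(observations = obs, truth = truth, config = config),
              class = "h2020_sim")
  })
}

#' @export
print.h2020_sim <- function(x, ...) {
  cat(sprintf(
    "<h2020_sim> %d countries, %d observations (seed %d)\n",
    nrow(x$truth), nrow(x$observations), x$config$seed
  ))
  invisible(x)
}

#' The packaged 53-country fixture roster
#'
#' A deterministic synthetic roster mirroring the shape of the WHO
#' European Region membership: 53 candidate countries of which exactly
#' three "microstates" miss more than six quantitative indicators on the
#' 2015 panel and therefore fall to the inclusion filter, leaving 50
#' scored countries. A handful of cells are shifted off the reference
#' years to exercise the +/-2-year substitution flags. The fixture is
#' generated from a fixed internal seed, so regeneration is byte-stable;
#' it is synthetic data, not WHO data.
#'
#' @param registry An `h2020_registry`.
#' @return An object of class `h2020_fixture`: a list with
#'   `observations`, `countries` (all 53 codes), `expected_excluded` (the
#'   three microstate codes), and `truth`.
#' @export
make_fixture_roster <- function(registry = default_registry()) {
  cfg <- synthetic_config(
    n_countries = 53, seed = 20200630L, gradient_strength = 1,
    noise_sd = 0.1, missing_rate_base = 0.02, missing_rate_slope = 0
  )
  sim <- generate_panel(cfg, registry)
  obs <- sim$observations
  micro <- c("C07", "C29", "C46")
  sparse_ids <- c(1L, 3L, 5L, 6L, 7L, 8L, 9L, 10L, 13L, 15L)

  # microstates: drop 10 of the 16 quantitative indicators entirely
  obs <- obs |>
    filter(!(.data$country %in% micro & .data$indicator_id %in% sparse_ids))

  # structural guarantee: no other country may cross the >6-missing
  # cut-off at 2015; restore any randomly-dropped cells from the
  # noiseless latent model (deterministic)
  q <- quantitative_indicators(registry)
  counts <- obs |>
    filter(.data$year == 2015, !(.data$country %in% micro)) |>
    distinct(.data$country, .data$indicator_id) |>
    count(.data$country)
  offenders <- counts$country[counts$n < nrow(q) - 6L]
  offenders <- union(offenders,
                     setdiff(sim$truth$country,
                             c(micro, unique(obs$country[obs$year == 2015]))))
  if (length(offenders) > 0) {
    cap <- stats::setNames(sim$truth$latent_capacity, sim$truth$country)
    fills <- tidyr::crossing(country = sort(offenders),
                             indicator_id = q$indicator_id,
                             year = 2015L) |>
      dplyr::anti_join(obs, by = c("country", "indicator_id", "year")) |>
      left_join(q |> select("indicator_id", "direction"),
                by = "indicator_id") |>
      mutate(value = 50 + ifelse(.data$direction == "higher_better", 1, -1) *
               10 * cap[.data$country]) |>
      select("country", "indicator_id", "year", "value")
    obs <- bind_rows(obs, fills)
  }

  # shift a few cells off the reference years to exercise substitution
  # (resolution pulls them back in, flagged with the asterisk)
  shift10 <- obs$indicator_id == 6L & obs$year == 2010L &
    obs$country %in% c("C03", "C24")
  obs$year[shift10] <- 2009L
  shift15 <- obs$indicator_id == 3L & obs$year == 2015L &
    obs$country %in% c("C05", "C31")
  obs$year[shift15] <- 2014L

  obs <- obs |> arrange(.data$country, .data$indicator_id, .data$year)
  structure(
    list(observations = obs, countries = sim$truth$country,
         expected_excluded = micro, truth = sim$truth),
    class = "h2020_fixture"
  )
}
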
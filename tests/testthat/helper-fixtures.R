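# Shared helpers: small registries and panels built in code.

# Write a registry JSON from plain lists and load it through the public API.
local_registry <- function(indicators, targets, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".json", .local_envir = env)
  jsonlite::write_json(list(indicators = unname(indicators),
                            targets = unname(targets)),
                       path, auto_unbox = TRUE)
  load_registry(path)
}

ind_def <- function(id, direction = "higher_better", targets = 1,
                    quantitative = TRUE, years = c(2005, 2010, 2015),
                    name = paste0("ind", id)) {
  list(indicator_id = id, name = name, is_quantitative = quantitative,
       direction = direction, target_ids = I(targets),
       available_reference_years = I(years))
}

tar_def <- function(id, quantitative = TRUE, name = paste0("target", id)) {
  list(target_id = id, name = name, is_quantitative = quantitative)
}

# Two quantitative targets, three indicators (one lower_better), plus a
# qualitative target/indicator pair — the smallest registry exercising
# every structural rule.
tiny_registry <- function(env = parent.frame()) {
  local_registry(
    indicators = list(
      ind_def(1, "higher_better", targets = 1),
      ind_def(2, "lower_better", targets = 1),
      ind_def(3, "higher_better", targets = 2),
      ind_def(4, quantitative = FALSE, targets = 6)
    ),
    targets = list(tar_def(1), tar_def(2), tar_def(6, quantitative = FALSE)),
    env = env
  )
}

# A fully observed panel for `registry` at all three reference years,
# with values drawn deterministically from a seed.
full_panel <- function(registry, n_countries = 6, seed = 1) {
  q <- quantitative_indicators(registry)
  withr::with_seed(seed, {
    grid <- tidyr::crossing(
      country = sprintf("C%02d", seq_len(n_countries)),
      indicator_id = q$indicator_id,
      year = c(2005L, 2010L, 2015L)
    )
    grid$value <- round(stats::runif(nrow(grid), 10, 90), 3)
    grid
  })
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
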
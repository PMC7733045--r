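test_that("fifty countries split into five groups of ten", {
  withr::with_seed(8, {
    dat <- tibble::tibble(country = sprintf("C%02d", 1:50),
                          index = runif(50, 1, 100))
  })
  qs <- assign_quintiles(dat)
  expect_equal(as.integer(table(qs$quintile)), rep(10L, 5))
  expect_equal(qs$rank, 1:50)
  expect_equal(qs$index, sort(dat$index, decreasing = TRUE))

  b <- quintile_boundaries(qs)
  expect_equal(as.character(b$quintile),
               c("high", "upper_middle", "middle", "lower_middle", "low"))
  # boundaries ordered and non-overlapping, high to low
  expect_true(all(diff(b$min_index) < 0))
  expect_true(all(b$min_index <= b$max_index))
  expect_true(all(utils::head(b$min_index, -1) >= utils::tail(b$max_index, -1)))
})

test_that("quintile sizes differ by at most one for any roster size", {
  withr::with_seed(12, {
    for (n in sample(5:137, 30)) {
      dat <- tibble::tibble(country = sprintf("C%03d", seq_len(n)),
                            index = runif(n, 1, 100))
      qs <- assign_quintiles(dat)
      sizes <- as.integer(table(qs$quintile))
      expect_equal(sum(sizes), n)
      expect_lte(diff(range(sizes)), 1L)
      # larger groups come first
      expect_true(all(diff(sizes) <= 0))
      # order preservation: min of a higher quintile >= max of the next
      b <- quintile_boundaries(qs)
      expect_true(all(utils::head(b$min_index, -1) >=
                        utils::tail(b$max_index, -1)))
    }
  })
  expect_error_class(
    assign_quintiles(tibble::tibble(country = letters[1:4], index = 1:4)),
    "h2020_validation_error"
  )
})

test_that("assignments ignore input row order and break ties by country code", {
  withr::with_seed(31, {
    dat <- tibble::tibble(country = sprintf("C%02d", 1:20),
                          index = round(runif(20, 1, 100), 1))
  })
  qs1 <- assign_quintiles(dat)
  qs2 <- assign_quintiles(dat[sample(20), ])
  expect_equal(as.data.frame(qs1), as.data.frame(qs2))

  # two countries tied exactly at a group boundary: code order decides
  tie <- tibble::tibble(
    country = c("AAA", "ZZZ", "MMM", "BBB", "CCC", "DDD", "EEE", "FFF",
                "GGG", "HHH"),
    index = c(90, 80, 80, 70, 60, 50, 40, 30, 20, 10)
  )
  qt <- assign_quintiles(tie)
  expect_equal(qt$country[qt$rank == 2], "MMM")   # MMM before ZZZ at 80
  expect_equal(as.character(qt$quintile[qt$country == "MMM"]), "high")
  expect_equal(as.character(qt$quintile[qt$country == "ZZZ"]), "upper_middle")
})

test_that("relative change is signed so that positive always means improvement", {
  # mortality-like indicator falling from 10 to 8: improvement
  expect_equal(relative_change(10, 8, "lower_better"), 0.2)
  expect_equal(relative_change(7.5, 7.5, "higher_better"), 0)
  expect_equal(relative_change(50, 40, "higher_better"), -0.2)
  expect_equal(relative_change(c(10, 50), c(8, 40),
                               c("lower_better", "higher_better")),
               c(0.2, -0.2))
  # negative baselines: |baseline| keeps the magnitude interpretable
  expect_equal(relative_change(-10, -8, "higher_better"), 0.2)
  expect_warning(out <- relative_change(0, 5, "higher_better"), "zero")
  expect_true(is.na(out))
  expect_error_class(relative_change(1, 2, "upwards"),
                     "h2020_validation_error")
})

test_that("trend cells use the right baseline and skip 2015-only indicators", {
  reg <- default_registry()
  fx <- make_fixture_roster(reg)
  resolved <- resolve_reference_years(fx$observations)
  rep <- apply_country_filter(resolved, reg)
  res <- compute_index_table(resolved, reg)
  ov15 <- dplyr::filter(res$overall_indices, reference_year == 2015,
                        !unscorable)
  qs <- assign_quintiles(dplyr::select(ov15, country, index))
  tr <- trend_table(resolved, reg, qs)

  expect_s3_class(tr, "h2020_trends")
  # 2015-only indicators produce no cells at all
  expect_false(any(tr$indicator_id %in% c(2L, 14L)))
  # 2010-onward indicators are baselined at 2010, the rest at 2005
  expect_true(all(tr$baseline_year[tr$indicator_id %in% c(4L, 12L)] == 2010L))
  expect_true(all(tr$baseline_year[!tr$indicator_id %in% c(4L, 12L)] == 2005L))
  # full grid: one row per usable indicator x quintile
  expect_equal(nrow(tr), 14 * 5)
  expect_true(all(tr$n_countries >= 0))
  expect_true(all(!is.na(tr$avg_relative_change[tr$n_countries > 0])))
})

test_that("each trend cell is an average of its members and keeps their sign", {
  reg <- local_registry(
    indicators = list(ind_def(1, "lower_better", targets = 1)),
    targets = list(tar_def(1))
  )
  # ten countries, mortality halves everywhere -> every change is +; the
  # cell must equal the exact per-quintile mean
  base_vals <- seq(10, 100, by = 10)
  tbl <- tibble::tibble(
    country = rep(sprintf("C%02d", 1:10), 2),
    indicator_id = 1L,
    reference_year = rep(c(2005L, 2015L), each = 10),
    value = c(base_vals, base_vals * c(0.5, 0.6, 0.7, 0.8, 0.9,
                                       0.5, 0.6, 0.7, 0.8, 0.9))
  )
  qs <- assign_quintiles(tibble::tibble(country = sprintf("C%02d", 1:10),
                                        index = 100 - 1:10))
  tr <- trend_table(tbl, reg, qs)
  changes <- c(0.5, 0.4, 0.3, 0.2, 0.1, 0.5, 0.4, 0.3, 0.2, 0.1)
  for (q in levels(qs$quintile)) {
    members <- qs$country[qs$quintile == q]
    expected <- mean(changes[match(members, sprintf("C%02d", 1:10))])
    got <- tr$avg_relative_change[tr$quintile == q]
    expect_equal(got, expected, tolerance = 1e-12)
    expect_gte(got, min(changes))
    expect_lte(got, max(changes))
    expect_gt(got, 0)      # all members improved, so the cell is positive
  }
})

test_that("countries missing an endpoint drop out of that cell only", {
  reg <- local_registry(
    indicators = list(ind_def(1, "higher_better", targets = 1)),
    targets = list(tar_def(1))
  )
  tbl <- tibble::tibble(
    country = c("A", "A", "B", "C", "C", "D", "D", "E", "E"),
    indicator_id = 1L,
    reference_year = c(2005L, 2015L, 2015L, 2005L, 2015L,
                       2005L, 2015L, 2005L, 2015L),
    value = c(10, 12, 99, 10, 11, 10, 9, 10, 10)
  )
  qs <- assign_quintiles(tibble::tibble(country = c("A", "B", "C", "D", "E"),
                                        index = c(90, 70, 50, 30, 10)))
  tr <- trend_table(tbl, reg, qs)
  # B has no 2005 baseline: its (high-quintile-neighbour) cell counts it out
  expect_equal(sum(tr$n_countries), 4L)
  expect_equal(tr$n_countries[tr$quintile == "upper_middle"], 0L)
  expect_true(is.na(tr$avg_relative_change[tr$quintile == "upper_middle"]))
})
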
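test_that("geometric_mean matches closed forms and refuses bad input", {
  expect_equal(geometric_mean(c(4, 9)), 6)
  expect_equal(geometric_mean(5.3), 5.3)
  # brute-force product oracle
  expect_equal(geometric_mean(c(25, 100, 1)), prod(c(25, 100, 1))^(1 / 3),
               tolerance = 1e-12)
  expect_equal(geometric_mean(c(17, 100, 32, 1, 3)),
               prod(c(17, 100, 32, 1, 3))^(1 / 5), tolerance = 1e-12)
  expect_error_class(geometric_mean(numeric(0)), "h2020_validation_error")
  expect_error_class(geometric_mean(c(3, 0)), "h2020_validation_error")
  expect_error_class(geometric_mean(c(3, -1)), "h2020_validation_error")
})

test_that("geometric mean sits between the harmonic and arithmetic means and scales as c^(1/n)", {
  withr::with_seed(5, {
    for (i in 1:100) {
      n <- sample(2:10, 1)
      x <- runif(n, 0.01, 100)
      gm <- geometric_mean(x)
      expect_gte(gm, min(x) - 1e-12)
      expect_lte(gm, max(x) + 1e-12)
      expect_lte(gm, mean(x) + 1e-12)
      expect_gte(gm, 1 / mean(1 / x) - 1e-12)
      # log-mean implementation vs direct product
      expect_equal(gm, prod(x)^(1 / n), tolerance = 1e-9)
      # partial substitutability: scaling one component by c scales the
      # mean by c^(1/n)
      c_ <- runif(1, 1, 10)
      y <- x
      y[1] <- c_ * y[1]
      expect_equal(geometric_mean(y), gm * c_^(1 / n), tolerance = 1e-9)
    }
  })
})

test_that("target indices are geometric means of whatever indicators are available", {
  reg <- tiny_registry()
  idx <- tibble::tibble(
    country = c("A", "A", "A", "B", "B"),
    indicator_id = c(1L, 2L, 3L, 1L, 3L),
    reference_year = 2015L,
    index = c(4, 9, 50, 25, 60)
  )
  tgt <- target_indices(idx, reg)
  cell <- function(ctry, t) tgt[tgt$country == ctry & tgt$target_id == t, ]
  expect_equal(cell("A", 1)$index, 6)               # GM(4, 9)
  expect_equal(cell("A", 1)$n_indicators_used, 2L)
  expect_equal(cell("A", 2)$index, 50)
  # B misses indicator 2: target 1 scored on the remainder
  expect_equal(cell("B", 1)$index, 25)
  expect_equal(cell("B", 1)$n_indicators_used, 1L)
  expect_false(cell("B", 1)$excluded)
})

test_that("a target with no available indicator is excluded, not invented", {
  reg <- tiny_registry()
  idx <- tibble::tibble(country = "A", indicator_id = 1L,
                        reference_year = 2015L, index = 80)
  tgt <- target_indices(idx, reg)
  t2 <- tgt[tgt$target_id == 2, ]
  expect_true(t2$excluded)
  expect_true(is.na(t2$index))
  expect_equal(t2$n_indicators_used, 0L)
})

test_that("dropping an indicator sitting exactly at the target mean leaves the target unchanged", {
  reg <- tiny_registry()
  base <- tibble::tibble(
    country = "A", indicator_id = c(1L, 2L), reference_year = 2015L,
    index = c(4, 9)
  )
  gm <- geometric_mean(c(4, 9))
  with_extra <- local_registry(
    indicators = list(ind_def(1), ind_def(2, "lower_better"),
                      ind_def(3, targets = 1)),
    targets = list(tar_def(1))
  )
  extra <- dplyr::bind_rows(base, tibble::tibble(
    country = "A", indicator_id = 3L, reference_year = 2015L, index = gm
  ))
  t_with <- target_indices(extra, with_extra)
  t_without <- target_indices(base, with_extra)
  expect_equal(t_with$index[t_with$target_id == 1],
               t_without$index[t_without$target_id == 1],
               tolerance = 1e-9)
})

test_that("the overall index is the geometric mean of surviving targets", {
  tgt <- tibble::tibble(
    country = "A", reference_year = 2015L, target_id = 1:5,
    index = c(17, 100, 32, NA, NA),
    n_indicators_used = c(2L, 1L, 2L, 0L, 0L),
    excluded = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  ov <- overall_indices(tgt)
  expect_equal(ov$n_targets_used, 3L)       # scored on 3 of 5 targets
  expect_equal(ov$index, prod(c(17, 100, 32))^(1 / 3), tolerance = 1e-9)
  expect_false(ov$unscorable)

  equal50 <- dplyr::mutate(tgt, index = 50, excluded = FALSE,
                           n_indicators_used = 1L)
  expect_equal(overall_indices(equal50)$index, 50)

  none <- dplyr::mutate(tgt, index = NA_real_, excluded = TRUE)
  ov0 <- overall_indices(none)
  expect_true(ov0$unscorable)
  expect_true(is.na(ov0$index))
})

test_that("raising any indicator index never lowers target or overall indices", {
  reg <- tiny_registry()
  withr::with_seed(21, {
    for (i in 1:100) {
      idx <- tibble::tibble(
        country = "A",
        indicator_id = c(1L, 2L, 3L),
        reference_year = 2015L,
        index = runif(3, 1, 100)
      )
      j <- sample(1:3, 1)
      bump <- idx
      bump$index[j] <- min(100, bump$index[j] + runif(1, 0, 30))
      t0 <- target_indices(idx, reg)
      t1 <- target_indices(bump, reg)
      ok <- is.na(t0$index) | t1$index >= t0$index - 1e-12
      expect_true(all(ok, na.rm = TRUE))
      o0 <- overall_indices(t0)$index
      o1 <- overall_indices(t1)$index
      expect_gte(o1, o0 - 1e-12)
    }
  })
})

test_that("with single-target indicators the overall index ignores target labels", {
  # every indicator on exactly one target; permuting which target an
  # indicator belongs to must not move the overall index when all targets
  # remain represented
  perm_registry <- function(assignment) {
    local_registry(
      indicators = purrr::imap(assignment,
                               ~ ind_def(as.integer(.y), targets = .x)),
      targets = list(tar_def(1), tar_def(2), tar_def(3))
    )
  }
  idx <- tibble::tibble(country = "A", indicator_id = 1:3,
                        reference_year = 2015L, index = c(10, 40, 90))
  r1 <- perm_registry(list(`1` = 1, `2` = 2, `3` = 3))
  r2 <- perm_registry(list(`1` = 2, `2` = 3, `3` = 1))
  o1 <- overall_indices(target_indices(idx, r1))$index
  o2 <- overall_indices(target_indices(idx, r2))$index
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("compute_index_table is deterministic and isolates unscorable countries", {
  reg <- tiny_registry()
  panel <- full_panel(reg, n_countries = 8, seed = 4)
  res <- compute_index_table(panel, reg)
  # permuting input rows changes nothing
  shuffled <- panel[withr::with_seed(1, sample(nrow(panel))), ]
  res2 <- compute_index_table(shuffled, reg)
  expect_equal(res2$overall_indices, res$overall_indices)
  expect_equal(res2$indicator_indices, res$indicator_indices)

  # one overall index per included country per year
  expect_equal(nrow(res$overall_indices), 8 * 3)
  expect_false(any(res$overall_indices$unscorable))
  # every overall index reproducible from its stored target indices
  check <- res$target_indices |>
    dplyr::filter(!excluded) |>
    dplyr::group_by(country, reference_year) |>
    dplyr::summarise(recomputed = exp(mean(log(index))), .groups = "drop") |>
    dplyr::inner_join(res$overall_indices, by = c("country", "reference_year"))
  expect_equal(check$recomputed, check$index, tolerance = 1e-9)
})

test_that("frozen goalposts can replace recomputed ones", {
  reg <- tiny_registry()
  panel <- full_panel(reg, n_countries = 6, seed = 9)
  res <- compute_index_table(panel, reg)
  res_frozen <- compute_index_table(panel, reg, goalposts = res$goalposts)
  expect_equal(res_frozen$overall_indices, res$overall_indices)
})
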
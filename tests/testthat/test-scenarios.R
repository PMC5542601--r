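fake_result <- function(pattern, tow, initial, winch, end) {
  pct <- function(v) round(100 * (v - initial) / initial)
  list(summary = tibble::tibble(
    pattern = pattern, tow_minutes = tow, initial = initial,
    at_winch_start = winch, at_winch_start_pct = pct(winch),
    at_end = end, at_end_pct = pct(end), n_fish = NA_integer_, t_end_s = NA_real_
  ))
}

test_that("summary cells render counts with signed percentage changes", {
  s <- summarize_scenarios(list(
    fake_result("square", 15, 10000, 11000, 12000),
    fake_result("rectangle", 0, 10000, 10000, 8600)
  ))
  expect_equal(s$at_end_cell[1], "12000 (20%)")
  expect_equal(s$at_winch_start_cell[1], "11000 (10%)")
  expect_equal(s$at_end_cell[2], "8600 (-14%)")
  # percentages recomputable from the raw counts
  expect_equal(s$at_end_pct, round(100 * (s$at_end - s$initial) / s$initial))
  expect_error(summarize_scenarios(list()), "no scenario")
})

test_that("cross-pattern and towing-gain comparisons are plain arithmetic", {
  res <- list(
    fake_result("square", 0, 10000, 10000, 9000),
    fake_result("square", 15, 10000, 11000, 12000),
    fake_result("rectangle", 0, 6400, 6400, 5000),
    fake_result("rectangle", 15, 6400, 6600, 10000)
  )
  cmp <- compare_patterns(res)
  expect_equal(cmp$excess_pct[cmp$tow_minutes == 0], 100 * (9000 - 5000) / 5000)
  expect_equal(cmp$excess_pct[cmp$tow_minutes == 15], 20)
  tg <- towing_gain(res)
  expect_true(all(is.na(tg$gain_pct[tg$tow_minutes == 0])))
  expect_equal(tg$gain_pct[tg$pattern == "square" & tg$tow_minutes == 15],
               100 * (12000 - 9000) / 9000)
})

test_that("scenario configs reject unknown layout patterns", {
  expect_error(run_scenario(scenario_config(pattern = "pentagon")), "arg")
})

test_that("a miniature scenario is reproducible end to end", {
  # 200 m ropes (square of side 100 m) keep the full chain fast
  cfg <- scenario_config("square", tow_minutes = 1, rope_length_each = 200,
                         seed = 7,
                         dynamics = dynamics_params(settle_time = 30,
                                                    depth = 10, n_log = 41L))
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$indicators, b$indicators)
  expect_s3_class(glance(a), "tbl_df")
  expect_equal(nrow(glance(a)), 1L)
  expect_true(all(c("t_s", "area_m2", "entry_width_m", "fish_encircled") %in%
                  names(tidy(a))))
})

test_that("plot builders return ggplot objects with the indicator mappings", {
  res <- list(
    structure(list(summary = fake_result("square", 15, 10, 10, 10)$summary,
                   indicators = tibble::tibble(t_s = 0:5, area_m2 = 6:1 * 10,
                                               entry_width_m = 1:6,
                                               fish_encircled = rep(5L, 6))),
              class = "seine_scenario")
  )
  for (w in c("count", "area", "width")) {
    p <- plot_indicators(res, w)
    expect_s3_class(p, "ggplot")
  }
  expect_s3_class(autoplot(make_layout("triangle")), "ggplot")
  expect_s3_class(autoplot(res[[1]]), "ggplot")
})
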
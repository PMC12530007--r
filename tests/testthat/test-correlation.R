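test_that("a perfect line is recovered exactly", {
  res <- daily_regression(c_g = 1:10, c_m = 2 * (1:10) + 1)
  expect_equal(res$n_included, 10L)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$intercept, 1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_true(res$passed_filters)
  expect_true(res$reported)
})

test_that("OLS agrees with the closed-form two-pass computation", {
  set.seed(13)
  for (i in 1:10) {
    x <- runif(40, 1, 10)
    y <- 0.5 * x + rnorm(40)
    res <- daily_regression(x, y)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    r2 <- sxy^2 / (sxx * sum((y - mean(y))^2))
    expect_equal(res$slope, slope, tolerance = 1e-12)
    expect_equal(res$intercept, intercept, tolerance = 1e-12)
    expect_equal(res$r_squared, r2, tolerance = 1e-12)
  }
})

test_that("inclusion filters reject degenerate snapshots", {
  # nobody with gonadal thiamine
  expect_false(daily_regression(rep(0, 50), runif(50, 1, 5))$passed_filters)
  # too little variation among included females (0.4 < 0.5 nmol/g range)
  cg <- seq(1, 1.4, length.out = 50)
  expect_false(daily_regression(cg, runif(50))$passed_filters)
  # spread just above the threshold passes
  cg2 <- seq(1, 1.6, length.out = 50)
  expect_true(daily_regression(cg2, 2 * cg2 + rnorm(50, 0, 0.01))$passed_filters)
  # included fraction must exceed 2/3 of the population
  cg3 <- c(rep(0, 40), seq(1, 5, length.out = 60))
  expect_false(daily_regression(cg3, runif(100))$passed_filters)
  cg4 <- c(rep(0, 30), seq(1, 5, length.out = 70))
  expect_true(daily_regression(cg4, runif(70 + 30))$passed_filters)
  # fewer than three included females: no fit
  expect_false(daily_regression(c(0, 0, 1, 2), c(1, 1, 1, 2))$passed_filters)
  # standard-deviation reading of the variation filter
  cg5 <- c(rep(1, 49), 1.8)  # range 0.8 but sd ~ 0.11
  expect_true(daily_regression(cg5, runif(50))$passed_filters)
  expect_false(daily_regression(cg5, runif(50),
                                variation_filter = "sd")$passed_filters)
})

test_that("the reporting rule keys on R-squared", {
  set.seed(21)
  x <- runif(100, 1, 10)
  weak <- daily_regression(x, 0.05 * x + rnorm(100, 0, 2))
  expect_true(weak$passed_filters)
  expect_false(weak$reported)
  strong <- daily_regression(x, x + rnorm(100, 0, 0.5))
  expect_true(strong$reported)
})

test_that("slope trajectories order days and mark constant populations", {
  p <- thiamalloc_params(N = 10L, i_max = 1L, reproductive_mode = "semelparous",
                         c_b_halfwidth = 0, grid = coarse_grid())
  pol <- optimize_policy(p)
  sim <- simulate(pol, seed = 1)
  tr <- slope_trajectory(sim)
  expect_s3_class(tr, "slope_trajectory")
  expect_equal(nrow(tr), p$days_per_year)
  expect_true(all(diff(tr$day) == 1))
  # identical females: no day can pass the variation filter
  expect_false(any(tr$passed_filters))
  expect_false(any(tr$reported))
})

test_that("Spearman correlations handle monotone, reversed and tied data", {
  tab <- function(x, y, sys = "limited", st = "spawning")
    data.frame(system = sys, stage = st,
               muscle_total_thiamine_nmol_g = y,
               gonad_total_thiamine_nmol_g = x)
  up <- spearman_by_group(tab(1:8, (1:8)^2), by = "system")
  expect_equal(up$rho, 1)
  down <- spearman_by_group(tab(1:8, 8:1), by = "system")
  expect_equal(down$rho, -1)
  # six pairs with one tie: frozen midrank computation
  tied <- spearman_by_group(tab(c(1, 2, 2, 3, 4, 5), c(2, 1, 3, 5, 4, 6)),
                            by = "system")
  expect_equal(tied$rho, 0.840668, tolerance = 1e-6)
  expect_false(tied$flagged)
  expect_lt(tied$p_value, 0.05)
  # groups smaller than three are flagged without a test
  small <- spearman_by_group(tab(1:2, 2:1), by = "system")
  expect_true(small$flagged)
  expect_true(is.na(small$p_value))
  # grouping by system and stage splits the table
  two <- rbind(tab(1:5, 1:5, st = "upstream"), tab(1:5, 5:1, st = "spawning"))
  two$stage <- factor(two$stage, levels = c("upstream", "spawning"))
  res <- spearman_by_group(two)
  expect_equal(nrow(res), 2)
  expect_equal(sort(res$rho), c(-1, 1))
})

test_that("terminal-window summaries count signs and trend", {
  p <- thiamalloc_params(N = 5L, i_max = 1L, reproductive_mode = "semelparous",
                         grid = coarse_grid())
  pol <- optimize_policy(p)
  sim <- simulate(pol, seed = 1)
  tr <- slope_trajectory(sim)
  # overwrite with a synthetic reported pattern to check the bookkeeping
  tr$reported <- tr$day >= 350
  tr$passed_filters <- tr$reported
  tr$slope <- ifelse(tr$day >= 358, 1 + (tr$day - 358) * 0.1, -0.5)
  sm <- terminal_window_summary(tr, window = 30, year = 1)
  expect_equal(sm$n_reported, 16)
  expect_equal(sm$n_positive, 8)
  expect_equal(sm$n_negative, 8)
  expect_equal(sm$majority_sign, 0)
  expect_true(sm$signal)
  expect_gt(sm$trend_tau, 0)
  sm2 <- terminal_window_summary(tr, window = 30, year = 1,
                                 signal_min_days = 20)
  expect_false(sm2$signal)
})
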
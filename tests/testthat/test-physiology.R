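p_def <- thiamalloc_params()

test_that("fitness components reproduce their closed forms", {
  # recruitment: (c_g/c_x)^v
  expect_equal(recruitment_probability(30, p_def), 1)
  expect_equal(recruitment_probability(0, p_def), 0)
  p_v <- thiamalloc_params(v = 0.025)
  expect_equal(recruitment_probability(15, p_v), 0.5^0.025, tolerance = 1e-12)
  expect_equal(0.5^0.025, 0.98283, tolerance = 1e-5)

  # daily survival spans [p0, px]
  expect_equal(daily_survival(0, p_def), p_def$p0)
  expect_equal(daily_survival(30, p_def), p_def$px)
  expect_equal(daily_survival(0, p_def), 0.981253, tolerance = 1e-6)
  expect_equal(daily_survival(30, p_def), 0.996209, tolerance = 1e-6)
  # a large exponent pushes interior survival towards the floor
  p_u <- thiamalloc_params(u = 500)
  expect_equal(daily_survival(15, p_u), p_u$p0, tolerance = 1e-6)

  # migration survival
  expect_equal(migration_survival(30, p_def), 1)
  expect_equal(migration_survival(0, p_def), 0)
  expect_equal(migration_survival(15, p_def), 0.5^0.2, tolerance = 1e-12)
  expect_equal(0.5^0.2, 0.87055, tolerance = 1e-5)

  expect_error(recruitment_probability(-1, p_def), "non-negative")
  expect_error(daily_survival(-0.1, p_def), "non-negative")
})

test_that("sigmoid loss rate matches its closed form and limits", {
  # midpoint: exponent 0 gives k_x (b+1) / (2b)
  expect_equal(loss_rate_sigmoid(15, 0.5, 30, 200), 0.5 * 201 / 400,
               tolerance = 1e-12)
  expect_equal(loss_rate_sigmoid(30, 0.5, 30, 200), 0.49754, tolerance = 1e-5)
  # at c = 0 the closed form is k_x (b + 1) / (b^2 + 1)
  expect_equal(loss_rate_sigmoid(0, 0.5, 30, 200), 0.5 * 201 / 40001,
               tolerance = 1e-12)
  expect_error(loss_rate_sigmoid(15, 0.5, 30, 1), "exceed 1")
  # approaches a step at c_x / 2 as b grows
  lo200 <- loss_rate_sigmoid(12, 0.5, 30, 200) / 0.5
  lo1e6 <- loss_rate_sigmoid(12, 0.5, 30, 1e6) / 0.5
  expect_lt(lo1e6, lo200)
  expect_lt(lo1e6, 0.1)
  hi1e6 <- loss_rate_sigmoid(18, 0.5, 30, 1e6) / 0.5
  expect_gt(hi1e6, loss_rate_sigmoid(18, 0.5, 30, 200) / 0.5)
  expect_gt(hi1e6, 0.9)
  expect_lt(loss_rate_sigmoid(5, 0.5, 30, 1e6) / 0.5, 1e-3)
  expect_gt(loss_rate_sigmoid(25, 0.5, 30, 1e6) / 0.5, 0.999)
})

test_that("reabsorption loss is continuous at c_t and hits its anchors", {
  k_lo <- loss_rate_reabsorption(6 - 1e-9, 0.5, 30, 3, 6)
  k_hi <- loss_rate_reabsorption(6, 0.5, 30, 3, 6)
  expect_equal(k_lo, k_hi, tolerance = 1e-9)
  expect_equal(k_hi, 0.1, tolerance = 1e-12)
  expect_equal(loss_rate_reabsorption(0, 0.5, 30, 3, 6), 0)
  expect_equal(loss_rate_reabsorption(30, 0.5, 30, 3, 6), 0.5)
  # b_c = 1 collapses to the pure linear law
  c <- seq(0, 30, by = 0.5)
  expect_equal(loss_rate_reabsorption(c, 0.35, 30, 1, 10),
               loss_rate_linear(c, 0.35, 30), tolerance = 1e-12)
})

test_that("all response functions are monotone in concentration", {
  set.seed(101)
  c <- seq(0, 30, length.out = 301)
  for (rep in 1:20) {
    p <- thiamalloc_params(u = runif(1, 0.01, 3), v = runif(1, 0.01, 3),
                           l = runif(1, 0.05, 2),
                           excretion_model = sample(c("sigmoid",
                                                      "reabsorption_passive",
                                                      "linear"), 1),
                           b = runif(1, 1.5, 500),
                           b_c = sample(2:6, 1), c_t = runif(1, 2, 25))
    expect_true(all(diff(recruitment_probability(c, p)) >= 0))
    expect_true(all(diff(daily_survival(c, p)) >= 0))
    expect_true(all(diff(migration_survival(c, p)) >= 0))
    expect_true(all(diff(loss_rate(c, 0.5, p)) >= -1e-12))
  }
})

test_that("a daily update balances amounts (hand-computed oracle)", {
  p <- thiamalloc_params(excretion_model = "sigmoid", b = 200)
  upd <- daily_update(c_g = 5, c_m = 10, alpha = 0.5, c_b = 2,
                      w_g = 100, w_m = 1000, w_b = 50, params = p)
  # independent balance: amount + inflow - loss, divided by (constant) mass
  k_g <- loss_rate_sigmoid(5, 0.5, 30, 200)
  k_m <- loss_rate_sigmoid(10, 0.35, 30, 200)
  expect_equal(upd$c_g, (5 * 100 + 0.5 * 2 * 50 - k_g * 100) / 100,
               tolerance = 1e-12)
  expect_equal(upd$c_m, (10 * 1000 + 0.9 * 0.5 * 2 * 50 - k_m * 1000) / 1000,
               tolerance = 1e-12)
})

test_that("conservation: with excretion disabled the allocated inflow is exact", {
  p0 <- thiamalloc_params(k_x_g = 0, k_x_m = 0)
  set.seed(7)
  for (i in 1:50) {
    # draws bounded away from the ceiling so no inflow is clamp-discarded
    cg <- runif(1, 0, 10); cm <- runif(1, 0, 10)
    a <- runif(1); cb <- runif(1, 0, 4)
    w_g <- runif(1, 100, 500); w_m <- runif(1, 500, 5000)
    w_b <- 0.05 * w_m
    upd <- daily_update(cg, cm, a, cb, w_g, w_m, w_b, params = p0)
    gained <- (upd$c_g * w_g + upd$c_m * w_m) - (cg * w_g + cm * w_m)
    expect_equal(gained, cb * w_b * (a * p0$q_m + (1 - a)), tolerance = 1e-9)
  }
})

test_that("updates clamp at the ceiling and floor at zero content", {
  p <- thiamalloc_params()
  # no inflow to gonads and nothing stored: stays at zero
  upd <- daily_update(0, 15, alpha = 1, c_b = 4, w_g = 10, w_m = 1000,
                      w_b = 50, params = p)
  expect_equal(upd$c_g, 0)
  # huge inflow into a tiny gonad is clamped at c_x and counted
  upd <- daily_update(29, 15, alpha = 0, c_b = 6, w_g = 1, w_m = 1000,
                      w_b = 50, params = p)
  expect_equal(upd$c_g, p$c_x)
  expect_equal(attr(upd, "n_clamped_g"), 1L)
  # loss cannot drive an amount negative: sigmoid loss at c_g = 0.001
  # (~0.0025 nmol/g/d) exceeds the content, so the amount floors at zero
  upd <- daily_update(0.001, 15, 1, 0, w_g = 1, w_m = 1000, w_b = 50,
                      params = p)
  expect_equal(upd$c_g, 0)
  expect_error(daily_update(5, 5, alpha = 1.2, c_b = 1, w_g = 1, w_m = 1,
                            w_b = 1, params = p), "alpha")
})

test_that("expected recruits combine recruitment, egg mass and survival", {
  p <- thiamalloc_params()
  expect_equal(expected_recruits(0, 50, 0.5, p), 0)
  expect_equal(expected_recruits(30, 50, 0, p), 0)
  expect_equal(expected_recruits(30, 50, 0.5, p), 25)  # r = 1 at the ceiling
  p_raw <- thiamalloc_params(recruits_use_raw_concentration = TRUE)
  expect_equal(expected_recruits(10, 50, 1, p_raw), 500)
})
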
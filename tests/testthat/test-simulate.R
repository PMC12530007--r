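# A hand-built policy object (constant alpha surface) for exercising the
# simulator independently of the optimizer.
fixed_alpha_policy <- function(params, alpha_value,
                               trajectory = build_trajectory(params)) {
  years <- if (params$reproductive_mode == "semelparous") 1L else params$i_max
  cg <- seq(0, params$c_x, by = params$grid$c_step)
  arr <- array(alpha_value, dim = c(length(cg), length(cg),
                                    params$days_per_year, years))
  structure(list(alpha = arr, value = array(0, dim = dim(arr)),
                 cg_grid = cg, cm_grid = cg,
                 alpha_levels = seq(0, 1, by = params$grid$alpha_step),
                 params = params,
                 trajectory = tissue_trajectory(
                   trajectory$w_m[, seq_len(years), drop = FALSE],
                   trajectory$w_g[, seq_len(years), drop = FALSE],
                   trajectory$w_b[, seq_len(years), drop = FALSE],
                   d_s = params$d_s)),
            class = "allocation_policy")
}

test_that("daily input draws respect range, mean and starvation", {
  p <- thiamalloc_params(c_b_mean = 6, c_b_halfwidth = 2)
  set.seed(99)
  x <- draw_daily_input(1e5, p)
  expect_true(all(x >= 4 & x <= 8))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 6), 3 * se)
  # degenerate distribution
  p0 <- thiamalloc_params(c_b_halfwidth = 0, c_b_mean = 3)
  expect_equal(draw_daily_input(10, p0), rep(3, 10))
  # zero input inside the starvation window
  ps <- thiamalloc_params(starvation_days = 60L)
  expect_equal(draw_daily_input(5, ps, day = ps$d_s - 10), rep(0, 5))
  expect_true(all(draw_daily_input(5, ps, day = ps$d_s - 61) > 0))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  p <- thiamalloc_params(N = 20L, i_max = 2L, grid = coarse_grid())
  pol <- fixed_alpha_policy(p, 0.7)
  s1 <- simulate(pol, seed = 5)
  s2 <- simulate(pol, seed = 5)
  expect_identical(s1[c("c_g", "c_m", "alpha", "c_b")],
                   s2[c("c_g", "c_m", "alpha", "c_b")])
  s3 <- simulate(pol, seed = 6)
  expect_false(identical(s1$c_b, s3$c_b))
})

test_that("with deterministic input all females are identical", {
  p <- thiamalloc_params(N = 30L, i_max = 2L, c_b_halfwidth = 0,
                         grid = coarse_grid())
  pol <- fixed_alpha_policy(p, 0.5)
  sim <- simulate(pol, seed = 1)
  v <- apply(sim$c_m, 1, stats::sd)
  expect_true(all(v == 0))
  expect_true(all(apply(sim$c_g, 1, stats::sd) == 0))
})

test_that("full muscle allocation leaves gonads empty until spawning", {
  p <- thiamalloc_params(N = 2L, i_max = 1L, reproductive_mode = "semelparous",
                         c_b_halfwidth = 0, grid = coarse_grid())
  pol <- fixed_alpha_policy(p, 1)
  sim <- simulate(pol, seed = 1)
  expect_true(all(sim$c_g == 0))
})

test_that("spawning resets gonads and logs spawn outputs", {
  p <- thiamalloc_params(N = 10L, i_max = 2L, grid = coarse_grid())
  pol <- fixed_alpha_policy(p, 0.3)
  sim <- simulate(pol, seed = 2)
  expect_equal(nrow(sim$spawns), 20)
  # gonad concentration on the day after spawning reflects the reset
  t_after <- p$days_per_year + 1
  expect_true(all(sim$c_g[t_after, ] <= p$c_x))
  sp1 <- sim$spawns[sim$spawns$year == 1, ]
  expect_equal(sp1$c_g, sim$c_g[p$d_s, ])
  expect_equal(sp1$recruit_prob, recruitment_probability(sp1$c_g, p))
  expect_true(all(sim$c_g >= 0 & sim$c_g <= p$c_x))
  expect_true(all(sim$c_m >= 0 & sim$c_m <= p$c_x))
})

test_that("low thiamine input keeps population muscle levels below high input", {
  g <- coarse_grid()
  pol_lo <- optimize_policy(scenario_preset("baseline_low_input", N = 100L,
                                            grid = g))
  pol_hi <- optimize_policy(scenario_preset("baseline_high_input", N = 100L,
                                            grid = g))
  s_lo <- simulate(pol_lo, seed = 3, years = 1)
  s_hi <- simulate(pol_hi, seed = 3, years = 1)
  m_lo <- rowMeans(s_lo$c_m[150:364, ])
  m_hi <- rowMeans(s_hi$c_m[150:364, ])
  expect_true(all(m_lo < m_hi))
})

test_that("long-format export matches the matrices", {
  p <- thiamalloc_params(N = 3L, i_max = 2L, days_per_year = 8L, d_s = 8L,
                         growth = growth_params(gonad_buildup_days = 4L),
                         grid = coarse_grid())
  pol <- fixed_alpha_policy(p, 0.5)
  sim <- simulate(pol, seed = 1)
  df <- as.data.frame(sim)
  expect_equal(nrow(df), 3 * 2 * 8)
  expect_equal(df$c_m[df$female == 2 & df$year == 2 & df$day == 3],
               sim$c_m[8 + 3, 2])
})
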
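test_that("daily survival bounds reproduce the annual anchors", {
  b <- derive_daily_survival_bounds(0.001, 0.25, 365)
  # frozen from the closed form p = exp(log(annual)/days)
  expect_equal(unname(b["p0"]), 0.9812527, tolerance = 1e-6)
  expect_equal(unname(b["px"]), 0.9962087, tolerance = 1e-6)
  expect_equal(b[["p0"]]^365, 0.001, tolerance = 1e-12)
  expect_equal(b[["px"]]^365, 0.25, tolerance = 1e-12)

  # symmetry and one-day degenerate cases
  expect_equal(unname(derive_daily_survival_bounds(0.1, 0.1, 50)),
               rep(0.1^(1 / 50), 2))
  expect_equal(unname(derive_daily_survival_bounds(0.25, 0.25, 1)),
               c(0.25, 0.25))
  expect_error(derive_daily_survival_bounds(0, 0.5, 365), "probability")
  expect_error(derive_daily_survival_bounds(0.5, 0.1, 365), "exceed")
})

test_that("reabsorption coefficient makes the loss branches meet at c_t", {
  a <- derive_reabsorption_coefficient(6, 0.5, 30, 3)
  expect_equal(a * 6^3, 0.5 * 6 / 30, tolerance = 1e-12)  # both give 0.1
  expect_equal(a, 4.6296296e-4, tolerance = 1e-7)
  # power branch degenerates to the linear branch when b_c = 1
  expect_equal(derive_reabsorption_coefficient(10, 0.35, 30, 1), 0.35 / 30)
  expect_error(derive_reabsorption_coefficient(40, 0.5, 30, 3), "c_x")
  expect_error(derive_reabsorption_coefficient(-1, 0.5, 30, 3), "positive")
})

test_that("default parameters carry the documented anchors", {
  p <- thiamalloc_params()
  expect_equal(p$c_x, 30)
  expect_equal(p$k_x_g, 0.5)
  expect_equal(p$k_x_m, 0.35)
  expect_equal(p$k_x_m / p$k_x_g, 0.7)
  expect_equal(p$q_m, 0.9)
  expect_equal(p$l, 0.2)
  expect_equal(p$i_max, 15L)
  expect_equal(p$N, 1000L)
  expect_equal(p$c_m_init, 15)
  expect_equal(p$p0^365, 0.001, tolerance = 1e-12)
  expect_equal(p$px^365, 0.25, tolerance = 1e-12)
})

test_that("validation errors name the offending field", {
  expect_error(thiamalloc_params(q_m = 1.5), "q_m")
  expect_error(thiamalloc_params(excretion_model = "sigmoid", b = 1), "`b`")
  expect_error(thiamalloc_params(excretion_model = "reabsorption_passive",
                                 c_t = 40), "c_t")
  expect_error(thiamalloc_params(c_b_mean = 1, c_b_halfwidth = 2),
               "c_b_halfwidth")
  expect_error(thiamalloc_params(d_s = 400), "d_s")
  expect_error(thiamalloc_params(grid = grid_params(c_step = 0.7)), "c_step")
  expect_error(thiamalloc_params(c_m_init = 40), "c_m_init")
  expect_error(thiamalloc_params(growth = growth_params(gonad_peak_fraction = 1.2)),
               "gonad_peak_fraction")
})

test_that("configuration files round-trip through YAML", {
  p <- thiamalloc_params(c_b_mean = 6, excretion_model = "reabsorption_passive",
                         b_c = 6, c_t = 10, seed = 42L,
                         grid = grid_params(c_step = 1))
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  q <- read_params(f)
  for (field in setdiff(names(p), c("growth", "grid")))
    expect_equal(q[[field]], p[[field]], info = field)
  expect_equal(unclass(q$grid), unclass(p$grid))
  expect_equal(unclass(q$growth), unclass(p$growth))

  # unknown keys are rejected with the field named
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(c_x = 30, not_a_field = 1), bad)
  expect_error(read_params(bad), "not_a_field")
  # omitted seed falls back to the documented default
  minimal <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(c_b_mean = 4), minimal)
  expect_equal(read_params(minimal)$seed, formals(thiamalloc_params)$seed)
})

test_that("scenario presets carry their documented exponents and modes", {
  lo <- scenario_preset("baseline_low_input")
  hi <- scenario_preset("baseline_high_input")
  expect_equal(lo$b, 200)
  expect_equal(lo$u, 0.05)
  expect_equal(c(lo$c_b_mean, hi$c_b_mean), c(2, 6))
  rb <- scenario_preset("reabsorption_low_input", b_c = 6, c_t = 10)
  expect_equal(rb$excretion_model, "reabsorption_passive")
  expect_equal(c(rb$u, rb$v), c(0.025, 0.025))
  expect_equal(c(rb$b_c, rb$c_t), c(6, 10))
  expect_equal(scenario_preset("semelparous_high_input")$reproductive_mode,
               "semelparous")
  expect_equal(scenario_preset("starvation_low_input")$starvation_days, 60L)
})

test_that("update_params re-derives dependent constants", {
  p <- thiamalloc_params()
  q <- update_params(p, annual_survival_min = 0.01, days_per_year = 100L,
                     d_s = 100L,
                     growth = growth_params(gonad_buildup_days = 50L))
  expect_equal(q$p0^100, 0.01, tolerance = 1e-12)
  expect_error(update_params(p, nonsense = 1), "nonsense")
})
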
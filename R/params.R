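#' Model parameters for the thiamine-allocation model
#'
#' Constructs and validates the full parameter set of the allocation model:
#' tissue-concentration ceiling and excretion kinetics, survival and
#' recruitment scalings, the stochastic blood-thiamine input, the life-history
#' calendar, growth and discretization settings. All concentrations are in
#' nmol per gram wet weight and all times in days.
#'
#' Two constants are derived at construction time and stored on the object:
#' the daily survival bounds `p0`, `px` (from the annual anchors, see
#' [derive_daily_survival_bounds()]) and the reabsorption coefficients
#' `a_g`, `a_m` that make the reabsorption-plus-passive-transport loss law
#' continuous at the passive-transport threshold `c_t` (see
#' [derive_reabsorption_coefficient()]).
#'
#' @param c_x Concentration ceiling in tissues, nmol/g.
#' @param k_x_g,k_x_m Maximal mass-specific loss rates for gonads and muscles,
#'   nmol/g/d. `k_x = 0` disables excretion for that tissue (the no-loss
#'   limiting case used in conservation checks).
#' @param q_m Efficiency of enzymatic conversion of free thiamine to TDP on
#'   allocation to muscle, in (0, 1].
#' @param annual_survival_min,annual_survival_max Probability of surviving one
#'   year at muscle concentration 0 and at the ceiling `c_x`; converted to the
#'   daily bounds `p0`, `px`.
#' @param u,v,l Dimensionless exponents scaling concentration-dependent daily
#'   survival, offspring recruitment, and post-spawning migration survival.
#' @param excretion_model One of `"sigmoid"` (active reabsorption at low and
#'   active secretion at high concentration), `"reabsorption_passive"`
#'   (reabsorption power law below `c_t`, passive linear transport above), or
#'   `"linear"` (passive transport only).
#' @param b Sigmoid shape parameter (> 1); larger values approach a step at
#'   `c_x / 2`.
#' @param b_c,c_t Reabsorption power-law exponent and passive-transport
#'   threshold concentration for the `"reabsorption_passive"` model.
#' @param c_b_mean Mean blood thiamine concentration (the input level of a
#'   scenario), nmol/g.
#' @param c_b_halfwidth Half-range of the stochastic daily input, nmol/g.
#' @param beta_shape Length-2 positive shape pair of the beta distribution the
#'   daily input is drawn from (rescaled to
#'   `c_b_mean +/- c_b_halfwidth`). The symmetric default gives a
#'   normal-like unimodal shape.
#' @param days_per_year Days in the yearly cycle.
#' @param d_s Spawning day within the year (eggs are released over one day).
#' @param i_max Maximum number of years (iteroparous horizon).
#' @param reproductive_mode `"iteroparous"` (spawns every year, survives the
#'   post-spawning migration with probability set by `l`) or `"semelparous"`
#'   (dies after the single spawning at the end of year 1).
#' @param starvation_days Length of the zero-input window immediately before
#'   spawning (0 disables; 60 models a two-month pre-spawn fast).
#' @param growth A [growth_params()] object.
#' @param grid A [grid_params()] object.
#' @param N Number of females in forward population simulations.
#' @param seed Default RNG seed recorded in outputs.
#' @param c_g_init,c_m_init Initial gonad and muscle concentrations of
#'   simulated females, nmol/g.
#' @param recruits_use_raw_concentration If `TRUE`, the spawning reward uses
#'   the raw gonadal concentration instead of the recruitment probability
#'   `(c_g/c_x)^v` (which makes `v` inert); default `FALSE`.
#' @param variation_filter How the "variation greater than 0.5 nmol" inclusion
#'   filter of the daily regressions measures spread of the included gonadal
#'   concentrations: `"range"` (default) or `"sd"`.
#' @param apply_mortality If `TRUE`, the forward simulator removes females
#'   stochastically by daily and migration survival; default `FALSE` so that
#'   correlation panels see the full population of trajectories.
#'
#' @return An object of class `"thiamalloc_params"` (a validated list with the
#'   derived constants `p0`, `px`, `a_g`, `a_m` attached).
#' @seealso [scenario_preset()], [read_params()], [optimize_policy()]
#' @examples
#' p <- thiamalloc_params()
#' p$p0^365        # annual survival at c_m = 0
#' p$k_x_m / p$k_x_g
#' @export
thiamalloc_params <- function(c_x = 30,
                              k_x_g = 0.5,
                              k_x_m = 0.35,
                              q_m = 0.9,
                              annual_survival_min = 0.001,
                              annual_survival_max = 0.25,
                              u = 0.05,
                              v = 0.025,
                              l = 0.2,
                              excretion_model = c("sigmoid",
                                                  "reabsorption_passive",
                                                  "linear"),
                              b = 200,
                              b_c = 3,
                              c_t = 6,
                              c_b_mean = 2,
                              c_b_halfwidth = 2,
                              beta_shape = c(4, 4),
                              days_per_year = 365L,
                              d_s = days_per_year,
                              i_max = 15L,
                              reproductive_mode = c("iteroparous",
                                                    "semelparous"),
                              starvation_days = 0L,
                              growth = growth_params(),
                              grid = grid_params(),
                              N = 1000L,
                              seed = 1L,
                              c_g_init = 0,
                              c_m_init = 15,
                              recruits_use_raw_concentration = FALSE,
                              variation_filter = c("range", "sd"),
                              apply_mortality = FALSE) {
  excretion_model <- match.arg(excretion_model)
  reproductive_mode <- match.arg(reproductive_mode)
  variation_filter <- match.arg(variation_filter)

  p <- list(
    c_x = c_x, k_x_g = k_x_g, k_x_m = k_x_m, q_m = q_m,
    annual_survival_min = annual_survival_min,
    annual_survival_max = annual_survival_max,
    u = u, v = v, l = l,
    excretion_model = excretion_model,
    b = b, b_c = b_c, c_t = c_t,
    c_b_mean = c_b_mean, c_b_halfwidth = c_b_halfwidth,
    beta_shape = beta_shape,
    days_per_year = as.integer(days_per_year),
    d_s = as.integer(d_s),
    i_max = as.integer(i_max),
    reproductive_mode = reproductive_mode,
    starvation_days = as.integer(starvation_days),
    growth = growth,
    grid = grid,
    N = as.integer(N),
    seed = as.integer(seed),
    c_g_init = c_g_init, c_m_init = c_m_init,
    recruits_use_raw_concentration = isTRUE(recruits_use_raw_concentration),
    variation_filter = variation_filter,
    apply_mortality = isTRUE(apply_mortality)
  )

  sb <- derive_daily_survival_bounds(annual_survival_min, annual_survival_max,
                                     p$days_per_year)
  p$p0 <- sb[["p0"]]
  p$px <- sb[["px"]]
  if (excretion_model == "reabsorption_passive") {
    p$a_g <- derive_reabsorption_coefficient(c_t, k_x_g, c_x, b_c)
    p$a_m <- derive_reabsorption_coefficient(c_t, k_x_m, c_x, b_c)
  } else {
    p$a_g <- NA_real_
    p$a_m <- NA_real_
  }

  class(p) <- "thiamalloc_params"
  validate_params(p)
  p
}

#' Grid (discretization) parameters
#'
#' Resolution of the state and decision grids used by the backward
#' optimization, and the number of quadrature nodes used for the expectation
#' over the stochastic daily input.
#'
#' @param c_step State-grid resolution for the gonad and muscle
#'   concentrations, nmol/g. Must divide the ceiling `c_x` evenly.
#' @param alpha_step Allocation-grid resolution, in (0, 1].
#' @param n_input_nodes Number of equal-probability quantile-midpoint nodes
#'   discretizing the beta input distribution in the backward pass (1 gives
#'   the mean-input variant; forward simulation always draws continuously).
#' @return An object of class `"grid_params"`.
#' @export
grid_params <- function(c_step = 0.5, alpha_step = 0.05, n_input_nodes = 5L) {
  g <- list(c_step = c_step, alpha_step = alpha_step,
            n_input_nodes = as.integer(n_input_nodes))
  class(g) <- "grid_params"
  g
}

#' Derive daily survival bounds from annual anchors
#'
#' Converts the probabilities of surviving one whole year at the concentration
#' extremes into the daily survival bounds `p0` (at muscle concentration 0)
#' and `px` (at the ceiling `c_x`), such that `p0^days = annual_min` and
#' `px^days = annual_max` to machine precision.
#'
#' @param annual_min,annual_max Annual survival probabilities at minimum and
#'   maximum muscle thiamine, in (0, 1), `annual_min <= annual_max`.
#' @param days_per_year Days in one year.
#' @return Named numeric vector `c(p0 = , px = )`.
#' @examples
#' derive_daily_survival_bounds(0.001, 0.25, 365)
#' @export
derive_daily_survival_bounds <- function(annual_min, annual_max,
                                         days_per_year) {
  stopifnot(length(annual_min) == 1, length(annual_max) == 1)
  if (!is.finite(annual_min) || annual_min <= 0 || annual_min >= 1)
    stop("`annual_min` must be a probability in (0, 1)", call. = FALSE)
  if (!is.finite(annual_max) || annual_max <= 0 || annual_max >= 1)
    stop("`annual_max` must be a probability in (0, 1)", call. = FALSE)
  if (annual_min > annual_max)
    stop("`annual_min` must not exceed `annual_max`", call. = FALSE)
  if (days_per_year < 1) stop("`days_per_year` must be >= 1", call. = FALSE)
  c(p0 = exp(log(annual_min) / days_per_year),
    px = exp(log(annual_max) / days_per_year))
}

#' Derive the reabsorption coefficient of the power-law loss branch
#'
#' In the reabsorption-plus-passive-transport excretion model the loss rate is
#' `a * c^b_c` below the passive-transport threshold `c_t` and
#' `k_x * c / c_x` above it. This returns the coefficient `a` that makes the
#' two branches meet at `c_t`: `a * c_t^b_c = k_x * c_t / c_x`.
#'
#' @param c_t Passive-transport threshold concentration, nmol/g, in (0, c_x).
#' @param k_x Maximal mass-specific loss rate, nmol/g/d.
#' @param c_x Concentration ceiling, nmol/g.
#' @param b_c Reabsorption power-law exponent (>= 1).
#' @return The coefficient `a`.
#' @examples
#' derive_reabsorption_coefficient(6, 0.5, 30, 3) * 6^3  # = 0.1
#' @export
derive_reabsorption_coefficient <- function(c_t, k_x, c_x, b_c) {
  if (any(c(c_t, k_x, c_x, b_c) <= 0))
    stop("all arguments of derive_reabsorption_coefficient must be positive",
         call. = FALSE)
  if (c_t >= c_x)
    stop("`c_t` must be below the concentration ceiling `c_x`", call. = FALSE)
  k_x * c_t^(1 - b_c) / c_x
}

fail_field <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

#' @keywords internal
validate_params <- function(p) {
  chk_pos <- function(field, allow_zero = FALSE) {
    x <- p[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        (allow_zero && x < 0) || (!allow_zero && x <= 0))
      fail_field(field, if (allow_zero) "must be a non-negative number"
                 else "must be a positive number")
  }
  chk_pos("c_x")
  chk_pos("k_x_g", allow_zero = TRUE)
  chk_pos("k_x_m", allow_zero = TRUE)
  chk_pos("u"); chk_pos("v"); chk_pos("l")
  if (p$q_m <= 0 || p$q_m > 1)
    fail_field("q_m", "conversion efficiency must lie in (0, 1]")
  if (p$excretion_model == "sigmoid" && p$b <= 1)
    fail_field("b", "sigmoid shape must exceed 1 (the sigmoid degenerates)")
  if (p$excretion_model == "reabsorption_passive") {
    if (p$c_t <= 0 || p$c_t >= p$c_x)
      fail_field("c_t", "passive-transport threshold must lie in (0, c_x)")
    if (p$b_c < 1) fail_field("b_c", "reabsorption exponent must be >= 1")
  }
  chk_pos("c_b_mean", allow_zero = TRUE)
  chk_pos("c_b_halfwidth", allow_zero = TRUE)
  if (p$c_b_mean - p$c_b_halfwidth < 0)
    fail_field("c_b_halfwidth", "input range must not extend below 0")
  if (p$c_b_mean + p$c_b_halfwidth > p$c_x)
    fail_field("c_b_mean", "input range must stay below the ceiling c_x")
  if (length(p$beta_shape) != 2 || any(!is.finite(p$beta_shape)) ||
      any(p$beta_shape <= 0))
    fail_field("beta_shape", "must be two positive shape parameters")
  if (p$days_per_year < 1) fail_field("days_per_year", "must be >= 1")
  if (p$d_s < 1 || p$d_s > p$days_per_year)
    fail_field("d_s", "spawning day must lie within the year")
  if (p$i_max < 1) fail_field("i_max", "must be >= 1")
  if (p$starvation_days < 0 || p$starvation_days >= p$d_s)
    fail_field("starvation_days", "must be in [0, d_s)")
  if (p$N < 1) fail_field("N", "population size must be >= 1")
  if (p$c_g_init < 0 || p$c_g_init > p$c_x)
    fail_field("c_g_init", "must lie in [0, c_x]")
  if (p$c_m_init < 0 || p$c_m_init > p$c_x)
    fail_field("c_m_init", "must lie in [0, c_x]")
  if (!inherits(p$growth, "growth_params"))
    fail_field("growth", "must be a growth_params() object")
  if (!inherits(p$grid, "grid_params"))
    fail_field("grid", "must be a grid_params() object")
  g <- p$grid
  if (g$c_step <= 0 || abs(p$c_x / g$c_step - round(p$c_x / g$c_step)) > 1e-9)
    fail_field("grid$c_step", "must divide the ceiling c_x evenly")
  if (g$alpha_step <= 0 || g$alpha_step > 1)
    fail_field("grid$alpha_step", "must lie in (0, 1]")
  if (g$n_input_nodes < 1)
    fail_field("grid$n_input_nodes", "must be >= 1")
  validate_growth(p$growth, p)
  # derived constants
  if (abs(p$p0^p$days_per_year - p$annual_survival_min) > 1e-12 ||
      abs(p$px^p$days_per_year - p$annual_survival_max) > 1e-12)
    fail_field("p0/px", "derived daily survival bounds are inconsistent")
  invisible(p)
}

#' @export
print.thiamalloc_params <- function(x, ...) {
  cat("Thiamine-allocation model parameters\n")
  cat(sprintf("  ceiling c_x = %g nmol/g; loss k_x (gonad/muscle) = %g/%g nmol/g/d\n",
              x$c_x, x$k_x_g, x$k_x_m))
  cat(sprintf("  excretion model: %s", x$excretion_model))
  if (x$excretion_model == "sigmoid") cat(sprintf(" (b = %g)", x$b))
  if (x$excretion_model == "reabsorption_passive")
    cat(sprintf(" (b_c = %g, c_t = %g)", x$b_c, x$c_t))
  cat("\n")
  cat(sprintf("  input: c_b = %g +/- %g nmol/g, beta(%g, %g)%s\n",
              x$c_b_mean, x$c_b_halfwidth, x$beta_shape[1], x$beta_shape[2],
              if (x$starvation_days > 0)
                sprintf(", %d-day pre-spawn starvation", x$starvation_days)
              else ""))
  cat(sprintf("  survival: p0 = %.6f, px = %.6f (annual %g / %g), u = %g\n",
              x$p0, x$px, x$annual_survival_min, x$annual_survival_max, x$u))
  cat(sprintf("  recruitment exponent v = %g; migration exponent l = %g\n",
              x$v, x$l))
  cat(sprintf("  life history: %s, %d years x %d days, spawning day %d\n",
              x$reproductive_mode, x$i_max, x$days_per_year, x$d_s))
  cat(sprintf("  grids: c_step = %g, alpha_step = %g, input nodes = %d; N = %d\n",
              x$grid$c_step, x$grid$alpha_step, x$grid$n_input_nodes, x$N))
  invisible(x)
}

# Update a parameter object with new values, re-deriving constants.
#' Modify a parameter set
#'
#' Returns a new validated parameter object with the given fields replaced and
#' all derived constants recomputed. Convenient for scenario sweeps.
#'
#' @param params A [thiamalloc_params()] object.
#' @param ... Named fields of [thiamalloc_params()] to replace.
#' @return A new `thiamalloc_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "thiamalloc_params"))
  new <- list(...)
  base <- params[setdiff(names(formals(thiamalloc_params)),
                         c("excretion_model", "reproductive_mode",
                           "variation_filter"))]
  base <- base[!vapply(base, is.null, logical(1))]
  base$excretion_model <- params$excretion_model
  base$reproductive_mode <- params$reproductive_mode
  base$variation_filter <- params$variation_filter
  unknown <- setdiff(names(new), names(formals(thiamalloc_params)))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(new)] <- new
  do.call(thiamalloc_params, base)
}
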
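#' Quadrature nodes of the stochastic daily input
#'
#' Equal-weight quantile-midpoint discretization of the beta-distributed
#' blood thiamine input used for the expectation in the backward pass. With
#' one node this reduces to the median (= mean for the symmetric default).
#' Days inside the pre-spawn starvation window have all nodes set to zero.
#'
#' @param params A [thiamalloc_params()] object.
#' @return List with `nodes` (days_per_year x n_input_nodes matrix, nmol/g)
#'   and `weights` (summing to 1).
#' @export
input_nodes <- function(params) {
  nq <- params$grid$n_input_nodes
  q <- stats::qbeta((2 * seq_len(nq) - 1) / (2 * nq),
                    params$beta_shape[1], params$beta_shape[2])
  vals <- params$c_b_mean - params$c_b_halfwidth +
    q * 2 * params$c_b_halfwidth
  nodes <- matrix(rep(vals, each = params$days_per_year),
                  nrow = params$days_per_year, ncol = nq)
  nodes[starvation_window(params), ] <- 0
  list(nodes = nodes, weights = rep(1 / nq, nq))
}

# Days of the year with zero input under pre-spawn starvation.
#' @keywords internal
starvation_window <- function(params) {
  if (params$starvation_days == 0) return(logical(params$days_per_year))
  d <- seq_len(params$days_per_year)
  d >= params$d_s - params$starvation_days & d < params$d_s
}

#' Fit the optimal state-dependent allocation policy
#'
#' Computes, by backward induction over the discretized
#' (gonad, muscle)-concentration state space, the allocation fraction
#' `alpha(d, i, c_g, c_m)` of the daily blood thiamine pool that maximizes
#' expected lifetime recruit production. Within a year the value recursion
#' multiplies the concentration-dependent daily survival into the
#' continuation value each day; on the spawning day the recruitment reward
#' (recruitment probability times gonad mass) is collected, gonads reset,
#' and — for iteroparous females — the post-spawning migration survival
#' chains the value across years up to `i_max`, after which the value is
#' zero. Off-grid next states are evaluated by bilinear interpolation of the
#' value surface; the expectation over the stochastic input uses the
#' [input_nodes()] quadrature; ties between allocation levels resolve to the
#' smaller `alpha`.
#'
#' @param params A [thiamalloc_params()] object.
#' @param trajectory A [tissue_trajectory()]; defaults to
#'   [build_trajectory()] of `params`.
#' @return An object of class `"allocation_policy"`: a list with arrays
#'   `alpha` and `value` of dimension
#'   `(n_cg, n_cm, days_per_year, years)` (years = 1 for semelparous mode;
#'   `alpha` is `NA` on the spawning day, which carries no allocation
#'   decision), the state grids, the allocation levels, and the resolved
#'   parameters. Methods: [print()], [summary()], [plot()],
#'   [simulate.allocation_policy()].
#' @examples
#' \donttest{
#' p <- scenario_preset("baseline_low_input",
#'                      grid = grid_params(c_step = 1, alpha_step = 0.1,
#'                                         n_input_nodes = 3))
#' pol <- optimize_policy(p)
#' summary(pol)
#' }
#' @export
optimize_policy <- function(params, trajectory = build_trajectory(params)) {
  stopifnot(inherits(params, "thiamalloc_params"),
            inherits(trajectory, "tissue_trajectory"))
  years <- if (params$reproductive_mode == "semelparous") 1L else params$i_max
  if (ncol(trajectory$w_m) < years)
    stop("trajectory covers fewer years than the optimization horizon",
         call. = FALSE)
  cut <- function(M) M[, seq_len(years), drop = FALSE]
  traj <- tissue_trajectory(cut(trajectory$w_m), cut(trajectory$w_g),
                            cut(trajectory$w_b), d_s = trajectory$d_s)
  nxt <- next_day_masses(traj)

  cg_grid <- seq(0, params$c_x, by = params$grid$c_step)
  cm_grid <- cg_grid
  alpha_levels <- seq(0, 1, by = params$grid$alpha_step)
  if (alpha_levels[length(alpha_levels)] < 1)
    alpha_levels <- c(alpha_levels, 1)
  inp <- input_nodes(params)

  par <- list(c_x = params$c_x, q_m = params$q_m,
              k_x_g = params$k_x_g, k_x_m = params$k_x_m,
              excretion_code = match(params$excretion_model,
                                     c("sigmoid", "reabsorption_passive",
                                       "linear")) - 1L,
              b = params$b, b_c = params$b_c, c_t = params$c_t,
              a_g = ifelse(is.na(params$a_g), 0, params$a_g),
              a_m = ifelse(is.na(params$a_m), 0, params$a_m),
              p0 = params$p0, px = params$px,
              u = params$u, v = params$v, l = params$l,
              d_s = params$d_s,
              iteroparous = params$reproductive_mode == "iteroparous",
              recruits_raw = params$recruits_use_raw_concentration)

  res <- cpp_backward_induction(cg_grid, cm_grid, alpha_levels,
                                traj$w_m, traj$w_g, traj$w_b,
                                nxt$w_m, nxt$w_g,
                                inp$nodes, inp$weights, par)
  structure(list(alpha = res$alpha, value = res$value,
                 cg_grid = cg_grid, cm_grid = cm_grid,
                 alpha_levels = alpha_levels,
                 params = params, trajectory = traj),
            class = "allocation_policy")
}

#' Interpolate the policy or value surface at arbitrary states
#'
#' Bilinear interpolation of the allocation (or value) array at off-grid
#' `(c_g, c_m)` states for a given day and year. States outside the grid hull
#' are clamped to it.
#'
#' @param policy An [optimize_policy()] result.
#' @param c_g,c_m State coordinates (vectors of equal length), nmol/g.
#' @param day,year Time coordinates (scalars).
#' @param what `"alpha"` or `"value"`.
#' @return Numeric vector of interpolated values.
#' @export
policy_lookup <- function(policy, c_g, c_m, day, year = 1,
                          what = c("alpha", "value")) {
  what <- match.arg(what)
  A <- policy[[what]][, , day, year]
  interp_bilinear(A, policy$cg_grid, policy$cm_grid, c_g, c_m)
}

#' @export
print.allocation_policy <- function(x, ...) {
  d <- dim(x$alpha)
  cat(sprintf("Optimal thiamine-allocation policy (%s, %s excretion)\n",
              x$params$reproductive_mode, x$params$excretion_model))
  cat(sprintf("  state grid %d x %d (step %g nmol/g), %d allocation levels, %d input nodes\n",
              d[1], d[2], x$params$grid$c_step, length(x$alpha_levels),
              x$params$grid$n_input_nodes))
  cat(sprintf("  horizon %d year(s) x %d days, spawning day %d, input c_b = %g nmol/g\n",
              d[4], d[3], x$params$d_s, x$params$c_b_mean))
  v0 <- policy_lookup(x, x$params$c_g_init, x$params$c_m_init, 1, 1, "value")
  cat(sprintf("  expected lifetime recruit production at the initial state: %.3f\n", v0))
  invisible(x)
}

#' @export
summary.allocation_policy <- function(object, ...) {
  p <- object$params
  v0 <- policy_lookup(object, p$c_g_init, p$c_m_init, 1, 1, "value")
  # allocation switch along the deterministic median-input path, year 1
  path <- median_state_path(object, year = 1)
  out <- list(value_at_init = v0,
              switch_day = path$switch_day,
              terminal_zero_run = path$terminal_zero_run,
              params = p)
  class(out) <- "summary.allocation_policy"
  out
}

#' @export
print.summary.allocation_policy <- function(x, ...) {
  cat(sprintf("Expected lifetime recruits at (c_g, c_m) = (%g, %g): %.3f\n",
              x$params$c_g_init, x$params$c_m_init, x$value_at_init))
  if (is.na(x$switch_day)) {
    cat("No allocation switch to gonads detected along the median path.\n")
  } else {
    cat(sprintf("Median-input path, year 1: full switch to gonads (alpha = 0) from day %d (%d days before spawning)\n",
                x$switch_day, x$params$d_s - x$switch_day))
  }
  invisible(x)
}

#' Deterministic median-input state path through a policy
#'
#' Follows the policy from the initial state under the constant median input
#' (no stochasticity) for one year and returns the daily states and
#' allocations — the "median-state trajectory" used to characterize the
#' qualitative policy shape (allocation to muscles early in the pre-spawn
#' year, complete switch to gonads in a terminal window before spawning).
#'
#' @param policy An [optimize_policy()] result.
#' @param year Year of the policy to traverse.
#' @return A list with `path` (data frame day, c_g, c_m, alpha for the
#'   requested year), `switch_day` (first day of the terminal all-to-gonads
#'   run ending at the day before spawning, NA if none) and
#'   `terminal_zero_run` (its length in days).
#' @export
median_state_path <- function(policy, year = 1) {
  p <- policy$params
  sim <- simulate(policy, seed = p$seed, N = 1L, years = year,
                  deterministic_input = TRUE)
  d <- seq_len(p$days_per_year)
  t <- (year - 1) * p$days_per_year + d
  path <- data.frame(day = d, c_g = sim$c_g[t, 1], c_m = sim$c_m[t, 1],
                     alpha = sim$alpha[t, 1])
  zero <- path$alpha[seq_len(p$d_s - 1)] < 0.005
  run <- 0L
  for (k in rev(seq_along(zero))) {
    if (!zero[k]) break
    run <- run + 1L
  }
  list(path = path,
       switch_day = if (run > 0) p$d_s - run else NA_integer_,
       terminal_zero_run = run)
}

#' @export
plot.allocation_policy <- function(x, day = x$params$d_s - 30, year = 1, ...) {
  A <- x$alpha[, , day, year]
  graphics::image(x$cg_grid, x$cm_grid, A,
                  col = grDevices::hcl.colors(21, "viridis"),
                  xlab = expression(c[g] ~ "(nmol/g)"),
                  ylab = expression(c[m] ~ "(nmol/g)"),
                  main = sprintf("optimal alpha, day %d year %d", day, year),
                  ...)
  invisible(x)
}
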
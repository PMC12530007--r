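#' Draw the stochastic daily blood thiamine input
#'
#' Samples the blood thiamine concentration of the day for `n` females: a
#' beta draw (shape pair `beta_shape`, symmetric by default, normal-like)
#' affinely mapped to `c_b_mean +/- c_b_halfwidth`. With `c_b_halfwidth = 0`
#' the input is exactly `c_b_mean`. Days inside the pre-spawn starvation
#' window (when `starvation_days > 0`) receive zero input.
#'
#' @param n Number of draws.
#' @param params A [thiamalloc_params()] object.
#' @param day Day of the year (used only to apply the starvation window;
#'   `NULL` skips the check).
#' @return Numeric vector of `n` concentrations, nmol/g.
#' @export
draw_daily_input <- function(n, params, day = NULL) {
  if (!is.null(day) && params$starvation_days > 0 &&
      day >= params$d_s - params$starvation_days && day < params$d_s)
    return(rep(0, n))
  if (params$c_b_halfwidth == 0) return(rep(params$c_b_mean, n))
  params$c_b_mean - params$c_b_halfwidth +
    stats::rbeta(n, params$beta_shape[1], params$beta_shape[2]) *
    2 * params$c_b_halfwidth
}

#' Simulate a population of females following the optimal policy
#'
#' Forward Monte-Carlo simulation of `N` females that start at
#' `(c_g, c_m) = (c_g_init, c_m_init)` and, each day, draw an individual
#' stochastic blood input, look up their allocation fraction by bilinear
#' interpolation of the fitted policy at their current state, and apply the
#' daily tissue update. On each spawning day the pre-spawn state is
#' recorded, the spawning output (gonad concentration and mass, recruitment
#' probability) logged, and gonads reset; iteroparous females continue into
#' the next year. By default no females are removed by mortality — survival
#' shapes the policy through fitness, but the correlation analysis uses the
#' full population of trajectories; set `apply_mortality = TRUE` in the
#' parameters for stochastic removal (states become `NA` after death).
#'
#' Runs are reproducible: the same `(seed, params, policy)` gives a
#' bit-identical result.
#'
#' @param object An [optimize_policy()] result.
#' @param nsim Number of replicate populations (with seeds
#'   `seed, seed + 1, ...`); `nsim > 1` returns a list.
#' @param seed RNG seed (defaults to `params$seed`).
#' @param N Number of females (defaults to `params$N`).
#' @param years Number of years to simulate (defaults to the policy horizon;
#'   analyses of the pre-spawning season only need year 1).
#' @param deterministic_input If `TRUE`, every female receives the constant
#'   median input each day (population variance collapses to zero).
#' @param ... Unused.
#' @return An object of class `"population_sim"`: day-by-female matrices
#'   `c_g`, `c_m`, `alpha`, `c_b` (rows are global days
#'   `(year - 1) * days_per_year + day`, states are start-of-day values), a
#'   `spawns` data frame (female, year, c_g, c_m, w_g, recruit_prob,
#'   recruits), an `alive` matrix when mortality is applied, and metadata
#'   (`seed`, `params`). Methods: `print`, `plot`, `as.data.frame`.
#' @export
simulate.allocation_policy <- function(object, nsim = 1, seed = NULL,
                                       N = NULL, years = NULL,
                                       deterministic_input = FALSE, ...) {
  p <- object$params
  if (is.null(seed)) seed <- p$seed
  if (nsim > 1) {
    return(lapply(seq_len(nsim) - 1L, function(k)
      simulate.allocation_policy(object, nsim = 1, seed = seed + k, N = N,
                                 years = years,
                                 deterministic_input = deterministic_input)))
  }
  if (is.null(N)) N <- p$N
  Yp <- dim(object$alpha)[4]
  if (is.null(years)) years <- Yp
  stopifnot(years >= 1, years <= Yp)
  D <- p$days_per_year
  nt <- D * years

  set.seed(seed)
  cg <- rep(p$c_g_init, N)
  cm <- rep(p$c_m_init, N)
  alive <- rep(TRUE, N)
  M <- function() matrix(NA_real_, nrow = nt, ncol = N)
  out_cg <- M(); out_cm <- M(); out_a <- M(); out_cb <- M()
  out_alive <- if (p$apply_mortality) matrix(NA, nt, N) else NULL
  spawns <- vector("list", years)
  nxt <- next_day_masses(object$trajectory)

  for (i in seq_len(years)) {
    for (d in seq_len(D)) {
      t <- (i - 1L) * D + d
      out_cg[t, ] <- ifelse(alive, cg, NA_real_)
      out_cm[t, ] <- ifelse(alive, cm, NA_real_)
      if (p$apply_mortality) out_alive[t, ] <- alive

      if (d == p$d_s) {
        rp <- recruitment_probability(pmax(cg, 0), p)
        spawns[[i]] <- data.frame(
          female = seq_len(N), year = i,
          c_g = ifelse(alive, cg, NA_real_),
          c_m = ifelse(alive, cm, NA_real_),
          w_g = object$trajectory$w_g[d, i],
          recruit_prob = ifelse(alive, rp, NA_real_),
          recruits = ifelse(alive, rp * object$trajectory$w_g[d, i],
                            NA_real_))
        cg[] <- 0  # egg release over one day: gonadal thiamine leaves
        if (p$apply_mortality && p$reproductive_mode == "iteroparous") {
          pf <- migration_survival(cm, p)
          alive <- alive & (stats::runif(N) < pf)
        }
        next
      }

      cb <- if (deterministic_input) {
        if (p$starvation_days > 0 && d >= p$d_s - p$starvation_days &&
            d < p$d_s) rep(0, N) else rep(p$c_b_mean, N)
      } else draw_daily_input(N, p, day = d)
      a <- interp_bilinear(object$alpha[, , d, i],
                           object$cg_grid, object$cm_grid,
                           pmin(pmax(cg, 0), p$c_x),
                           pmin(pmax(cm, 0), p$c_x))
      out_a[t, ] <- ifelse(alive, a, NA_real_)
      out_cb[t, ] <- ifelse(alive, cb, NA_real_)
      upd <- daily_update(cg, cm, a, cb,
                          w_g = object$trajectory$w_g[d, i],
                          w_m = object$trajectory$w_m[d, i],
                          w_b = object$trajectory$w_b[d, i],
                          w_g_next = nxt$w_g[d, i],
                          w_m_next = nxt$w_m[d, i],
                          params = p)
      cg <- upd$c_g
      cm <- upd$c_m
      if (p$apply_mortality) {
        ps <- daily_survival(cm, p)
        alive <- alive & (stats::runif(N) < ps)
      }
    }
    if (p$reproductive_mode == "semelparous") break
  }

  structure(list(c_g = out_cg, c_m = out_cm, alpha = out_a, c_b = out_cb,
                 alive = out_alive,
                 spawns = do.call(rbind, spawns[!vapply(spawns, is.null,
                                                        logical(1))]),
                 years = years, N = N, seed = seed, params = p),
            class = "population_sim")
}

# Global day index helper.
#' @keywords internal
sim_day_index <- function(sim, day, year) {
  (year - 1L) * sim$params$days_per_year + day
}

#' @export
print.population_sim <- function(x, ...) {
  cat(sprintf("Simulated population: %d females x %d year(s) x %d days (seed %d)\n",
              x$N, x$years, x$params$days_per_year, x$seed))
  sp <- x$spawns[x$spawns$year == 1, ]
  cat(sprintf("  year-1 spawning: mean c_g = %.2f nmol/g, mean c_m = %.2f nmol/g, mean recruit prob = %.3f\n",
              mean(sp$c_g, na.rm = TRUE), mean(sp$c_m, na.rm = TRUE),
              mean(sp$recruit_prob, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.population_sim <- function(x, ..., years = seq_len(x$years)) {
  D <- x$params$days_per_year
  rows <- as.vector(vapply(years, function(i) (i - 1L) * D + seq_len(D),
                           integer(D)))
  nt <- length(rows)
  data.frame(
    female = rep(seq_len(x$N), each = nt),
    year = rep(rep(years, each = D), times = x$N),
    day = rep(rep(seq_len(D), times = length(years)), times = x$N),
    c_g = as.vector(x$c_g[rows, ]),
    c_m = as.vector(x$c_m[rows, ]),
    alpha = as.vector(x$alpha[rows, ]),
    c_b = as.vector(x$c_b[rows, ]))
}

#' @export
plot.population_sim <- function(x, year = 1, n_females = 50, ...) {
  D <- x$params$days_per_year
  rows <- sim_day_index(x, seq_len(D), year)
  idx <- seq_len(min(n_females, x$N))
  graphics::matplot(seq_len(D), x$c_m[rows, idx], type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.3),
                    xlab = sprintf("day of year %d", year),
                    ylab = "concentration (nmol/g)",
                    ylim = c(0, x$params$c_x), ...)
  graphics::matlines(seq_len(D), x$c_g[rows, idx], lty = 1,
                     col = grDevices::adjustcolor("firebrick", 0.3))
  graphics::lines(seq_len(D), rowMeans(x$c_m[rows, , drop = FALSE],
                                       na.rm = TRUE), lwd = 2)
  graphics::lines(seq_len(D), rowMeans(x$c_g[rows, , drop = FALSE],
                                       na.rm = TRUE), col = "firebrick",
                  lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("black", "firebrick"),
                   legend = c("muscle c_m", "gonad c_g"))
  invisible(x)
}
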
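#' Daily cross-sectional gonad-to-muscle regression
#'
#' Ordinary least-squares regression of muscle concentration (response) on
#' gonad concentration (predictor) across the females of one daily
#' population snapshot, with the inclusion filters that guard against
#' numerically meaningless fits: only females with `c_g > 0` enter; the fit
#' is attempted only when at least 3 females are included, the included
#' fraction exceeds `min_fraction` of the population, and the spread of the
#' included gonadal concentrations exceeds `var_threshold` nmol/g (spread
#' measured as the range by default, or the standard deviation via
#' `variation_filter = "sd"` in the parameters). A fitted day is *reported*
#' when its R-squared exceeds `r2_threshold`.
#'
#' @param c_g,c_m Per-female gonad and muscle concentrations of one day,
#'   nmol/g (`NA`s, e.g. dead females, are dropped).
#' @param var_threshold Minimum spread of included gonadal concentrations,
#'   nmol/g.
#' @param min_fraction Minimum included fraction of the population.
#' @param r2_threshold R-squared above which a slope is reported.
#' @param variation_filter `"range"` or `"sd"`.
#' @return One-row data frame: `n_included`, `slope`, `intercept`,
#'   `r_squared`, `passed_filters`, `reported`.
#' @examples
#' daily_regression(1:10, 2 * (1:10) + 1)  # exact line: slope 2, R^2 = 1
#' @export
daily_regression <- function(c_g, c_m, var_threshold = 0.5,
                             min_fraction = 2 / 3, r2_threshold = 0.2,
                             variation_filter = c("range", "sd")) {
  variation_filter <- match.arg(variation_filter)
  stopifnot(length(c_g) == length(c_m), length(c_g) > 0)
  ok <- !is.na(c_g) & !is.na(c_m)
  n_pop <- sum(ok)
  inc <- ok & c_g > 0
  n_inc <- sum(inc)
  empty <- data.frame(n_included = n_inc, slope = NA_real_,
                      intercept = NA_real_, r_squared = NA_real_,
                      passed_filters = FALSE, reported = FALSE)
  if (n_pop == 0 || n_inc < 3) return(empty)
  spread <- if (variation_filter == "range")
    diff(range(c_g[inc])) else stats::sd(c_g[inc])
  if (!(spread > var_threshold) || !(n_inc > min_fraction * n_pop))
    return(empty)
  fit <- stats::lm(y ~ x, data = data.frame(x = c_g[inc], y = c_m[inc]))
  tss <- sum((c_m[inc] - mean(c_m[inc]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  data.frame(n_included = n_inc,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = r2,
             passed_filters = TRUE,
             reported = r2 > r2_threshold)
}

#' Daily regression-slope trajectory of a simulated population
#'
#' Applies [daily_regression()] to every (year, day) snapshot of a
#' population simulation, producing the slope-versus-time series whose sign
#' and trend in the pre-spawn window are the model's headline indicator of
#' thiamine limitation.
#'
#' @param sim A [simulate.allocation_policy()] result.
#' @param years Years to analyse (default: all simulated years).
#' @param ... Passed to [daily_regression()] (`variation_filter` defaults to
#'   the simulation's parameter).
#' @return An object of class `"slope_trajectory"`: a data frame (year, day,
#'   n_included, slope, intercept, r_squared, passed_filters, reported)
#'   ordered by time, with the parameters attached.
#' @export
slope_trajectory <- function(sim, years = seq_len(sim$years), ...) {
  stopifnot(inherits(sim, "population_sim"))
  dots <- list(...)
  if (is.null(dots$variation_filter))
    dots$variation_filter <- sim$params$variation_filter
  D <- sim$params$days_per_year
  res <- vector("list", length(years) * D)
  k <- 0L
  for (i in years) {
    for (d in seq_len(D)) {
      t <- (i - 1L) * D + d
      k <- k + 1L
      row <- do.call(daily_regression,
                     c(list(c_g = sim$c_g[t, ], c_m = sim$c_m[t, ]), dots))
      row$year <- i
      row$day <- d
      res[[k]] <- row
    }
  }
  out <- do.call(rbind, res)
  out <- out[, c("year", "day", "n_included", "slope", "intercept",
                 "r_squared", "passed_filters", "reported")]
  attr(out, "params") <- sim$params
  class(out) <- c("slope_trajectory", "data.frame")
  out
}

#' Summarize reported slopes in the terminal pre-spawn window
#'
#' Aggregates the reported daily regression slopes over the last `window`
#' days before (and including) the spawning day of the chosen year: how many
#' days were reported, the sign balance, and whether the reported slopes are
#' non-decreasing towards spawning. This is the scenario-level summary used
#' to classify an input regime as showing a positive, negative, or no
#' gonad-muscle correlation signal.
#'
#' @param traj A [slope_trajectory()] result.
#' @param window Length of the pre-spawn window, days.
#' @param year Year to summarize.
#' @return A list: `n_days`, `n_reported`, `n_positive`, `n_negative`,
#'   `mean_slope`, `majority_sign` (+1, -1 or 0), `nondecreasing_fraction`
#'   (fraction of non-negative day-over-day slope changes among consecutive
#'   reported days), `trend_tau` (Kendall rank correlation of reported slope
#'   with day — positive when the slope rises towards spawning), `signal`
#'   (TRUE when at least `signal_min_days` days are reported: distinguishes a
#'   sustained correlation signal from isolated switch-day transients), and
#'   the subset data frame `days`.
#' @param signal_min_days Minimum number of reported days for the window to
#'   count as carrying a correlation signal.
#' @export
terminal_window_summary <- function(traj, window = 60,
                                    year = min(traj$year),
                                    signal_min_days = 10) {
  stopifnot(inherits(traj, "slope_trajectory"))
  p <- attr(traj, "params")
  d_s <- p$d_s
  sel <- traj$year == year & traj$day > d_s - window & traj$day <= d_s
  sub <- traj[sel, , drop = FALSE]
  rep_rows <- sub[sub$reported %in% TRUE, , drop = FALSE]
  n_pos <- sum(rep_rows$slope > 0)
  n_neg <- sum(rep_rows$slope < 0)
  nondec <- if (nrow(rep_rows) >= 2) {
    ds <- diff(rep_rows$slope[order(rep_rows$day)])
    mean(ds >= -1e-9)
  } else NA_real_
  tau <- if (nrow(rep_rows) >= 3)
    suppressWarnings(stats::cor(rep_rows$day, rep_rows$slope,
                                method = "kendall")) else NA_real_
  list(n_days = nrow(sub),
       n_reported = nrow(rep_rows),
       n_positive = n_pos,
       n_negative = n_neg,
       mean_slope = if (nrow(rep_rows)) mean(rep_rows$slope) else NA_real_,
       majority_sign = sign(n_pos - n_neg),
       nondecreasing_fraction = nondec,
       trend_tau = tau,
       signal = nrow(rep_rows) >= signal_min_days,
       days = sub)
}

#' @export
plot.slope_trajectory <- function(x, years = unique(x$year), ...) {
  p <- attr(x, "params")
  sel <- x$year %in% years & x$reported %in% TRUE
  t <- (x$year[sel] - 1) * p$days_per_year + x$day[sel]
  graphics::plot(t / p$days_per_year, x$slope[sel], type = "p", pch = 16,
                 cex = 0.6,
                 xlab = "time (years)", ylab = "regression slope (reported days)",
                 ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Spearman rank correlations of tissue thiamine by group
#'
#' Spearman rank correlation between muscle and gonad total thiamine in a
#' tissue-measurement table (simulated or empirical-style), per group of the
#' given labels (ties handled by midranks; two-sided p-value from the
#' large-sample test). Groups with fewer than 3 complete pairs are flagged
#' and get no test.
#'
#' @param tissue_table Data frame with columns
#'   `muscle_total_thiamine_nmol_g`, `gonad_total_thiamine_nmol_g`, and the
#'   grouping columns.
#' @param by Character vector of grouping column names (default system and
#'   stage; use `"system"` for stage-pooled correlations).
#' @return Data frame with one row per group: the group labels, `n`, `rho`,
#'   `p_value` and `flagged` (TRUE when n < 3 or a tissue is constant).
#' @export
spearman_by_group <- function(tissue_table, by = c("system", "stage")) {
  stopifnot(all(c("muscle_total_thiamine_nmol_g",
                  "gonad_total_thiamine_nmol_g", by) %in%
                  names(tissue_table)))
  key <- interaction(tissue_table[by], drop = TRUE, lex.order = TRUE)
  out <- lapply(split(tissue_table, key), function(g) {
    x <- g$gonad_total_thiamine_nmol_g
    y <- g$muscle_total_thiamine_nmol_g
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    base <- g[1, by, drop = FALSE]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(cbind(base, data.frame(n = length(x), rho = NA_real_,
                                    p_value = NA_real_, flagged = TRUE)))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    cbind(base, data.frame(n = length(x), rho = unname(ct$estimate),
                           p_value = ct$p.value, flagged = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
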
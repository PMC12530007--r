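#' Growth parameters of the deterministic tissue-mass trajectories
#'
#' The female body consists of locomotor (muscle) tissue, reproductive
#' (gonad) tissue, and blood. Somatic mass follows a saturating
#' (von-Bertalanffy-style) mass curve from the start of the modelled life
#' (one year before first spawning) towards an asymptote; gonads ramp up
#' linearly over the pre-spawn build-up window to a fixed gonadosomatic index
#' and are emptied at spawning (eggs released over one day); blood mass is a
#' fixed fraction of somatic mass. Tissue growth is independent of thiamine
#' status.
#'
#' @param soma_initial_mass Muscle mass at the start of the modelled life, g.
#' @param soma_asymptotic_mass Asymptotic muscle mass, g.
#' @param soma_growth_rate Growth-rate constant of the saturating mass curve,
#'   1/d.
#' @param gonad_peak_fraction Gonadosomatic index at spawning (gonad mass as a
#'   fraction of muscle mass), in (0, 1).
#' @param gonad_buildup_days Length of the pre-spawn gonad growth window, d.
#'   The default covers most of the year between spawnings, reflecting that
#'   oogenesis (and hence measurable gonadal thiamine) starts long before the
#'   spawning migration.
#' @param blood_fraction Blood mass as a fraction of muscle mass.
#' @param growth_mode `"growing"` (saturating somatic growth) or `"fixed"`
#'   (no growth after maturation, the capital-breeder variant: muscle and
#'   blood mass constant over life).
#' @param gonad_reset_mass Small positive gonad mass immediately after
#'   spawning (keeps concentrations defined), g.
#' @return An object of class `"growth_params"`.
#' @export
growth_params <- function(soma_initial_mass = 2000,
                          soma_asymptotic_mass = 8000,
                          soma_growth_rate = 0.001,
                          gonad_peak_fraction = 0.2,
                          gonad_buildup_days = 270L,
                          blood_fraction = 0.05,
                          growth_mode = c("growing", "fixed"),
                          gonad_reset_mass = 1) {
  growth_mode <- match.arg(growth_mode)
  g <- list(soma_initial_mass = soma_initial_mass,
            soma_asymptotic_mass = soma_asymptotic_mass,
            soma_growth_rate = soma_growth_rate,
            gonad_peak_fraction = gonad_peak_fraction,
            gonad_buildup_days = as.integer(gonad_buildup_days),
            blood_fraction = blood_fraction,
            growth_mode = growth_mode,
            gonad_reset_mass = gonad_reset_mass)
  class(g) <- "growth_params"
  g
}

#' @keywords internal
validate_growth <- function(g, p) {
  if (any(!vapply(g[c("soma_initial_mass", "soma_asymptotic_mass",
                      "soma_growth_rate", "gonad_peak_fraction",
                      "blood_fraction", "gonad_reset_mass")],
                  function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x) && x > 0, logical(1))))
    fail_field("growth", "all growth parameters must be positive numbers")
  if (g$gonad_peak_fraction >= 1)
    fail_field("growth$gonad_peak_fraction",
               "gonadosomatic index must be below 1")
  if (g$soma_asymptotic_mass < g$soma_initial_mass)
    fail_field("growth$soma_asymptotic_mass",
               "asymptote must not be below the initial mass")
  if (!missing(p) && g$gonad_buildup_days > p$days_per_year)
    fail_field("growth$gonad_buildup_days", "must not exceed days_per_year")
  invisible(g)
}

#' Low-level tissue-trajectory container
#'
#' Wraps day-by-year matrices of muscle, gonad and blood mass into a
#' `"tissue_trajectory"` object. Normally produced by [build_trajectory()];
#' exposed so that hand-crafted trajectories (e.g. constant masses) can be
#' passed to [optimize_policy()].
#'
#' @param w_m,w_g,w_b Numeric matrices of identical dimension
#'   (days_per_year x years) holding muscle, gonad and blood mass in g.
#' @param d_s Spawning day recorded for plotting (optional).
#' @return An object of class `"tissue_trajectory"`.
#' @export
tissue_trajectory <- function(w_m, w_g, w_b, d_s = nrow(w_m)) {
  stopifnot(is.matrix(w_m), is.matrix(w_g), is.matrix(w_b),
            all(dim(w_m) == dim(w_g)), all(dim(w_m) == dim(w_b)))
  if (any(w_m <= 0) || any(w_b <= 0) || any(w_g <= 0))
    stop("all tissue masses must be strictly positive", call. = FALSE)
  structure(list(w_m = w_m, w_g = w_g, w_b = w_b, d_s = d_s),
            class = "tissue_trajectory")
}

#' Deterministic tissue-mass trajectories over the female's life
#'
#' Builds the day-by-year matrices of muscle, gonad and blood mass implied by
#' the growth parameters: the modelled life starts one year before first
#' spawning, somatic mass grows (or stays fixed) deterministically, gonads
#' ramp linearly from their post-spawning reset mass to
#' `gonad_peak_fraction * w_m(d_s)` over the final `gonad_buildup_days`
#' before each spawning day, and drop back to the reset mass the day after
#' spawning. No randomness is involved.
#'
#' @param params A [thiamalloc_params()] object.
#' @return A [tissue_trajectory()] object with matrices of dimension
#'   `days_per_year x i_max`.
#' @examples
#' tr <- build_trajectory(thiamalloc_params(i_max = 2))
#' tr$w_g[365, 1] / tr$w_m[365, 1]  # gonadosomatic index at spawning
#' @export
build_trajectory <- function(params) {
  stopifnot(inherits(params, "thiamalloc_params"))
  g <- params$growth
  D <- params$days_per_year
  Y <- params$i_max
  d_s <- params$d_s

  # cumulative age in days since the start of the modelled life
  age <- matrix(seq_len(D * Y) - 1L, nrow = D, ncol = Y)
  if (g$growth_mode == "growing") {
    w_m <- g$soma_asymptotic_mass -
      (g$soma_asymptotic_mass - g$soma_initial_mass) *
      exp(-g$soma_growth_rate * age)
  } else {
    w_m <- matrix(g$soma_initial_mass, nrow = D, ncol = Y)
  }
  w_b <- g$blood_fraction * w_m

  w_g <- matrix(g$gonad_reset_mass, nrow = D, ncol = Y)
  ramp_start <- d_s - g$gonad_buildup_days
  for (i in seq_len(Y)) {
    peak <- g$gonad_peak_fraction * w_m[d_s, i]
    d <- seq_len(D)
    frac <- (d - ramp_start) / g$gonad_buildup_days
    frac <- pmin(pmax(frac, 0), 1)
    frac[d > d_s] <- 0  # emptied the day after spawning
    w_g[, i] <- g$gonad_reset_mass + frac * (peak - g$gonad_reset_mass)
  }
  tissue_trajectory(w_m, w_g, w_b, d_s = d_s)
}

# Masses of the *next* calendar day, aligned with each (day, year) cell.
# Day D of year i is followed by day 1 of year i+1; the final cell keeps its
# own masses (its continuation value is the terminal zero anyway).
#' @keywords internal
next_day_masses <- function(traj) {
  shift <- function(M) {
    D <- nrow(M); Y <- ncol(M)
    out <- M
    if (D > 1) out[seq_len(D - 1), ] <- M[seq(2, D), ]
    if (Y > 1) out[D, seq_len(Y - 1)] <- M[1, seq(2, Y)]
    out[D, Y] <- M[D, Y]
    out
  }
  list(w_m = shift(traj$w_m), w_g = shift(traj$w_g), w_b = shift(traj$w_b))
}

#' @export
print.tissue_trajectory <- function(x, ...) {
  D <- nrow(x$w_m); Y <- ncol(x$w_m)
  cat(sprintf("Tissue trajectory: %d days x %d years (spawning day %d)\n",
              D, Y, x$d_s))
  cat(sprintf("  muscle mass %g..%g g; peak gonad mass %g g; blood %g..%g g\n",
              min(x$w_m), max(x$w_m), max(x$w_g), min(x$w_b), max(x$w_b)))
  invisible(x)
}

#' @export
as.data.frame.tissue_trajectory <- function(x, ...) {
  D <- nrow(x$w_m); Y <- ncol(x$w_m)
  data.frame(year = rep(seq_len(Y), each = D),
             day = rep(seq_len(D), times = Y),
             w_m = as.vector(x$w_m),
             w_g = as.vector(x$w_g),
             w_b = as.vector(x$w_b))
}

#' @export
plot.tissue_trajectory <- function(x, ...) {
  df <- as.data.frame(x)
  t <- (df$year - 1) * nrow(x$w_m) + df$day
  graphics::plot(t / 365, df$w_m, type = "l", lwd = 2,
                 xlab = "age (years into modelled life)", ylab = "mass (g)",
                 ylim = c(0, max(df$w_m)), ...)
  graphics::lines(t / 365, df$w_g, col = "firebrick", lwd = 2)
  graphics::lines(t / 365, df$w_b, col = "steelblue")
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("black", "firebrick", "steelblue"),
                   legend = c("muscle", "gonad", "blood"))
  invisible(x)
}
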
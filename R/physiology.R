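#' Concentration-dependent recruitment, survival and migration probabilities
#'
#' The three fitness components of the model, each an allometric function of
#' a tissue thiamine concentration relative to the ceiling `c_x`:
#' \describe{
#'   \item{`recruitment_probability()`}{probability that spawned offspring
#'     recruit, `r = (c_g/c_x)^v`, driven by the gonadal concentration at
#'     spawning.}
#'   \item{`daily_survival()`}{daily adult survival,
#'     `p = p0 + (px - p0) (c_m/c_x)^u`, driven by the muscle TDP level.}
#'   \item{`migration_survival()`}{probability of surviving the post-spawning
#'     migration, `p_f = (c_m/c_x)^l` (iteroparous females only).}
#' }
#' All are monotone non-decreasing in the concentration and vectorized.
#'
#' @param c_g,c_m Tissue concentration(s), nmol/g, in `[0, c_x]`.
#' @param params A [thiamalloc_params()] object.
#' @return Probability vector of the same length as the concentration input.
#' @examples
#' p <- thiamalloc_params()
#' recruitment_probability(15, p)   # 0.5^0.025
#' daily_survival(c(0, 30), p)      # p0 and px
#' @name fitness_components
NULL

#' @rdname fitness_components
#' @export
recruitment_probability <- function(c_g, params) {
  if (any(c_g < 0)) stop("`c_g` must be non-negative", call. = FALSE)
  (pmin(c_g, params$c_x) / params$c_x)^params$v
}

#' @rdname fitness_components
#' @export
daily_survival <- function(c_m, params) {
  if (any(c_m < 0)) stop("`c_m` must be non-negative", call. = FALSE)
  params$p0 + (params$px - params$p0) *
    (pmin(c_m, params$c_x) / params$c_x)^params$u
}

#' @rdname fitness_components
#' @export
migration_survival <- function(c_m, params) {
  if (any(c_m < 0)) stop("`c_m` must be non-negative", call. = FALSE)
  (pmin(c_m, params$c_x) / params$c_x)^params$l
}

#' Concentration-dependent thiamine loss rate
#'
#' Mass-specific rate at which thiamine is lost from a tissue, as a function
#' of its concentration. Three kinetic laws are available:
#' \describe{
#'   \item{sigmoid}{renal reabsorption at low and active secretion at high
#'     concentration, `k = k_x / (((b-1)/(b+1)) * b^((0.5*c_x - c)/(0.5*c_x)) + 1)`;
#'     approaches a step at `c_x/2` as `b` grows.}
#'   \item{reabsorption + passive transport}{`k = a * c^b_c` below the
#'     threshold `c_t` and `k = k_x * c / c_x` above; `a` is derived so the
#'     branches meet at `c_t` (see [derive_reabsorption_coefficient()]).}
#'   \item{linear}{passive transport only, `k = k_x * c / c_x`.}
#' }
#'
#' `loss_rate()` dispatches on `params$excretion_model` and is the form used
#' by the optimizer and the simulator; the law-specific functions are exposed
#' for tabulating and plotting the kinetics.
#'
#' @param c Concentration(s), nmol/g, in `[0, c_x]`.
#' @param k_x Maximal mass-specific loss rate, nmol/g/d (tissue-specific:
#'   `params$k_x_g` for gonads, `params$k_x_m` for muscles).
#' @param c_x Concentration ceiling, nmol/g.
#' @param b Sigmoid shape (> 1).
#' @param b_c,c_t Reabsorption exponent and passive-transport threshold.
#' @param params A [thiamalloc_params()] object.
#' @return Loss rate(s), nmol/g/d, same length as `c`.
#' @examples
#' loss_rate_sigmoid(15, 0.5, 30, 200)  # k_x * (b+1) / (2b)
#' @name loss_rate
NULL

#' @rdname loss_rate
#' @export
loss_rate_sigmoid <- function(c, k_x, c_x, b) {
  if (b <= 1) stop("sigmoid shape `b` must exceed 1", call. = FALSE)
  if (any(c < 0)) stop("`c` must be non-negative", call. = FALSE)
  half <- 0.5 * c_x
  k_x / (((b - 1) / (b + 1)) * b^((half - c) / half) + 1)
}

#' @rdname loss_rate
#' @export
loss_rate_reabsorption <- function(c, k_x, c_x, b_c, c_t) {
  if (any(c < 0)) stop("`c` must be non-negative", call. = FALSE)
  a <- derive_reabsorption_coefficient(c_t, k_x, c_x, b_c)
  ifelse(c < c_t, a * c^b_c, k_x * c / c_x)
}

#' @rdname loss_rate
#' @export
loss_rate_linear <- function(c, k_x, c_x) {
  if (any(c < 0)) stop("`c` must be non-negative", call. = FALSE)
  k_x * c / c_x
}

#' @rdname loss_rate
#' @export
loss_rate <- function(c, k_x, params) {
  if (k_x == 0) return(rep(0, length(c)))
  switch(params$excretion_model,
         sigmoid = loss_rate_sigmoid(c, k_x, params$c_x, params$b),
         reabsorption_passive =
           loss_rate_reabsorption(c, k_x, params$c_x, params$b_c, params$c_t),
         linear = loss_rate_linear(c, k_x, params$c_x))
}

#' One daily update of the tissue thiamine state
#'
#' Applies one day of thiamine bookkeeping to the gonad and muscle
#' concentrations of one or more females (explicit Euler step of one day,
#' rates evaluated at the start-of-day state). The daily allocatable pool is
#' the free thiamine in the blood, `c_b * w_b` (nmol); a fraction `alpha`
#' goes to the muscles (converted to TDP with efficiency `q_m`) and
#' `1 - alpha` to the gonads. Tissue losses are `k(c) * w` with the selected
#' excretion kinetics. The updated *amounts* are divided by the next day's
#' tissue masses (growth dilution) to give the new concentrations, floored at
#' 0 (loss cannot exceed content) and clamped at the ceiling `c_x` (surplus
#' inflow is discarded; clamping counts are attached as attributes
#' `n_clamped_g` / `n_clamped_m`).
#'
#' @param c_g,c_m Start-of-day concentrations, nmol/g (vectors recycle
#'   against each other).
#' @param alpha Allocation fraction(s) to muscle, in `[0, 1]`.
#' @param c_b Blood thiamine concentration(s) today, nmol/g.
#' @param w_g,w_m,w_b Today's tissue masses, g.
#' @param w_g_next,w_m_next Tomorrow's gonad and muscle masses, g.
#' @param params A [thiamalloc_params()] object.
#' @return List with elements `c_g` and `c_m` (new concentrations), with
#'   clamping-count attributes.
#' @export
daily_update <- function(c_g, c_m, alpha, c_b, w_g, w_m, w_b,
                         w_g_next = w_g, w_m_next = w_m, params) {
  if (any(alpha < 0 | alpha > 1))
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (any(c_b < 0)) stop("`c_b` must be non-negative", call. = FALSE)
  if (any(c_g < 0) || any(c_m < 0))
    stop("concentrations must be non-negative", call. = FALSE)

  pool <- c_b * w_b
  amt_g <- c_g * w_g + (1 - alpha) * pool - loss_rate(c_g, params$k_x_g, params) * w_g
  amt_m <- c_m * w_m + params$q_m * alpha * pool -
    loss_rate(c_m, params$k_x_m, params) * w_m
  amt_g <- pmax(amt_g, 0)
  amt_m <- pmax(amt_m, 0)
  new_g <- amt_g / w_g_next
  new_m <- amt_m / w_m_next
  n_clamp_g <- sum(new_g > params$c_x)
  n_clamp_m <- sum(new_m > params$c_x)
  out <- list(c_g = pmin(new_g, params$c_x), c_m = pmin(new_m, params$c_x))
  attr(out, "n_clamped_g") <- n_clamp_g
  attr(out, "n_clamped_m") <- n_clamp_m
  out
}

#' Expected recruit production of one spawning
#'
#' The per-spawning fitness reward: recruitment probability at the spawning
#' gonadal concentration, times the gonad (egg) mass released, times the
#' probability of having survived the year up to spawning.
#'
#' @param c_g_at_spawn Gonadal concentration at the spawning day, nmol/g.
#' @param w_g_at_spawn Gonad mass at the spawning day, g.
#' @param survival_product Product of the daily survival probabilities from
#'   the start of the year through the spawning day, in `[0, 1]`.
#' @param params A [thiamalloc_params()] object.
#' @return Expected recruit production (units of egg mass, g).
#' @export
expected_recruits <- function(c_g_at_spawn, w_g_at_spawn, survival_product,
                              params) {
  if (any(survival_product < 0 | survival_product > 1))
    stop("`survival_product` must lie in [0, 1]", call. = FALSE)
  fac <- if (params$recruits_use_raw_concentration) c_g_at_spawn
         else recruitment_probability(c_g_at_spawn, params)
  fac * w_g_at_spawn * survival_product
}
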
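#' Named scenario presets
#'
#' Ready-made parameter sets for the scenario families the model is studied
#' under. All share the default anchors (ceiling 30 nmol/g, maximal loss
#' rates 0.5/0.35 nmol/g/d, annual survival anchors 0.001/0.25) and differ in
#' the excretion kinetics, the fitness-scaling exponents, the input level and
#' the reproductive mode:
#' \describe{
#'   \item{`baseline_low_input` / `baseline_high_input`}{sigmoid excretion
#'     (`b = 200`, near-step reabsorption-to-secretion switch at `c_x/2`),
#'     `u = 0.05`, `v = 0.025`, blood input 2 resp. 6 nmol/g — the low- and
#'     high-input scenarios whose pre-spawn regressions are positive resp.
#'     negative.}
#'   \item{`linear_loss`}{passive transport only (loss linear in
#'     concentration), same exponents; no reported correlations at any input
#'     level. Set `c_b_mean` via `...`.}
#'   \item{`reabsorption_low_input` / `reabsorption_high_input`}{renal
#'     reabsorption below the threshold `c_t` plus passive transport above
#'     (no active secretion), `u = v = 0.025`; pass `b_c` (3 or 6) and `c_t`
#'     (6 or 10) for the four studied kinetic shapes.}
#'   \item{`semelparous_high_input` / `semelparous_intermediate_input`}{the
#'     baseline sigmoid scenario with a single terminal spawning; the abrupt
#'     allocation switch leaves no correlations at these input levels.}
#'   \item{`starvation_low_input`}{the baseline low-input scenario with a
#'     two-month zero-input fast before spawning.}
#' }
#'
#' @param name Preset name (see above).
#' @param ... Parameter overrides forwarded to [thiamalloc_params()]
#'   (e.g. `grid`, `N`, `seed`, `b_c`, `c_t`, `c_b_mean`).
#' @return A [thiamalloc_params()] object.
#' @examples
#' scenario_preset("baseline_low_input")$c_b_mean
#' scenario_preset("reabsorption_low_input", b_c = 6, c_t = 10)$excretion_model
#' @export
scenario_preset <- function(name = c("baseline_low_input",
                                     "baseline_high_input",
                                     "linear_loss",
                                     "reabsorption_low_input",
                                     "reabsorption_high_input",
                                     "semelparous_high_input",
                                     "semelparous_intermediate_input",
                                     "starvation_low_input"),
                            ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    baseline_low_input = list(excretion_model = "sigmoid", b = 200,
                              u = 0.05, v = 0.025, c_b_mean = 2),
    baseline_high_input = list(excretion_model = "sigmoid", b = 200,
                               u = 0.05, v = 0.025, c_b_mean = 6),
    linear_loss = list(excretion_model = "linear",
                       u = 0.05, v = 0.025, c_b_mean = 2),
    reabsorption_low_input = list(excretion_model = "reabsorption_passive",
                                  b_c = 3, c_t = 6, u = 0.025, v = 0.025,
                                  c_b_mean = 2),
    reabsorption_high_input = list(excretion_model = "reabsorption_passive",
                                   b_c = 3, c_t = 6, u = 0.025, v = 0.025,
                                   c_b_mean = 6),
    semelparous_high_input = list(excretion_model = "sigmoid", b = 200,
                                  u = 0.05, v = 0.025, c_b_mean = 6,
                                  reproductive_mode = "semelparous"),
    semelparous_intermediate_input = list(excretion_model = "sigmoid",
                                          b = 200, u = 0.05, v = 0.025,
                                          c_b_mean = 4,
                                          reproductive_mode = "semelparous"),
    starvation_low_input = list(excretion_model = "sigmoid", b = 200,
                                u = 0.05, v = 0.025, c_b_mean = 2,
                                starvation_days = 60)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(thiamalloc_params, base)
}
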
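# Shared fixtures: coarse grids for fast policy runs and tiny grid-exact
# instances with an exhaustive-enumeration oracle for the backward induction.

coarse_grid <- function(n_input_nodes = 3L) {
  grid_params(c_step = 1, alpha_step = 0.1, n_input_nodes = n_input_nodes)
}

acceptance_grid <- function() {
  grid_params(c_step = 0.5, alpha_step = 0.05, n_input_nodes = 3L)
}

# A tiny deterministic instance whose dynamics land exactly on grid nodes:
# zero excretion, q_m = 1, equal constant tissue masses, integer input, so
# each daily update moves concentrations by integer grid steps (clamped at
# the ceiling). Semelparous, horizon <= 4 days.
make_tiny_instance <- function(seed) {
  set.seed(seed)
  D <- sample(2:4, 1)
  cb <- sample(c(2, 4), 1)
  alpha_step <- sample(c(1, 0.5), 1)   # levels {0,1} or {0,0.5,1}
  w <- sample(c(1, 2), 1)
  params <- thiamalloc_params(
    c_x = 5, k_x_g = 0, k_x_m = 0, q_m = 1,
    u = sample(c(0.5, 1, 2), 1), v = sample(c(0.5, 1, 2), 1), l = 0.2,
    excretion_model = "linear",
    c_b_mean = cb, c_b_halfwidth = 0,
    days_per_year = D, d_s = D, i_max = 1,
    reproductive_mode = "semelparous",
    grid = grid_params(c_step = 1, alpha_step = alpha_step,
                       n_input_nodes = 1L),
    growth = growth_params(gonad_buildup_days = 1L),
    N = 2L, c_g_init = 0, c_m_init = 0)
  traj <- tissue_trajectory(matrix(w, D, 1), matrix(w, D, 1),
                            matrix(w, D, 1), d_s = D)
  list(params = params, trajectory = traj)
}

# Exhaustive enumeration over all allocation sequences, using the same daily
# bookkeeping as the model but no value interpolation. Returns the maximal
# value for every grid state at day 1.
brute_force_values <- function(params, traj) {
  D <- params$days_per_year
  cg_grid <- seq(0, params$c_x, by = params$grid$c_step)
  alevels <- seq(0, 1, by = params$grid$alpha_step)
  w_g <- traj$w_g[1, 1]; w_m <- traj$w_m[1, 1]; w_b <- traj$w_b[1, 1]
  cb <- params$c_b_mean

  step <- function(cg, cm, a) {
    upd <- daily_update(cg, cm, a, cb, w_g, w_m, w_b, w_g, w_m, params)
    c(upd$c_g, upd$c_m)
  }
  recurse <- function(cg, cm, d) {
    if (d == params$d_s)
      return(daily_survival(cm, params) *
               recruitment_probability(cg, params) * w_g)
    best <- -Inf
    for (a in alevels) {
      s <- step(cg, cm, a)
      v <- daily_survival(cm, params) * recurse(s[1], s[2], d + 1)
      if (v > best) best <- v
    }
    best
  }
  outer(cg_grid, cg_grid,
        Vectorize(function(g, m) recurse(g, m, 1)))
}
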
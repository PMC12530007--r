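// Backward induction over the (c_g, c_m) state grid for the optimal
// day-by-day thiamine allocation fraction alpha.
//
// The value function V(d, i, c_g, c_m) is the expected future recruit
// production of a female alive at the start of day d in year i. Within a
// year, V(d) = max_alpha p(c_m) * E_{c_b}[ V(d+1, next_state) ]; on the
// spawning day the recruitment reward is collected, gonads reset to c_g = 0,
// and (iteroparous mode) the migration survival chains the years. The
// dynamics are separable in the two state axes, so the bilinear value
// interpolation factorizes into two per-axis linear interpolations.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum ExcretionModel { SIGMOID = 0, REABSORPTION = 1, LINEAR = 2 };

static inline double loss_rate_c(double c, double k_x, double c_x, int model,
                                 double b, double b_c, double c_t, double a) {
  if (k_x == 0.0) return 0.0;
  switch (model) {
  case SIGMOID: {
    double half = 0.5 * c_x;
    return k_x / (((b - 1.0) / (b + 1.0)) * std::pow(b, (half - c) / half) + 1.0);
  }
  case REABSORPTION:
    return (c < c_t) ? a * std::pow(c, b_c) : k_x * c / c_x;
  default:
    return k_x * c / c_x;
  }
}

// per-axis next-state interpolation coordinates on a uniform grid
static inline void axis_coord(double cn, double step, int n, int &i0,
                              double &fr) {
  double pos = cn / step;
  i0 = (int)std::floor(pos);
  if (i0 > n - 2) i0 = n - 2;
  if (i0 < 0) i0 = 0;
  fr = pos - i0;
  if (fr < 0.0) fr = 0.0;
  if (fr > 1.0) fr = 1.0;
}

// [[Rcpp::export]]
List cpp_backward_induction(NumericVector cg_grid, NumericVector cm_grid,
                            NumericVector alpha_levels,
                            NumericMatrix w_m, NumericMatrix w_g,
                            NumericMatrix w_b, NumericMatrix w_m_next,
                            NumericMatrix w_g_next,
                            NumericMatrix input_nodes,
                            NumericVector input_weights, List par) {
  const int n_g = cg_grid.size(), n_m = cm_grid.size();
  const int n_a = alpha_levels.size(), n_q = input_weights.size();
  const int D = w_m.nrow(), Y = w_m.ncol();
  const int ns = n_g * n_m;

  const double c_x = par["c_x"], q_m = par["q_m"];
  const double k_x_g = par["k_x_g"], k_x_m = par["k_x_m"];
  const int model = par["excretion_code"];
  const double b = par["b"], b_c = par["b_c"], c_t = par["c_t"];
  const double a_g = par["a_g"], a_m = par["a_m"];
  const double p0 = par["p0"], px = par["px"];
  const double u = par["u"], v = par["v"], l = par["l"];
  const int ds0 = (int)par["d_s"] - 1;  // 0-based spawning day
  const bool iteroparous = par["iteroparous"];
  const bool recruits_raw = par["recruits_raw"];
  const double step_g = (n_g > 1) ? cg_grid[1] - cg_grid[0] : 1.0;
  const double step_m = (n_m > 1) ? cm_grid[1] - cm_grid[0] : 1.0;

  // state-only precomputations
  std::vector<double> kg(n_g), km(n_m), p_day(n_m), p_mig(n_m), rew(n_g);
  for (int g = 0; g < n_g; ++g) {
    kg[g] = loss_rate_c(cg_grid[g], k_x_g, c_x, model, b, b_c, c_t, a_g);
    rew[g] = recruits_raw ? cg_grid[g] : std::pow(cg_grid[g] / c_x, v);
  }
  for (int m = 0; m < n_m; ++m) {
    km[m] = loss_rate_c(cm_grid[m], k_x_m, c_x, model, b, b_c, c_t, a_m);
    p_day[m] = p0 + (px - p0) * std::pow(cm_grid[m] / c_x, u);
    p_mig[m] = std::pow(cm_grid[m] / c_x, l);
  }

  NumericVector alpha_out((R_xlen_t)ns * D * Y);
  NumericVector value_out((R_xlen_t)ns * D * Y);
  alpha_out.attr("dim") = IntegerVector::create(n_g, n_m, D, Y);
  value_out.attr("dim") = IntegerVector::create(n_g, n_m, D, Y);

  std::vector<double> V_next(ns, 0.0), V_cur(ns), EV(ns);
  std::vector<std::vector<double>> V_day1(Y, std::vector<double>(ns, 0.0));
  std::vector<int> gi0(n_g), mi0(n_m);
  std::vector<double> gfr(n_g), mfr(n_m);

  for (int i = Y - 1; i >= 0; --i) {
    for (int d = D - 1; d >= 0; --d) {
      if (d == D - 1) {
        // successor of the last day of year i is day 1 of year i + 1
        if (i == Y - 1) std::fill(V_next.begin(), V_next.end(), 0.0);
        else V_next = V_day1[i + 1];
      }
      R_xlen_t off = ((R_xlen_t)i * D + d) * ns;

      if (d == ds0) {
        // spawning day: reward + (iteroparous) migration into next day with
        // gonads reset to c_g = 0 (grid node 0, no interpolation needed)
        double wgs = w_g(d, i);
        for (int m = 0; m < n_m; ++m) {
          double cont = 0.0;
          if (iteroparous) cont = p_mig[m] * V_next[0 + m * n_g];
          for (int g = 0; g < n_g; ++g) {
            double val = p_day[m] * (rew[g] * wgs + cont);
            V_cur[g + m * n_g] = val;
            value_out[off + g + m * n_g] = val;
            alpha_out[off + g + m * n_g] = NA_REAL;
          }
        }
      } else {
        double wg = w_g(d, i), wm = w_m(d, i), wb = w_b(d, i);
        double wgn = w_g_next(d, i), wmn = w_m_next(d, i);
        std::vector<double> best(ns, -1.0), besta(ns, NA_REAL);
        for (int a = 0; a < n_a; ++a) {
          double al = alpha_levels[a];
          std::fill(EV.begin(), EV.end(), 0.0);
          for (int q = 0; q < n_q; ++q) {
            double cb = input_nodes(d, q), wq = input_weights[q];
            double pool = cb * wb;
            for (int g = 0; g < n_g; ++g) {
              double amt = cg_grid[g] * wg + (1.0 - al) * pool - kg[g] * wg;
              if (amt < 0.0) amt = 0.0;
              double cn = amt / wgn;
              if (cn > c_x) cn = c_x;
              axis_coord(cn, step_g, n_g, gi0[g], gfr[g]);
            }
            for (int m = 0; m < n_m; ++m) {
              double amt = cm_grid[m] * wm + q_m * al * pool - km[m] * wm;
              if (amt < 0.0) amt = 0.0;
              double cn = amt / wmn;
              if (cn > c_x) cn = c_x;
              axis_coord(cn, step_m, n_m, mi0[m], mfr[m]);
            }
            for (int m = 0; m < n_m; ++m) {
              const double *col0 = V_next.data() + (R_xlen_t)mi0[m] * n_g;
              const double *col1 = col0 + n_g;
              double fm = mfr[m], omfm = 1.0 - fm;
              double *evrow = EV.data() + (R_xlen_t)m * n_g;
              for (int g = 0; g < n_g; ++g) {
                int i0 = gi0[g];
                double fg = gfr[g], omfg = 1.0 - fg;
                double val = omfm * (omfg * col0[i0] + fg * col0[i0 + 1]) +
                             fm * (omfg * col1[i0] + fg * col1[i0 + 1]);
                evrow[g] += wq * val;
              }
            }
          }
          for (int m = 0; m < n_m; ++m) {
            double p = p_day[m];
            for (int g = 0; g < n_g; ++g) {
              int s = g + m * n_g;
              double obj = p * EV[s];
              if (obj > best[s]) {  // strict: ties resolve to smaller alpha
                best[s] = obj;
                besta[s] = al;
              }
            }
          }
        }
        for (int s = 0; s < ns; ++s) {
          if (!std::isfinite(best[s]))
            stop("non-finite value at day %d, year %d, state %d",
                 d + 1, i + 1, s + 1);
          V_cur[s] = best[s];
          value_out[off + s] = best[s];
          alpha_out[off + s] = besta[s];
        }
      }
      V_next = V_cur;
      if (d == 0) V_day1[i] = V_cur;
    }
  }
  return List::create(_["alpha"] = alpha_out, _["value"] = value_out);
}
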
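# thiamalloc

Optimal thiamine (vitamin B1) allocation between muscles and gonads in
female salmonids, and the tissue-correlation signal it leaves in a
population.

Episodes of mass juvenile mortality in salmonids (the M74 syndrome of the
Baltic, and related syndromes elsewhere) are caused by thiamine deficiency:
females produce eggs of normal mass but load them with too little of the
vitamin. `thiamalloc` implements a state-dependent life-history model of how
a female should split her daily thiamine supply between locomotor tissue
(muscle, where the vitamin as TDP supports survival) and reproductive tissue
(gonads, where free thiamine determines offspring recruitment), given that
renal excretion makes the *rate of loss depend on tissue concentration*. The
model's practical output is an early-warning indicator: the sign and trend
of the daily cross-sectional regression between gonad and muscle thiamine
concentrations across females of a population.

## The model

State: gonadal free-thiamine concentration `c_g` and muscle TDP
concentration `c_m` (nmol/g wet weight, both capped at a ceiling
`c_x = 30`). Each day a female allocates a fraction `alpha` of the blood
thiamine pool `c_b * w_b` to muscle (conversion efficiency `q_m = 0.9`) and
the rest to gonads; tissues lose thiamine at a mass-specific rate `k(c)`.

Fitness components:

- recruitment probability `r = (c_g / c_x)^v` at spawning,
- daily adult survival `p = p0 + (px − p0) (c_m / c_x)^u`, calibrated so
  that a female survives a year with probability 0.001 at `c_m = 0` and
  0.25 at `c_m = c_x`,
- post-spawning migration survival `p_f = (c_m / c_x)^l` (iteroparous mode).

Excretion kinetics `k(c)` (per tissue, maxima 0.5 gonads / 0.35 muscles
nmol/g/d):

- **sigmoid** — renal reabsorption at low and active secretion at high
  concentration, inflection at `c_x / 2`, shape `b`;
- **reabsorption + passive** — a power law `a c^(b_c)` below a threshold
  `c_t`, linear passive transport above it;
- **linear** — passive transport only.

The fitness-maximizing allocation policy `alpha(day, year, c_g, c_m)` is
computed by backward induction over a discretized state space (expected
lifetime recruit production, horizon 15 years, daily survival chained
through each year and migration survival between years). Populations of
females following the policy under stochastic beta-distributed daily input
are then simulated forward, and daily OLS regressions of muscle on gonad
concentration — with inclusion filters and an `R² > 0.2` reporting rule —
give the slope-versus-time indicator. A synthetic tissue-table generator
emulates two-system (thiamine-limited vs. replete) field sampling for the
Spearman-correlation analysis path.

## Worked example

```r
library(thiamalloc)

p   <- scenario_preset("baseline_low_input", N = 300,
                       grid = grid_params(c_step = 1, alpha_step = 0.1,
                                          n_input_nodes = 3))
pol <- optimize_policy(p)
pol
#> Optimal thiamine-allocation policy (iteroparous, sigmoid excretion)
#>   state grid 31 x 31 (step 1 nmol/g), 11 allocation levels, 3 input nodes
#>   horizon 15 year(s) x 365 days, spawning day 365, input c_b = 2 nmol/g
#>   expected lifetime recruit production at the initial state: 179.704

summary(pol)
#> Expected lifetime recruits at (c_g, c_m) = (0, 15): 179.704
#> Median-input path, year 1: full switch to gonads (alpha = 0) from day 353 (12 days before spawning)

sim <- simulate(pol, seed = 1, years = 3)
tr  <- slope_trajectory(sim, years = 3)
sm  <- terminal_window_summary(tr, window = 120, year = 3)
sm[c("n_reported", "n_positive", "mean_slope", "trend_tau")]
#> $n_reported  [1] 101
#> $n_positive  [1] 101
#> $mean_slope  [1] 0.4470081
#> $trend_tau   [1] 0.4782349
```

Under this low-input scenario the expected lifetime output at the initial
state (`c_g = 0`, `c_m = 15` nmol/g) is ~180 g of recruit-weighted egg mass;
the optimal policy sends everything to muscle for most of the year and
switches completely to the gonads 12 days before spawning; and in the final
120 pre-spawn days of a steady annual cycle, 101 daily regressions pass the
reporting rule, all with positive slopes (mean 0.45 nmol/g per nmol/g) that
rise towards spawning (Kendall trend +0.48) — the signature of a
thiamine-limited population. Re-running with
`scenario_preset("baseline_high_input")` (blood level 6 nmol/g) flips every
reported slope negative, and `scenario_preset("linear_loss", ...)` reports
no sustained correlation at all: the indicator separates input regimes only
through the concentration-dependent excretion kinetics.

See `vignettes/thiamine-allocation.Rmd` for the full account of the model,
its parameters and the design choices.

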
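# oxyreg

Hypoxia response curve (HRC) analysis for closed-system respirometry, with
in-situ dissolved-oxygen logger summaries and a ground-truth synthetic data
generator.

## The problem

When a sealed respirometry chamber is allowed to draw down from ~100% air
saturation to anoxia, the organism's oxygen consumption rate (VO₂, mg O₂
h⁻¹) traced against ambient oxygen (pO₂, % air saturation) reveals where it
sits on the oxyconformer–oxyregulator continuum: a strict conformer's VO₂
falls in direct proportion to pO₂ (the identity line on normalized axes),
while a regulator holds VO₂ above that line as oxygen declines. `oxyreg`
turns raw optode traces into these curves, fits a constrained model family,
and parameterises regulation capacity via the **regulation function**

    ρ(x) = f(x)/x − f′(x),

where `f` is the fitted HRC on dimensionless axes (x = pO₂/100, y = VO₂
relative to the full-saturation rate). ρ ≡ 0 under strict conformity;
positive ρ is regulation effort beyond conformity. From ρ the package
extracts:

- **T_pos** — total positive regulation, ∫ max(ρ, 0) dx over the evaluated
  pO₂ window (relative units);
- **P_cmax** — the pO₂ (% air sat) of maximum regulation effort (for a
  Michaelis–Menten fit `f = Vmax·x/(K+x)`, analytically at x = K, since
  ρ = Vmax·x/(K+x)²), a hypoxic threshold for upregulation;
- **P_cmin** — the pO₂ of least regulation effort.

The model family is the one conventionally compared on such data: a
slope-only linear model through the origin (1 free parameter = scaled
strict conformity), origin-constrained polynomials of degree 2–12, and the
2-parameter Michaelis–Menten kinetics form, ranked by Gaussian-likelihood
AIC (`n·ln(2π·rss/n) + n + 2(p+1)`).

Audience: ecological physiologists running sealed-chamber drawdown assays
(corals and other benthic invertebrates) and anyone needing reproducible
oxyregulation statistics with honest model selection.

## Worked example

Simulate a regulator (Michaelis–Menten kinetics, K = 0.15, basal rate
0.3 mg O₂ h⁻¹) drawn down in a 400-mL chamber with 0.5% air-sat sensor
noise, then recover its regulation profile:

```r
library(oxyreg)
sim   <- simulate_drawdown(regulator_model("mm", basal_rate = 0.3, K = 0.15),
                           simulation_config(noise_sd = 0.5, seed = 1))
rates <- compute_vo2_curve(sim$trace, sim$blank)   # blank- & volume-corrected
curve <- normalize_curve(rates)
sel   <- select_best(curve)                        # AIC over the model family
head(sel$table, 3)
#>                model p_free      rss        aic
#> 1   michaelis_menten      2 5.961503 -14.883486
#> 2 constrained_poly_4      4 5.934573 -11.431317
#> 3 constrained_poly_6      6 5.885500  -8.436034
regulation_profile(sel$best)
#> <regulation_profile> T_pos = 1.367, P_cmax = 15.61%, P_cmin = 2.30% on [0.02, 0.99]
d <- drawdown_duration(sim$trace)
sprintf("drawdown: %.2f h (min %.1f%% air sat)", d$hours, d$min_airsat)
#> "drawdown: 10.10 h (min 1.4% air sat)"
```

The 2-parameter Michaelis–Menten fit beats every higher-order polynomial on
AIC, and the recovered P_cmax of 15.6% air saturation sits next to the
generating truth of 15% (100·K). T_pos is the integral of positive ρ over
the observed window [0.02, 0.99].

Group workflows (`make_experiment_fixture()` → `run_hrc_pipeline()`) add
per-group means ± SE and pairwise pooled t-tests; field logger analysis
(`read_logger_csv()`, `summarize_series()`, `cumulative_time_histogram()`,
`interior_exterior_delta()`, `align_with_tides()`, `run_field_pipeline()`)
summarises in-situ DO deployments and correlates interior-versus-exterior
DO deltas with ΔT_pos across colonies. A CLI wrapper lives at
`inst/cli/oxyreg.R` (see `?oxyreg_cli`).

### Output column dictionary (`run_hrc_pipeline()`)

| table | columns |
|---|---|
| `fragments` | `chamber_id`, `group`, `duration_h` (drawdown 100→0% with censoring flag), `best_model`, `rss`, `aic`, `t_pos`, `t_neg`, `p_cmax`, `p_cmin` (% air sat), `flagged`, `flag_reason` |
| `groups` | `group`, `statistic`, `mean`, `se` (sd/√n), `n` |
| `comparisons` | `statistic`, `group_a`, `group_b`, `t`, `df` (pooled: nₐ+n_b−2), `p`, `mean_a`, `mean_b` |

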
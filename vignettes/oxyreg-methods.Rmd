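---
title: "Methods: respirometry, HRC models and the regulation profile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry, HRC models and the regulation profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## From drawdown trace to consumption curve

A closed-system respirometry run produces an optode time series of percent
air saturation at nominally 60-s cadence in a sealed chamber of known
volume, alongside a coral-free seawater control (blank) and the seawater
displacement volume of the fragment. `compute_vo2_curve()` converts this to
an oxygen-consumption-versus-ambient-oxygen curve as follows.

**Windowed slopes.** Percent air saturation is converted to concentration
via `o2_solubility()` (Benson–Krause solubility with vapour-pressure-aware
barometric scaling) at each window's mean temperature, and a least-squares
slope is taken per sliding window. The instrument protocol only fixes the
cadence, not a rate-estimation window; the defaults — **window 600 s, step
300 s** (10 samples per window, 50% overlap) — smooth optode noise while
still resolving the low-pO₂ region where regulation collapses. Both are
exposed.

**Blank correction in pO₂, not wall-clock.** Control and organism chambers
traverse pO₂ at very different speeds, so the blank's volumetric rate
(mg L⁻¹ h⁻¹) is interpolated against *ambient pO₂* and subtracted at the
matching pO₂ of each organism window. When the blank spans less than 5
percentage points of air saturation — the usual case, since microbial
drawdown is slow — interpolation would merely extrapolate a single noisy
window estimate across the whole trace, so the blank rate is pooled (mean
over windows) instead. This choice is load-bearing: per-window blank slopes
carry standard errors comparable to the signal, and propagating one such
estimate into every low-pO₂ window badly inflates the variance of the
downstream K estimate.

**Volume scaling.** Net rates are multiplied by
`v_net = (chamber_volume − displacement_volume)/1000` litres to give whole-
fragment VO₂ in mg O₂ h⁻¹.

**Pre-processing.** Air saturation is clamped to [0, 120] (small sensor
excursions are tolerated on input within [−2, 120]) and the exact-zero
post-anoxia flatline is dropped before windowing, since it carries no rate
information.

**Normalization.** `normalize_curve()` maps to dimensionless axes:
x = pO₂/100 and y = VO₂/y_ref with **y_ref = mean VO₂ over the top decile
of observed x**. The normalization convention is not fixed by the assay;
a single highest-x point is too noisy a reference, while a top-decile mean
is stable and keeps y ≈ 1 at saturation for every model kind.

**Solubility conventions.** The default conversion uses salinity 35 ppt and
1013.25 mbar (seawater incubations). Note a documented quirk: the
freshwater (zero-salinity) value at 29.12 °C is 7.67 mg L⁻¹, and field
reports sometimes quote that figure for seawater; `o2_solubility()` takes
salinity explicitly so either convention is reproducible, and the airsat ↔
mg/L conversions are exact inverses.

## The model family

`fit_model()` supports three kinds, all constrained through the origin
(no oxygen, no aerobic respiration):

- **linear** `y = m·x` — scaled strict oxyconformity, 1 free parameter.
  An intercept model would have 2; the 1-parameter count is what makes the
  linear row the conformity null in AIC comparisons.
- **constrained_poly** `y = Σ_{j=1..d} a_j x^j`, degree 2–12 — the
  "constrained" in the name means only the intercept is omitted (f(0)=0),
  which matches the free-parameter count d. The default candidate set uses
  even degrees {2,…,12}; odd degrees are accepted.
- **michaelis_menten** `y = Vmax·x/(K+x)` — the 2-parameter saturating
  kinetics form; nonlinear least squares (port algorithm) with bounds
  Vmax ∈ (0, 10], K ∈ (10⁻⁴, 10], start Vmax₀ = max(y), K₀ = x at the
  first y ≥ Vmax₀/2, and fallback starts K₀·{0.1, 10} before failing with
  diagnostics.

**Conditioning at degree 12.** The polynomial solve uses a scaled power
basis `(x/max(x))^j` factored by QR, with coefficients reported on the raw
basis. On x ∈ [0, 1] this passes both conditioning checks the suite
imposes (normal-equation orthogonality of residuals at 10⁻⁸ and exact
invariance under re-expressing x in percent); a full orthogonal-polynomial
change of basis was considered and found unnecessary at these sizes.

**AIC.** `hrc_aic()` uses the Gaussian likelihood with the residual
variance counted as an estimated parameter,
`AIC = n·ln(2π·rss/n) + n + 2(p+1)` — the same convention as `AIC(lm(...))`
in R, so absolute values are comparable with common statistical reporting.
Because published absolute AICs depend on this bookkeeping, a
`gaussian_fixed_sigma` convention (without the +1) is available; AIC
*differences within one convention* — all that model ranking uses — do not
depend on the choice. `rss = 0` (perfect interpolation) returns −∞ with a
warning, which makes a perfectly nested exact fit win, with ties broken by
fewer free parameters and then kind order (linear < MM < polynomial).

## The regulation profile

`rho()` evaluates ρ(x) = f(x)/x − f′(x) analytically for every model kind
(for MM, ρ = Vmax·x/(K+x)², maximal exactly at x = K; for polynomials,
ρ = Σ (1−j)a_j x^{j−1}). For every origin-constrained fit ρ(0) is defined
by its limit, 0. `regulation_profile()` then:

- evaluates ρ on a uniform grid (default `grid_n = 1000`) over
  `[max(0.02, x_min observed), min(1, x_max observed)]`;
- integrates T_pos = ∫ max(ρ,0) dx and T_neg = ∫ min(ρ,0) dx by trapezoid;
- refines P_cmax/P_cmin from the grid arg-extrema by bounded scalar
  optimisation of the analytic ρ over the bracketing grid cells;
- reports P_cmax/P_cmin as undefined (NA) when ρ is constant across the
  grid within 10⁻¹² (conformity), and breaks exact argmin ties toward the
  larger x, so the minimum-regulation point of a saturating fit lands at
  the high-pO₂ end of the window rather than arbitrarily.

**Why the 2% floor.** The evaluation floor `floor = 0.02` mirrors the
assay's own termination criterion (runs are stopped at anoxia or just
below 2% air saturation), avoids the f/x singularity for shapes that do
not pass through the origin, and determines which end of the window hosts
P_cmin for saturating fits.

**T_pos convention.** T_pos here is the *plain integral* over the
evaluation window (`tpos_mode = "integral"`). The literature sometimes
glosses T_pos as an "average" regulation, which would suggest dividing by
the window width; that variant ships as `tpos_mode = "range_mean"`.
Calibrating which convention a given published table used requires that
study's archived data, so the package defaults to the integral and exposes
the switch rather than guessing. Note the scaling property the suite
verifies: multiplying y by c > 0 scales ρ and T_pos by c but leaves
P_cmax/P_cmin untouched, which is why P_cmax is the most
normalization-robust of the three statistics.

## Group comparisons

`two_sample_t()` defaults to the pooled-variance method (df = nₐ+n_b−2 —
the df printed in the field's reports for 6-vs-6 designs), with Welch and
paired options. `pearson()` reports r, R² = r² and the two-sided p with
df = n−2. `assumption_checks()` provides Shapiro–Wilk per group and a
Brown–Forsythe (median-centred) Levene test — implemented in-package as a
one-way ANOVA on absolute deviations from group medians, equivalent to the
squared pooled t on those deviations — and is advisory only: it never
gates the t-test. No multiple-testing correction is applied across a suite
of comparisons; callers doing many comparisons should correct themselves.

## What the synthetic generator does and does not emulate

`simulate_drawdown()` integrates the chamber mass balance
dC/dt = −[VO₂(pO₂)/v_net + blank_rate] by classical RK4 at the 60-s
logging cadence (Euler drifts measurably for fast conformers), with
VO₂ = basal_rate·g(pO₂/100) and g the conformer identity, the
endpoint-normalised MM form (1+K)x/(K+x) (so basal_rate is the rate at
full saturation regardless of K), or a supplied origin-constrained
polynomial. Sensor noise is i.i.d. Gaussian in % air saturation — the
optode's measurement domain — not in concentration. Integration terminates
on crossing below 2% air saturation or at 12 h, mirroring the assay's
termination rule; this matters for near-ideal regulators, whose tail decay
is exponential and would otherwise never reach an exact 0.

Defaults state the assumed world: 400-mL chambers, 50-mL displacement,
27 °C, 35 ppt, start at 100% air saturation, noise 0.5% air sat, microbial
blank 0.01 mg L⁻¹ h⁻¹, basal rate 0.3 mg O₂ h⁻¹ (≈ 8-h drawdown, the
middle of the typical 6–12-h run). `simulate_field_series()` generates a
diel-dominated exterior DO signal (24-h sinusoid peaking mid-afternoon,
plus a 12.42-h tidal component) and an interior copy scaled down by a
configured percentage with independent noise.

The generator does **not** emulate: diffusive-boundary-layer
microenvironments, photosynthetic O₂ production (dark respiration only),
commensal respiration, chamber mixing artefacts, optode drift or
autocorrelated noise, or tidal asymmetries. A green end-to-end test
therefore establishes that the estimation chain is unbiased and stable
under the stated noise model — not that any particular field dataset will
be reproduced.

## Numerical choices and degenerate inputs

- Trapezoidal integration plus analytic refinement keeps T_pos stable
  under grid refinement (|ΔT_pos| < 10⁻⁴ between 1000 and 2000 points).
- Finite-difference ρ from f agrees with analytic ρ to 10⁻⁶ on the grid
  (a property test, guarding the closed forms).
- Drawdown-duration crossings interpolate linearly between samples; the
  `end` threshold is non-strict so a trace ending exactly at the threshold
  counts as having reached it; traces that never reach `end` return a
  censored duration to the minimum attained.
- Non-respiring traces (y_ref ≤ 0), rank-deficient polynomial systems, MM
  non-convergence after fallbacks, and all-candidates-failed selection are
  hard errors with diagnostics; in the pipeline they flag the fragment and
  exclude it from summaries instead of aborting the run.

## Known limitations

- Michaelis–Menten K estimates from windowed rates are noisy at realistic
  sensor noise; replicate designs (n ≥ 3 per group) are assumed, as in the
  assay this package serves.
- The pooled t-test and Pearson correlation inherit their usual small-n
  fragility; the field pipeline flags correlations computed across fewer
  than 3 colonies rather than refusing them.
- Intermittent-flow respirometry, light incubations, and breakpoint-based
  P_crit estimation are out of scope.
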
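---
title: "Methods: from semi-quantitative cover records to effect sizes, ordination and calcification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from semi-quantitative cover records to effect sizes, ordination and calcification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefstats)
```

reefstats implements the statistical machinery needed to analyse
multi-decadal benthic surveys of coral communities colonising artificial
structures (breakwaters, wave-dissipating blocks, artificial tide pools)
alongside natural reefs, together with carbonate-chemistry estimates of net
ecosystem calcification (NEC) in artificial tide pools. This vignette is the
package's account of the models, their assumptions, the tunable parameters,
and the design decisions taken where the methodology left choices open.
Every empirical statement here is computed by the package's test suite or
examples; nothing is quoted from external data.

## 1. Resolving semi-quantitative cover records

Historical survey reports record percent cover per taxon (seven groups:
*Acropora*, *Pocillopora*, *Montipora*, *Porites*, Faviidae, *Millepora*,
other hard corals) as a number, a range, the symbol "R" (rare, under 1%
cover), "+" (1–5% cover), an explicit 0, or an empty cell. The resolution
rules are:

* a **range** resolves to its midpoint — the median of an interval is its
  midpoint, so `(low + high) / 2`;
* in the **total-cover** column, "R" is valued at 0.5% and "+" at 3%;
* an **empty cell is "no data"**, never 0. A recorded 0 means coral was
  looked for and not found. The two propagate differently: missing cells
  stay `NA` through `resolve_survey()` and exclude a record from analyses
  that need complete compositions.
* **per-taxon symbols** are valued jointly by `allocate_taxon_cover()`:
  count R-units across the symbolic cells ("+" counts as 6 R-units), take
  the remainder `diff = total − Σ(numeric taxon covers)`, and if positive
  give each symbolic taxon `units × diff / n_units`; if the remainder is
  zero or negative every symbolic cell gets 0. Numeric entries are never
  rescaled, and resolved totals may legitimately undershoot the taxon sum
  in raw data.

A deliberate consequence (left unclamped by design): an allocated "+" cell
can exceed the 5% ceiling of its definition when the unexplained remainder
is large. We apply the allocation rule verbatim rather than second-guessing
the recorder.

Elevation is stored signed relative to low water level (LWL), positive
upward, so an observation at "LWL −2 m" stores `elevation_lwl_m = -2`;
model covariates use depth below LWL, `depth_m = -elevation_lwl_m`. One
convention spans tide pools above LWL and breakwater faces below it.

## 2. Compositional transforms

Cover is compositional: the seven taxa plus the coral-free base
("other benthic") close to 100%. Analyses operate on log-ratios:

* `close_composition()` divides by 100 and appends
  `other_benthic = 1 − Σ parts`;
* `replace_zeros()` substitutes each zero with δ = 0.0025 (0.25%, half the
  1%-recording rounding error) and multiplies the nonzero parts by
  `1 − kδ`. The multiplicative variant is the default because it preserves
  closure and the ratios among nonzero parts; the naive substitution
  (no rescaling) is available via `method = "naive"` for sensitivity
  checks, since the source methodology does not state which variant was
  used;
* `alr_transform()` takes `log(part / other_benthic)` — the additive
  log-ratio with the coral-free base as denominator, removing the
  constant-sum constraint;
* `inverse_alr()` maps back (`parts ∝ exp(coord)`, denominator ∝ 1),
  normalises the named parts to 100%, and — only where explicitly requested
  (fitted response curves, Section 5) — zeroes covers below 0.25% without
  re-normalising. The floor mirrors the zero-replacement value; applying it
  to observed data would bias records, so it is restricted to
  back-transformed model output;
* `rclr_transform()` centres each row's logs by the row mean; Euclidean
  distance between rclr rows is the robust Aitchison distance used in
  ordination.

The round trip `inverse_alr(alr_transform(x))` reproduces `x` to 1e-10
(tested), and zero replacement preserves closure exactly.

## 3. Hierarchical Bayesian effect-size models

Three model equations share one sampling protocol (`hbm_spec()`,
`fit_hbm()`):

* **reef_cover** — alr cover of a taxon (or of total cover) against
  substrate (artificial = 0 / natural = 1), depth below LWL, survey year,
  and the substrate×depth and substrate×year interactions, with random
  intercepts for the 11 survey sites and 5 survey methods. Normal errors,
  identity link. The substrate×year interaction is the recovery-rate
  contrast: fitted to the post-bleaching window it asks whether cover
  recovered faster on artificial structures than natural reefs.
* **block_cover** — alr cover on wave-dissipating blocks against
  surface processing (grooved vs plain), depth, years since installation
  and both interactions; no random terms (single block field).
* **block_colony** — colony density on blocks, same design, gamma errors
  parameterized by mean and variance with a log link. Internally the
  mean–variance pair converts to shape `μ²/ε²` and rate `μ/ε²`. Zero
  counts are rejected with guidance — the gamma distribution has support
  on (0, ∞) — and the block generator draws strictly positive densities.

**Standardization.** All fixed covariates, binary indicators included, are
centred and divided by **twice** the sample SD (`standardize_design()`),
putting binary and continuous effect sizes on one scale (a standardized
column has SD 0.5). Interactions are products of the standardized main
effects, not standardized products, preserving main-effect interpretation.
Multicollinearity is screened (not gated) with `screen_collinearity()`:
VIFs from auxiliary least-squares fits plus the full Pearson matrix.

**Priors.** Coefficients have Uniform(−10, 10) priors (Uniform(−20, 20)
for the colony model); all SD scale parameters (residual, site, method)
have Half-Cauchy priors with scale 10⁻². That scale is unusually tight for
an SD prior — we implement it as stated because the Cauchy's heavy tail
still lets the likelihood dominate at realistic sample sizes (parameter
recovery tests confirm no measurable shrinkage at n ≈ 100–400), and
`hbm_spec(halfcauchy_scale = )` overrides it in one keystroke.

**Sampling.** Five independent MCMC runs with seeds derived
deterministically from one master seed; each run discards 1000 tuning
iterations and retains 2000, pooling 10,000 draws. The engine is JAGS
(via rjags), the package's choice of Bayesian engine in R; the posterior
is defined by the model and priors, not by the sampler family, and
convergence is verified rather than assumed: the classical (non-split)
Gelman–Rubin statistic is computed across the five runs per parameter
(`gelman_rubin()`, cross-checked against `coda::gelman.diag()` in the
tests) and rounds to 1.00 on well-specified synthetic fits. Model fit is
summarised by Bayesian R² — per-draw `var(fit)/(var(fit)+var(resid))`.

**Effect classification.** Each coefficient is summarised by its posterior
median and 80%/95% highest density intervals (`hdi()`: the shortest
contiguous interval holding the requested mass of sorted draws). A trend
is *credible* when the 80% HDI excludes zero; an endpoint exactly at zero
counts as overlapping (conservative). Under null slopes the rule flags
≈20% of coefficients, which the acceptance suite verifies within binomial
error.

## 4. Ordination and permutation tests

`robust_aitchison_dist()` → `nmds()` → `fit_env_vectors()` /
`permanova()` / `pairwise_permanova()` wrap the vegan implementations
(`metaMDS`/`monoMDS`, `envfit`, `adonis2`) behind a tidy surface, because
vegan is the canonical tool for exactly these steps. Choices:

* nMDS minimises Kruskal stress-1 by monotone regression with random
  restarts; the restart budget defaults to 999 (the search stops early on
  convergent repeated solutions), and the best configuration is centred
  and rotated to principal axes. The "999 permutations for ordination"
  convention is ambiguous between restarts and an internal test; we read
  it as a restart budget and expose it as `restarts`.
* PERMANOVA uses sequential (Type-I) sums of squares in entry order
  substrate, year, depth, then the substrate interactions, with
  `p = (exceedances + 1) / (perms + 1)` from free row permutation
  (default 9999). Year enters as a numeric covariate here — matching its
  role in the cover model — but as the grouping factor in pairwise tests
  between years. The Gower-partition pseudo-F is verified against an
  exhaustive-enumeration oracle (all n! relabelings for n ≤ 7) in the
  acceptance suite.
* Pairwise PERMANOVA runs one-factor tests per group pair and applies
  Bonferroni (`min(1, p × n_pairs)`); groups with fewer than 2 samples are
  skipped with a warning rather than silently dropped.

## 5. Environmental response curves

`fit_smooth()` models alr cover against one gradient (depth, slope, light)
with a thin-plate regression spline, smoothing penalty chosen by
generalized cross-validation (mgcv's `GCV.Cp`). Defaults: basis dimension
`k = 10`; pass `k = 7` where the survey design offers only seven distinct
depths (the port-side wall case) — `fit_smooth()` also auto-reduces `k`
with a warning when distinct covariate values are fewer. Confidence bands
are fitted ± 1.96 SE from the penalized-fit covariance. GCV occasionally
undersmooths an individual realisation (median EDF is 1.0 under a linear
truth, but ~1 draw in 5 fits a slightly wiggly curve), which is why the
tests assess EDF on the median over replicates.

`back_transform_curves()` evaluates all seven taxon smooths plus the base
on a shared grid, inverse-alr transforms, normalises each grid point to
100%, and floors sub-0.25% covers to zero (no re-normalisation). Total
cover is back-transformed as the two-part total/other case.

## 6. Net ecosystem calcification in tide pools

During low tide an artificial tide pool is isolated from the sea; total
alkalinity (TA) then changes only through benthic processes, two moles of
TA per mole of CaCO₃. `window_nec()` implements

NEC = −½ · (ΔTA/Δt) · Z̄ · ρ_water  [mmol CaCO₃ m⁻² h⁻¹],

with ΔTA/Δt the least-squares TA-vs-time slope over a short window (using
all samples, not endpoints — the regression SE then propagates directly to
the NEC SE), Z̄ the mean water depth and ρ the seawater density from the
EOS-80 one-atmosphere polynomial (`seawater_density()`, constant override
available). TA is carried in mmol kg⁻¹; the series validator warns when
values look like µmol kg⁻¹. Windows must lie wholly inside a stagnant span
(the advection-free assumption) and span more than 30 min. With a 10–12
min sampling interval three samples span only 20–24 min, so
`nec_windows()` widens windows beyond the 3-sample minimum until the
30-min requirement holds — typically four samples.

`fit_light_response()` regresses window NEC on light as either a
saturating hyperbolic tangent `a·tanh(I/I_k) + c` (the
photosynthesis–irradiance analogue: `a` the light-saturated amplitude,
`I_k` the saturation onset, `c` the dark rate) or a straight line; the
parameterization and the selection rule (small-sample AIC, with a linear
fallback if the nonlinear fit fails) are package choices, since the
methodology names both forms without a criterion. `integrate_daily_nec()`
integrates the fitted response over a 24-h light record (trapezoid,
night-time zeros included) and propagates parameter uncertainty to the
integral by the delta method — the gradient of the integral in the
parameters through the fit covariance — verified against a 10,000-draw
Monte-Carlo oracle to within 10%. `compare_station_slopes()` covers the
between-station question with a standard ANCOVA of TA against time by
station and Tukey-style slope contrasts.

Sign convention, everywhere: TA drawdown (calcification) ⇒ positive NEC.

## 7. What the synthetic generators emulate

The generators are first-class, tested code; they define the study
conditions under which all calibration and recovery claims are made.

* `simulate_survey()` — an 11-site, 5-method design split across
  artificial and natural substrate; per-taxon alr means from the reef-cover model
  design with site/method random intercepts (SDs 0.4 / 0.25) and residual
  SD 0.5; true coefficients are expressed on the standardized scale the
  models estimate on, and the generator standardizes its own design with
  the same 2SD rule, so recovery tests are exact contrasts. Cells whose
  true cover is below 1% (respectively 1–5%) may be degraded to "R"
  (resp. "+"), and larger covers to ranges, at configurable rates —
  symbols are only injected where their definitions permit. The default
  span is the post-bleaching recovery window (2000–2018); spans reaching
  back to 1989 superimpose a disturbance drop (2.0 alr units) at 1998
  with linear relaxation over 6 years on artificial substrate versus 14
  on natural reef, encoding the faster-recovery contrast.
* `simulate_block_survey()` — the block design exactly: 2 processing
  levels × 3 sections × 3 depths (2/5/8 m below LWL) = 18 quadrats per
  year over 18 years; cover via the block-cover normal-alr model and colonies via
  the block-colony gamma model (γ SD 2.0 colonies m⁻²).
* `simulate_tidepool_day()` — a sinusoidal daytime light curve (peak 1500,
  daylight 06:00–18:00), a known tanh light response (defaults a = 6,
  I_k = 500, c = −1 mmol m⁻² h⁻¹), TA evolved forward through the
  TA-anomaly relation on a fine grid, and measurement noise at the
  titration accuracy (3 µmol kg⁻¹). The default stagnant spans pair a
  morning span with a night span, emulating the pooling of daytime and
  night-time sampling days that makes both ends of the light response
  identifiable. The truth sidecar includes the analytic daily integral of
  the true response.

What the generators do **not** emulate — and hence what passing tests do
not certify about real data: transcription errors and method drift in
40-year survey archives, spatial autocorrelation among neighbouring sites,
non-normal alr residuals (e.g. heavy-tailed bleaching years), tide-driven
depth variation within a stagnant span, and advective exchange when a pool
rim is marginally submerged.

## 8. Problem sizes, numerics and reproducibility

Test and example problem sizes are deliberate package choices balancing
statistical resolution against runtime: survey recovery uses n ≈ 400
records × 20 replicates; HDI calibration uses 50 null replicates of the
4-year block design; PERMANOVA calibration uses 50 null replicates at
n = 20 with 199 permutations (9999 where a single sharp p-value matters);
the exhaustive PERMANOVA oracle enumerates all permutations for n ≤ 7.

Degenerate inputs are errors, not silent repairs: constant covariates,
zero colony counts, all-zero composition rows, inverted ranges, windows
crossing a stagnant boundary, light series with gaps over 2 h. Ties in the
HDI are resolved by the first shortest window of sorted draws; an 80% HDI
endpoint exactly at zero is classified not-credible.

All randomness descends from explicit seeds: `fit_hbm()` expands one
master seed into five run seeds; `run_stage()` threads a single seed
through every stage and records it in a JSON manifest with input/output
digests, so a run can be reproduced bit-for-bit.

## 9. Known limitations

* The sampler is JAGS's conditional samplers, not Hamiltonian; for the
  model sizes here mixing is excellent (R̂ = 1.00), but much larger
  random-effect structures might mix slower.
* PERMANOVA p-values use free permutation; no restricted permutation
  within sites/years is offered.
* The NEC module deliberately omits advection, diffusion, carbonate
  speciation and nutrient corrections to TA.
* Back-transformed curve bands are pointwise on the alr scale; the
  percent-scale curves carry no bands because normalisation couples taxa.
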
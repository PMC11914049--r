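# reefstats

Statistical pipeline for long-term coral community recovery surveys on
artificial structures and natural reefs, and for carbonate-chemistry
estimates of net ecosystem calcification in artificial tide pools.

Decades of harbour-works monitoring produce benthic cover tables that are
only semi-quantitative — a cell may hold `23`, `20-30`, `R` (rare, <1%
cover), `+` (1–5%), `0`, or nothing at all — yet they are the only record
of how coral communities collapsed after mass bleaching and recovered on
breakwaters versus natural reefs. reefstats turns those records into
defensible statistics for coastal ecologists and eco-engineering
practitioners:

* **Record resolution** — deterministic rules for symbols and ranges
  (`R` → 0.5%, `+` → 3% in totals; per-taxon symbols valued from the
  unexplained remainder with `+` counting 6 R-units), with a strict
  zero-vs-missing distinction (`parse_cover_entry()`,
  `allocate_taxon_cover()`, `resolve_survey()`).
* **Compositional analysis** — closure against the coral-free base,
  multiplicative zero replacement at δ = 0.0025, additive log-ratio (alr)
  transform and inverse, robust centred log-ratio (`cover_to_alr()`,
  `inverse_alr()`, `rclr_transform()`).
* **Hierarchical Bayesian effect sizes** — alr cover ~ substrate + depth +
  year + interactions with site and method random intercepts (and the
  block-survey normal and gamma variants), covariates standardized by 2 SD,
  Uniform coefficient priors, Half-Cauchy(10⁻²) scale priors, five
  independent MCMC runs of 1000 tuning + 2000 retained draws (10,000
  pooled), 80%/95% HDIs with credible-trend classification, Gelman–Rubin
  and Bayesian R² (`fit_hbm()`, `hdi()`, `classify_trend()`).
* **Community ordination** — robust Aitchison distances, nMDS with random
  restarts, fitted correlation vectors, sequential two-way PERMANOVA and
  Bonferroni-corrected pairwise tests (`nmds()`, `permanova()`).
* **Response curves** — thin-plate-spline smooths of alr cover against
  depth/slope/light with GCV-selected penalty, 95% bands, and
  back-transformation to percent cover with the 0.25% floor
  (`fit_smooth()`, `back_transform_curves()`).
* **Calcification** — NEC = −½ · ΔTA/Δt · Z̄ · ρ from stagnant tide-pool
  alkalinity windows, tanh/linear light-response fits, daily integration
  with delta-method error propagation (`window_nec()`,
  `integrate_daily_nec()`).
* **Synthetic data with known truth** — seeded generators for every stage
  (`simulate_survey()`, `simulate_block_survey()`,
  `simulate_tidepool_day()`), used by the test suite for parameter-recovery
  and calibration checks.

Everything takes and returns tibbles, pipes cleanly, and has
`tidy()`/`glance()`/`autoplot()` methods for the fitted objects.

## Worked example

Simulate the wave-dissipating-block survey (18 quadrats per year over 18
years: 2 surface-processing levels × 3 sections × 3 depths) and estimate
the effect of surface processing on coral cover:

```r
library(reefstats)

sim <- simulate_block_survey(block_sim_config(seed = 1))
fit <- fit_hbm(sim$data, "alr_cover", hbm_spec("block_cover"), seed = 1)
fit
#> Hierarchical Bayesian fit (block_cover): n = 324, 5 runs x 2000 draws = 10000 pooled
#>   term     median hdi80_lower hdi80_upper hdi95_lower hdi95_upper credible  rhat
#> 1 interce… -1.48      -1.51        -1.44       -1.53       -1.42  credibl… 1.000
#> 2 process…  0.763      0.693        0.830       0.660       0.872 credibl… 1.00
#> 3 depth    -0.471     -0.544       -0.407      -0.577      -0.369 credibl… 1.00
#> 4 years     1.00       0.930        1.07        0.896       1.11  credibl… 1.000
#> 5 process…  0.110     -0.0275      0.249       -0.109       0.322 not_cre… 1.00
#> 6 process…  0.562      0.420        0.702       0.344       0.774 credibl… 1.000
#> 7 eps       0.486      0.460        0.508       0.449       0.524 <NA>     1.000
#> Bayesian R2 (median): 0.669; max rhat: 1.001
```

The `processing` row is the headline effect size: surface-processed block
areas carry credibly higher alr cover (posterior median 0.76, 80% HDI
0.69–0.83, truth used by the generator 0.8), and the `processing:years`
interaction (median 0.56, truth 0.5) says the processed surfaces also
gained cover faster. Effects are on the standardized (2 SD) alr scale;
`credible` flags use the 80% HDI-excludes-zero rule and every Gelman–Rubin
statistic rounds to 1.00.

Estimate daily net ecosystem calcification for a simulated tide-pool
sampling day:

```r
tp <- simulate_tidepool_day(tidepool_sim_config(seed = 1))
w  <- nec_windows(tp$series)             # sliding >30-min TA windows
lr <- fit_light_response(w$nec, w$mean_light)
lr
#> Light response (tanh): a = 6.084, Ik = 618.9, c = -0.8535
integrate_daily_nec(lr, tp$light_day)
#>   daily_nec daily_nec_sd
#> 1      27.7         8.89
tp$truth$daily_nec_true
#> st1: 26.48
```

The saturating (tanh) form is selected by small-sample AIC; the daily
integral, 27.7 ± 8.9 mmol CaCO₃ m⁻² day⁻¹, brackets the generator's
analytic truth of 26.5 well within one propagated SD.

The stages also run as an orchestrated pipeline with JSON manifests:

```r
run_pipeline(c("simulate", "resolve", "ordinate", "curves"),
             outdir = "run1", seed = 1)
```

See `vignettes/coral-recovery-methods.Rmd` for the models, their
assumptions and the design decisions.

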
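# stagetherm

Stagewise analysis of temperature-dependent insect development, built
around the destructive-sampling study design used for the cowpea seed
beetle *Callosobruchus maculatus*: cohorts of same-age eggs are sacrificed
at scheduled ages and staged, so stage timing must be inferred from counts
of individuals past each stage boundary rather than from individual
trajectories.

The package implements the full inferential chain:

1. **Median transition times** — per stage boundary and temperature, a
   binomial logistic regression of the proportion past the boundary on
   cohort age, `logit P = β₀ + β₁t`, with the median transition time
   `t₅₀ = −β₀/β₁`. Synchronous transitions separate completely (all-0
   jumps to all-1), so a Firth-type bias-reduced fit maximizing
   `ℓ(β) + ½ log det I(β)` is provided and selected automatically; it is
   finite under separation.
2. **Stage durations and rates** — durations are differences of
   consecutive transition times; rates are reciprocal durations
   (`R = 1/D`), with explicit per-hour/per-day unit tags.
3. **Thermal reaction norms** — ordinary least squares `R = a + bT`
   against actual chamber temperatures, accepted as linear when
   `R² ≥ 0.97`; otherwise a provisional quadratic whose smaller real root
   is the provisional threshold. Linear fits yield the lower temperature
   threshold `LTT = −a/b` (with approximate SE) and thermal constant
   `K = 1/b` in degree-hours/degree-days.
4. **Individually-resolved stages** (larva, pupa, teneral adult, adult
   mass) — heteroskedastic GLS with a distinct residual variance per
   temperature-by-sex stratum (REML, profiled variances) and sequential
   type-I F-tests; median/quartile stage summaries.
5. **Scaling diagnostics** — stage proportions of a reference span,
   span ratios, and the spread of per-stage thresholds as a descriptive
   rate-isomorphy diagnostic.
6. **Cohort simulator** — synthetic destructive samples and individual
   records under known thermal laws (lognormal individual variation,
   optional shared slow/fast factor, 20-min oviposition window, binomial
   observation), used throughout the tests for parameter recovery.

The published summary tables of the beetle study are included as
machine-readable fixtures (`cmac_transition_times()`,
`cmac_stage_durations()`, `cmac_individual_summaries()`,
`cmac_rate_coefficients()`, `cmac_quadratic_coefficients()`).

## Worked example

Refit the germ-band-extension reaction norm from the packaged stage
durations:

```r
library(stagetherm)
d <- subset(cmac_stage_durations(), stage == "germ_band_extension")
rates <- rates_from_durations(d$duration_h, "per_hour")
fit <- fit_linear_norm(d$temp_c, rates, "per_hour")
print(fit)
#> Thermal reaction norm (per hour rates)
#>   R = -0.20878 + 0.012504 * T   (R2 = 0.978, N = 5)
#>   LTT = 16.7 degC (SE 0.9), K = 3.3 degree-days
```

The stage needs 3.3 degree-days (80 degree-hours) above a lower threshold
of 16.7 °C; the regression explains 97.8% of the rate variation across the
five chamber temperatures. Closed forms from published coefficients:

```r
co <- cmac_rate_coefficients()
pupa <- co[which(co$stage == "pupa"), ]
ltt(pupa$a, pupa$b)                                    # 12.4 degC
thermal_constant(pupa$b, "per_day")[["degree_days"]]   # 77.2 degree-days
```

And an end-to-end run on simulated data with known ground truth:

```r
cfg <- default_sim_config(cv = 0.05)
sim <- simulate_cohort(cfg, seed = 42)
rep <- run_pipeline(samples = sim$samples, records = sim$individuals)
rep$norm_table[1:5, c("stage", "model", "ltt_c", "k_dd", "r2")]
#>                  stage  model ltt_c   k_dd     r2
#> 1      early_cleavages linear 15.25  2.865 0.9999
#> 2       late_cleavages linear 11.50  6.825 0.9994
#> 3  germ_band_extension linear 16.55  3.383 0.9986
#> 4 germ_band_retraction linear 14.83 11.944 0.9999
#> 5       dorsal_closure linear 13.55 14.957 0.9995
```

Estimated thresholds recover the configured stage laws to a few tenths of
a degree at this noise level (CV 0.05, 50 eggs per sample).

A thin command-line wrapper over these functions lives at
`inst/scripts/stagetherm-cli.R` (subcommands `simulate`,
`fit-transitions`, `fit-norms`, `fit-individuals`, `report`, `all`).

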
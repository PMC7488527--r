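---
title: "Methods: stagewise thermal development analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stagewise thermal development analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagetherm)
```

## The problem

Holometabolous insects develop through a fixed sequence of stages whose
durations shrink as temperature rises. For a cryptic species such as the
cowpea seed beetle *Callosobruchus maculatus*, whose embryos and young
larvae cannot be observed alive, stage timing must be inferred from
*destructive sampling*: cohorts of same-age eggs are sacrificed at
scheduled ages and each individual is staged, yielding, per sample, a count
of individuals at or past each stage boundary. `stagetherm` implements the
full inferential chain from such counts (and from individually-resolved
rearing records for the stages that can be followed through a window cut in
the seed coat) to stage-specific thermal reaction norms, lower temperature
thresholds and degree-day constants, plus a cohort simulator that generates
data with exactly the statistical structure the chain assumes.

## Estimating median transition times

For one stage boundary at one temperature, the proportion of individuals
past the boundary rises from 0 to 1 with cohort age. We model each sample
as a binomial observation with its own size $n$ and fit

$$\operatorname{logit} P(\text{past at age } t) = \beta_0 + \beta_1 t,$$

reporting the median transition time $t_{50} = -\beta_0/\beta_1$, the age
at which the fitted proportion is exactly one half. Whether samples should
be weighted by their $n$ is a modelling choice; treating each sample as a
binomial draw is the faithful likelihood for count data and is the default
here.

Rapid, synchronous transitions produce *complete or quasi-complete
separation*: samples jump from all-zero to all-one with no intermediate
proportions, and the maximum-likelihood estimates diverge. We therefore
provide a Firth-type bias-reduced estimator that maximizes the
Jeffreys-prior penalized likelihood
$\ell(\beta) + \tfrac12 \log \det I(\beta)$, which is guaranteed finite
under separation. `fit_transition(method = "auto")` uses plain ML and falls
back to the penalized fit when separation is detected, mirroring the
practice of using penalized fits for the fast early-embryonic transitions
and ML for the slower, better-interleaved later ones.

Numerical choices:

* Ages are centred and scaled internally; coefficients are reported on the
  hour scale. Both estimators are location/scale equivariant, so this is
  purely numerical.
* IRLS with ascent-only step-halving, converged when the (penalized) score
  norm falls below `1e-8`, capped at 100 iterations. When Newton stalls —
  which happens when nearly all weight sits on one or two samples — the
  same objective is polished by quasi-Newton restarts before the fit is
  declared non-converged; non-convergence is always surfaced, never
  silent.
* Separation is declared when a standardized coefficient exceeds 25 (the
  bound is configurable) while the score has not vanished.
* Replicate samples whose ages agree after rounding to the nearest hour
  are pooled by summing counts (`pool_replicates()`); a sample alone in its
  hour keeps its exact age, so sub-hour designs lose no resolution.

## From transitions to reaction norms

Median durations are differences of consecutive median transition times
(the first stage's duration is its transition time), so durations sum
exactly to the final transition time; non-monotone inputs are rejected
naming the offending pair. Durations convert to rates $R = 1/D$, with
per-hour rates for the destructively sampled (embryonic and early larval)
stages and per-day rates for the individually reared stages. Mixed units
are easy to confuse in this literature, so every fit carries an explicit
`rate_unit` tag; the lower threshold is unit-invariant and the thermal
constant converts as degree-days = degree-hours / 24.

Within the permissive range the rate is modelled linearly,
$R = a + bT$, giving the lower temperature threshold
$\mathrm{LTT} = -a/b$ and thermal constant $K = 1/b$. A fit is accepted as
linear when $R^2 \ge 0.97$ (the gate is configurable); below the gate the
response is treated as markedly nonlinear and provisionally fitted with a
quadratic, whose *smaller* real root (the crossing below the vertex) plays
the role of the provisional threshold, with "no crossing" reported when
the discriminant is negative. Actual chamber temperatures (e.g. 19.8 °C,
not the 20 °C set point) are the regression covariates; set-point labels
are kept for reporting, and the two chamber blocks used for pre- and
post-dorsal-closure stages are kept distinct.

The standard error of the LTT is approximate at best with one rate value
per temperature. Three estimators are provided: the classical
approximation $\mathrm{SE} = (\bar R/b)\sqrt{s^2/(N\bar R^2) +
(\mathrm{SE}_b/b)^2}$, the first-order delta method on $-a/b$ with the
full coefficient covariance, and a parametric residual bootstrap. All are
unit-invariant. The published per-stage SEs cannot be reproduced exactly
from the printed summary tables, so no SE estimator is privileged; the
choice is an argument (`se_method`), defaulting to the classical form.

## Individually-resolved stages

Larval, pupal and teneral durations and adult mass come as one record per
individual. Rates are per-individual reciprocal durations (per day).
Because variance differs strongly among rearing temperatures and between
sexes, the linear model

$$y = \mu + \beta_T (T - \bar T) + \beta_S s + \beta_{TS} (T-\bar T)s$$

(with $s = \pm\tfrac12$ for females/males) is fitted by generalized least
squares with a distinct residual variance per temperature-by-sex stratum,
estimated by REML. Estimation profiles the variances: given stratum
variances, coefficients solve weighted least squares; each stratum
variance is then updated as its residual sum of squares divided by its
REML-adjusted degrees of freedom (stratum size minus accumulated
leverage), iterating to a relative tolerance of `1e-8`. The same model
fitted by `nlme::gls(weights = varIdent(...))` is used as an independent
cross-check in the test suite. Term significance uses sequential (type I)
F-tests in the order temperature, sex, interaction, comparing nested
weighted residual sums of squares with the final weights held fixed;
denominator degrees of freedom are $N$ minus the number of coefficients
(574 individuals give 570). The sex coding only affects the sign of the
sex coefficient, not the F-tests.

Stage summaries are medians with lower/upper quartiles; the quantile
convention is linear interpolation (type 7) by default and configurable,
since the convention behind the published quartiles is unstated. Records
flagged as overlooked or discarded are excluded with a reported count;
early-emerging teneral outliers are retained by default.

## The cohort simulator

`simulate_cohort()` draws data under known ground truth so that every
downstream estimate can be checked for parameter recovery:

* each stage has a thermal law (linear $a + bT$, or quadratic for the two
  sclerotization-dominated stages) defining the median duration
  $D(T) = 1/R(T)$, validated to be finite and positive at every configured
  temperature;
* individual stage durations are $D(T)\,e^{\varepsilon}e^{\eta}$ with
  $\varepsilon \sim N(0, \sigma)$ from a per-stage CV (default 0.08, a
  calibration choice — the source data do not state within-cohort
  variance) and a shared per-individual factor $\eta$ (default SD 0)
  modelling persistently slow or fast individuals, which destructive
  sampling cannot measure but which is biologically plausible;
* oviposition is jittered uniformly over a 20-minute collection window,
  with sample ages referenced to the window midpoint (the least-biased
  convention when only the window is known);
* each scheduled sample is an independent cohort; `n_past` counts
  individuals whose cumulative transition time has passed at fixation;
* individually reared stages yield per-individual records with sex drawn
  at a configurable ratio, an optional sex-by-temperature rate contrast
  (acting on centred temperature, so it is a pure interaction), and adult
  mass from sex-specific quadratic means — females heavier, declining with
  temperature; males lighter with a more curvilinear response — plus
  Gaussian noise (default SD 0.6 mg).

`default_sim_config()` ties the ground truth to the published stage
durations (stage laws are OLS refits of the printed duration table), and
`transition_schedule()` mirrors the study's strategy of sampling each
transition window densely (nine ages spanning ±4 transition-time SDs by
default). The simulator deliberately omits mortality, infertile eggs, the
'active form' polyphenism and within-seed competition: passing recovery
tests therefore demonstrates correctness of the inferential chain under
its own assumptions, not robustness to those real-data complications.

Determinism: one integer seed fixes all output bitwise within a package
version; cross-language bit equality is not promised.

## Scaling diagnostics

`stage_proportions()` expresses stage durations as fractions of a
reference span (proportions of a fully partitioned span sum to 1),
`span_ratio()` compares two spans per regime (e.g. post- vs
pre-dorsal-closure development), and `ltt_spread()` summarizes per-stage
thresholds, flagging a range below 1 °C (configurable) as compatible with
developmental rate isomorphy. These are descriptive: the package performs
no formal regression-of-proportions isomorphy test, which requires
individually-resolved data unavailable for embryonic stages. The
pupa-to-feeding ratio is reported both as a ratio of stage medians and as
a median of per-individual ratios, because the two differ and the
published sequence is consistent with neither definition applied to the
printed medians alone.

## Problem sizes and test design

The test suite checks estimator contracts against independent oracles: a
derivative-free nested grid-refinement maximizer of the (penalized)
binomial likelihood, `stats::glm` for plain ML, closed-form normal
equations for OLS, brute-force nested weighted RSS for sequential F, and
`nlme::gls` for the REML variance model. Stochastic properties use fixed
seeds with sizes chosen to keep the default run within a few minutes:
threshold recovery uses 20 simulated cohorts (five temperatures, 50 eggs
per sample, CV 0.05; each stage's threshold recovered within 0.5 °C in the
median), variance-ratio recovery uses 500 observations per stratum over 20
seeds, and the interaction F-test's type-I error is checked over 500 null
replicates of 30 observations per stratum.

## Known limitations

* Each transition is fitted marginally; no joint multinomial or
  continuation-ratio model across stages, and no random effects.
* The quadratic reaction norm is a provisional description, not a
  biophysical model (no Sharpe–Schoolfield or Brière forms).
* LTT standard errors are approximations whose sampling properties with
  one rate per temperature are poorly characterized; treat comparisons
  across stages with caution.
* With one rate value per temperature the linearity gate cannot
  distinguish curvature from noise at 32 °C; the linear model is retained
  for gated stages by design.
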
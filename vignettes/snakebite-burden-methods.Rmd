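---
title: "Methods: estimating snakebite mortality and burden from verbal-autopsy surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating snakebite mortality and burden from verbal-autopsy surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakeburden)
library(dplyr)
```

# The problem

India carries roughly half of the world's snakebite deaths, yet most of
those deaths happen at home, outside any facility-based reporting system.
The only nationally representative window on them is verbal-autopsy
surveillance in the style of the Million Death Study (MDS): trained field
staff interview households about each death in a large sample of small
areas (Sample Registration System sampling units), and two independent
physicians assign an ICD-10 cause to every record. `snakeburden` implements
the full analytical chain that turns such records into national burden
estimates:

1. **Inclusion rules and plausible ranges** from dual-coder agreement
   (`classify_records()`, `coding_bounds()`).
2. **Cause fractions to death totals**: sampling-weighted snakebite
   fractions, three-year backward moving averages, interpolation of empty
   strata, and scaling to an external all-cause death envelope
   (`weighted_fractions()`, `moving_average()`,
   `interpolate_zero_strata()`, `scale_to_envelope()`).
3. **Rates and cumulative risk**: age-standardized rates against a fixed
   standard population and the additive risk of dying of snakebite before
   age 70 (`age_standardize()`, `risk_before_70()`), with cubic-spline
   trend projection outside the observation window (`spline_trend()`) and
   in/out-of-hospital splits (`hospital_split()`).
4. **Seasonality and altitude**: a harmonic Poisson model of daily deaths
   on a composite year (`fit_seasonal()`, `monsoon_share()`) and crude
   rates by 100 m altitude bin (`altitude_profile()`).
5. **Spatial risk**: a Bayesian Poisson model of national age-sex rates
   (`fit_national_rates()`), a geostatistical relative-risk model with a
   Matern spatial field (`fit_geostatistical_rr()`), grid prediction
   (`predict_rr_grid()`), conversion to absolute risk before 70
   (`absolute_risk()`), and population-at-risk tabulation
   (`population_at_risk()`).
6. **Indirect prevalence**: a through-origin regression of study deaths on
   study bites for the case-fatality rate (`estimate_cfr()`), and
   scenario-based back-calculation of national bites and envenomations
   (`total_bites()`, `partition_envenomation()`).
7. **Surveillance coverage**: officially reported hospital deaths against
   model-estimated in-hospital deaths (`coverage_table()`).

Because unit-record MDS data cannot be redistributed, the package ships a
first-class synthetic-data generator that emulates the survey's structure
with a known ground truth, so every stage has a recovery test.

# Models

## Dual-coder inclusion and plausible ranges

A record is an immediate snakebite agreement when both physicians coded
X20. A record is a review candidate when at least one coder gave X20, X27
or X29 without dual X20 agreement; candidates are resolved by an explicit
review table (in synthetic pipelines, the generator's true cause). The
plausible range is: lower = immediate agreements; central = lower plus
review-confirmed candidates; upper = every record with at least one X20
code plus review-confirmed X27/X29-only candidates. The published wording
is ambiguous about whether X29-only records belong in the upper bound, so
`coding_bounds(include_x29_only = TRUE)` provides the wider reading (all
X27/X29-only candidates). Review decisions are an input, not a model: the
original review used narrative symptom keywords that no reimplementation
can reproduce, and modelling them would invent an NLP stage.

## Cause fractions and envelope scaling

Sampling weights enter as record-level multipliers. The moving average
smooths the weighted *numerator and denominator separately* (default equal
lag weights (1,1,1)/3) and recomputes the ratio; smoothing counts rather
than ratios keeps envelope conservation exact, and edge years renormalize
over the available shorter window so the first year of a sampling frame is
its own value. Strata-years with no observed deaths are interpolated
linearly along year within the stratum, carrying the nearest observed
value at the edges; this is one standard choice among several the source
material leaves open. Scaling multiplies each stratum's fraction by the
envelope total for that stratum; by construction, fractions that partition
all causes reproduce the envelope exactly.

## Risk before age 70

With 5-year band rates $r_b$ (per 100,000 per year) for the 14 bands
covering ages 0-69,

$$\text{risk}(\%) = 100 \times \sum_{b=1}^{14} \frac{5\, r_b}{100000}.$$

This is the additive approximation (no $1 - \exp(-\Sigma)$ survival
correction), used deliberately because the published quantity was computed
by summation; at snakebite magnitudes (risk ~0.4%) the difference is below
0.001 percentage points.

```{r}
risk_before_70(rep(5, 14))
```

## Spline trends

`spline_trend()` fits a cubic B-spline with 3 interior knots at year
quantiles (the smallest default that can bend twice over a 12-year
series; configurable) and extrapolates linearly, continuing the fitted
curve's slope at the data boundary. The unconstrained cubic basis
reproduces any cubic polynomial exactly; linear extrapolation is
deliberately conservative for out-of-window projection.

## Seasonality

Death dates pool across years into a composite 365-day year (Feb 29 folds
into Feb 28). Daily counts are modelled as Poisson with log link on
sine/cosine pairs of the day of year; two harmonics by default, because a
single-peaked but asymmetric annual curve is not representable with one.
With an intercept and the canonical link the fitted curve sums exactly to
the observed total. Peak and trough days are the argmax/argmin of the
fitted curve; a curve whose max/min ratio is below 1.01 is reported as
flat with undefined peak (the degenerate-input tie-break).

## Spatial models

The national model is Poisson with log person-years offset, one free
parameter per age-sex cell (no global intercept) and a linear time trend
centred at 2010, so cell effects are reference-year log rates. The
geostatistical model compares observed unit deaths $y_i$ with expected
deaths $E_i$ from the national rates:

$$y_i \sim \mathrm{Poisson}(E_i\, \lambda_i), \qquad
\log \lambda_i = x_i^\top \beta + w(s_i) + u_i,$$

with covariates (urban/rural, female illiteracy in rural units only,
altitude, long-term mean temperature), a Matern spatial field $w$
(smoothness fixed at 1, standard and well-behaved in 2D disease mapping)
and an iid unit effect $u_i$. The field uses a reduced-rank representation
on a regular knot grid (default 8 x 8) with bilinear interpolation, which
keeps the latent dimension manageable at thousands of units.

Inference is empirical-Bayes Laplace, written for this package: a damped
Newton solver finds the joint posterior mode of $(\beta, z, u)$ given the
hyperparameters; the hyperparameters (field SD, range, unit SD) maximize
the Laplace-approximate marginal posterior under weak priors (exponential
on the SDs, lognormal on the range centred at a quarter of the domain
diagonal); latent posteriors are the Gaussian approximation at the mode.
This is the fast approximate mode of standard disease-mapping practice
(the same Laplace strategy INLA-style tools use); posterior summaries are
therefore approximate, and the null-truth calibration test (fraction of
95% intervals excluding RR = 1 at most 7.5%) guards against
overconfidence. Hyperparameters are point-estimated, so recovery tests
check them to order of magnitude and check the latent field by
correlation with truth.

Grid predictions use covariates and the spatial field only; unit-level iid
effects are survey-unit noise, not attributes of place. Absolute risk is
the relative-risk surface times the national risk before 70, so ratios of
absolute risks equal ratios of relative risks by construction, and
population at risk demands exactly co-registered grids (no silent
resampling).

## Case fatality and indirect prevalence

The case-fatality rate is the slope of ordinary least squares of study
deaths on study bites **through the origin**: a study with zero bites must
imply zero deaths. A free-intercept variant sits behind a flag. Outliers
are removed in one pass at |standardized residual| > 3; both the rule and
the threshold are configurable because the source analysis states only
that extreme outliers were removed. Bites back-calculate as hospital
deaths / CFR, and scenario rows (hospital deaths, CFR, out:in ratio,
envenomation share) make every assumption explicit and auditable:

```{r}
total_bites(default_prevalence_scenarios()) |>
  select(scenario, total_bites, envenomations)
```

The shipped scenarios are labelled illustrative: the exact out-of-hospital
assumptions behind published ranges are not reproducible from public text,
so the scenario grid is the user's responsibility.

# The synthetic world

`sim_config()` fixes the generative conditions; the defaults are the study
conditions, chosen once:

| parameter | default | why |
|---|---|---|
| `base_rate` | 4.8 /100k person-years | the observed standardized national rate |
| age pattern | 4.5 / 3.1 / 5.8 / 5.0 by broad band | observed broad-band rates, normalized so the standardized rate equals `base_rate` |
| `coder_agreement` | 0.92 | observed immediate dual-coder agreement |
| `seasonal_amplitude` | 0.663 | log-scale sinusoid giving the observed peak/trough ratio exp(2 x 0.663) = 3.77 |
| `seasonal_peak_day` | 196 (mid-July) | observed monsoon peak; implies ~0.51 of deaths in June-September |
| `hospital_fraction` | 0.23 | 77% of snakebite deaths occur out of hospital |
| `rural_share` | 0.75 with rural log-RR +1.65 | produces ~94% of snakebite deaths in rural areas |
| `other_death_rate` | 7.5 /1,000 | India-like all-cause crude death rate |
| altitude | lognormal, median 150 m | ~84% of units below 400 m; effect -0.0014 /m gives lower risk at altitude |

The spatial truth is a Matern (smoothness 1) Gaussian field sampled on a
coarse grid and interpolated to units, centred so the population-weighted
mean relative risk is exactly 1; covariate multipliers are centred the
same way, so the configured base rate *is* the national rate. The seasonal
truth is a single annual sinusoid on the log scale (the observed curve has
one annual peak and trough). Coder 1 always codes a true snakebite death
X20; coder 2 agrees with probability `coder_agreement`, otherwise codes
X27 or X29. Non-snakebite deaths use a small fixed ICD-10 list — only
their count matters downstream. Sampling weights are a config input
(`sampling_weights`), not an asserted scheme, because the survey's weight
distribution across strata is not public.

What the generator does **not** emulate: real administrative boundaries
and the real risk map; narrative verbal-autopsy text and physician
behaviour beyond the two-code agreement; weather-driven year-to-year
seasonal variation (season is purely calendrical); migration and
demographic change within the observation window; misclassification of
non-snakebite deaths *into* the candidate codes. Passing recovery tests
therefore demonstrate internal consistency of the estimators under the
stated generative assumptions, not robustness to the full messiness of
field data.

# Numerical choices and degenerate inputs

* Newton iterations cap the linear predictor at 30 on the log scale to
  avoid overflow, damp by step halving, and add 1e-6 ridge only if a
  Hessian Cholesky fails.
* Matern covariance matrices get a 1e-8 (simulation) / 1e-6 (inference)
  diagonal jitter.
* Hyperparameter search is Nelder-Mead on log scales, warm-starting the
  inner Newton from the previous mode.
* Empty record sets give all-zero bounds with an `NA` agreement fraction;
  all-zero daily counts, all-excluded study tables, and fewer years than
  knots + 4 raise typed errors rather than degenerate fits.
* Rates tables report one decimal and national totals round to the nearest
  thousand only in report/table modes; internal computation is full
  precision.

# Problem sizes used by the test-suite

The packaged tests exercise the estimators at sizes chosen to balance
Monte-Carlo error against runtime on a single CPU: recovery of national
totals, the standardized rate and risk-70 uses a world with ~10,000
snakebite deaths (500 units); seasonality recovery uses ~58,000 deaths per
year (the estimated national scale); spatial calibration and cluster
detection use a 500-unit fixture with ~1,200 deaths; the end-to-end smoke
test runs 200 units. The full suite completes in a few minutes.

# Limitations

* Posterior summaries are Laplace approximations; heavier-tailed
  posteriors (few deaths, strong fields) will be summarized
  optimistically. The calibration test bounds, but does not eliminate,
  this.
* The reduced-rank field cannot represent variation finer than the knot
  spacing; planted-cluster detection works because clusters span several
  knots.
* The moving average, interpolation and envelope conventions are one
  admissible reading of briefly described methods; all are configurable.
* Scenario-based prevalence is arithmetic on explicit assumptions, not
  inference; its ranges are only as good as the scenario grid.
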
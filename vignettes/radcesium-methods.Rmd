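---
title: "Modelling radiocesium time courses in wild boar and black bear: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiocesium time courses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcesium)
```

## The model

After a large release of radiocesium, the activity concentration measured
in the tissues of wide-ranging omnivores such as wild boar (*Sus scrofa*)
and Asian black bear (*Ursus thibetanus*) reflects three superimposed
processes: physical decay of the two isotopes deposited on the landscape,
a slower "ecological" loss of bioavailable cesium (downward migration in
soil, decontamination work, run-off), and a seasonal cycle of intake driven
by diet (soil-associated foods and fungi in the cold months push burdens
up; green vegetation in summer pulls them down).  `radcesium` models the
natural log of the decay-corrected total radiocesium burden at collection
time $T$ (years since the accident) as

$$
\mathrm{LnCs}_c \;=\; X(T) + Q - \mu\,T^{\nu}
  + A \sin\!\bigl[2\pi (T + P)\bigr] + \varepsilon ,
$$

with the environment term

$$
X(T) \;=\; \ln\!\Bigl[ e^{L_{134}}\, 2^{-T/T_{h,134}}
  + e^{L_{137}}\, 2^{-T/T_{h,137}} \Bigr]
$$

describing pure physical decay of the 134/137 mixture from its ln-scale
intercepts $L_{134}, L_{137}$ at $T = 0$.

Parameters, units, and defaults:

| parameter | units | meaning |
|---|---|---|
| $Q$ | ln[m²/Bq] | ties tissue burden (Bq/kg) to environmental deposition (Bq/m²) |
| $\mu$ | 1/years | net ecological loss rate; ecological half-life $= \ln 2/\mu$ |
| $\nu$ | — | power of the loss-time dependence; $\nu = 1$ (exponential) is the default, bounded to $[0.1, 10]$ when free |
| $A$ | ln(Bq/kg) | seasonal amplitude, canonical form $A \ge 0$ |
| $P$ | years | seasonal phase, canonical range $[0, 1)$; burden peaks at $(0.25 - P) \bmod 1$ of the year |

Physical half-lives default to 2.0652 y (¹³⁴Cs) and 30.08 y (¹³⁷Cs)
(standard nuclide data), the accident date to 2011-03-11, and the
at-release 134:137 activity ratio to 1; all are configurable through
`isotope_constants()`.

Because $A\sin[2\pi(T+P)] = a\sin 2\pi T + b\cos 2\pi T$ with
$a = A\cos 2\pi P$, $b = A\sin 2\pi P$, the model is **linear** in
$(Q, \mu, a, b)$ once $\nu$ is fixed.  Every estimator in the package
exploits this: the nonlinear multi-start search is always accompanied (and
checked) by a closed-form linearised solve, and free $\nu$ is profiled —
an outer one-dimensional search over $\nu$ with an inner linear solve.
Reported $(A, P)$ and their standard errors come from the $(a, b)$ scale
by the delta method; when $A \approx 0$ the phase is unidentifiable and
its standard error is reported as `NA`.

## Data ingestion and decay correction

`read_samples()` accepts an analysis-ready layout (species, $T$, district,
municipality, $\mathrm{LnCs}_c$) and a raw layout with collection and
measurement dates plus per-isotope activities.  Calendar dates convert to
$T$ at exactly 365.25 days/year.  Records with missing fields or
below-detection flags are excluded and counted — detection-limit values
are dropped, not imputed, matching common practice for these monitoring
data; a censoring-aware likelihood is out of scope.  Unknown species
labels reject the row with a warning; ambiguous dates are an error, never
guessed.

Between collection and measurement each isotope decays physically, so the
reported total is back-corrected by $2^{+\Delta/T_h}$ per isotope
(`correct_decay()`).  When per-isotope activities are present they are
used directly; otherwise the 134:137 split at the measurement date is
inferred from the release ratio decayed since the accident.  Both paths
are exposed and selectable (`composition=`) because monitoring exports
differ in what they carry; when both are possible the per-isotope path
takes precedence.  The round trip forward-decay → correction is exact to
better than $10^{-10}$ relative, which the test suite asserts over
randomised mixtures and delays up to five years.

Isotope intercepts for the environment term are estimated per species by
robust (Huber) straight-line regression of ln activity on $T$
(`estimate_isotope_intercepts()`); pooling across species is possible by
concatenating records, but per-species estimation is the default since
accumulation differs between boar and bear.

## Estimation methods

**Multi-start least squares** (`fit_ols()`): the sum of squared residuals
is minimised from initial values obtained by perturbing the linearised
solution multiplicatively with $N(1, 0.1^2)$ noise per parameter; the
restart with the lowest RMSE wins.  For fixed $\nu$ the problem is convex
and restarts agree with the closed form to $10^{-6}$ (asserted); for free
$\nu$ the profile is additionally seeded from a 25-point grid over
$[0.1, 10]$.  The default of 200 restarts is far more than the convex case
needs; the study-scale profile used 2000 and remains configurable.

**Robust M-regression** (`fit_robust()`): iteratively reweighted least
squares with a MAD residual scale and Huber weights (tuning 1.345;
bisquare 4.685 available).  Among restarts the winner is the solution with
the smallest absolute median residual.  Standard errors use the standard
M-estimation asymptotic variance with the finite-sample correction factor
— the same formulas `MASS::rlm` reports, and the two agree on the
linearised design (asserted in the tests).  Robustness weights are
emitted per record; their exact values depend on the chosen $\psi$, so
they are reported but not treated as reference quantities.

**Quantile regression** (`fit_quantile()`): the pinball loss
$\rho_\tau(r) = r(\tau - \mathbf 1[r<0])$ is minimised by an IRLS scheme
(weights $|\tau - \mathbf 1[r<0]|/\max(|r|,\epsilon)$, floor
$\epsilon = 10^{-6}\,\mathrm{mad}(r)$) polished by Nelder–Mead on the
exact loss.  Initial values come from the robust fit.  Standard errors are
by case-resampling bootstrap (default 500 resamples, seeded); bootstrap
phases are unwrapped around the point estimate before taking standard
deviations so that draws near the $[0,1)$ boundary do not inflate them.
The 25th/50th/75th percentiles are the intended targets; more extreme
percentiles are data-starved in this setting.  AIC is not defined for
pinball fits and is reported as `NA`.

**Mixed effects** (`fit_mixed()`): the $\nu=1$ linearised model is fitted
by maximum likelihood with `nlme::lme` — ML rather than REML so that
structure comparisons by likelihood are valid.  Random effects (diagonal
covariance) go on any subset of $\{Q, \mu, \text{seasonal}\}$, grouped by
district or by municipality within district; the seasonal pair is random
on the $(a,b)$ scale and its $(A,P)$ random SDs are delta-method
projections, declared as an approximation in the output.  Residual
variances may differ by district (`varIdent`), motivated by the
Fligner–Killeen test (`variance_homogeneity_test()`).  Outliers are
pre-filtered by robust Mahalanobis distance on $(T, \mathrm{LnCs}_c)$
using the MCD covariance at the $\chi^2_{2,0.975}$ cutoff
(`detect_outliers()`), or by a verbatim exclusion list; performance
metrics ($R^2$, RMSE) are evaluated on the **unfiltered** records, with
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ on the ln burden scale including
predicted random effects — this definition is frozen in the tests.

**Variant comparison**: `compare_variants()` uses
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ with $k$ counting the mean
parameters plus the residual scale.  The additive constant is fixed and
documented so that only deltas — the quantity actually used — matter.

## Derived summaries

The ecological half-life is $\ln 2/\mu$ with the Wald interval mapped
through the transform; whenever $\mu - 1.96\,\mathrm{se} \le 0$ the upper
bound is $\infty$, and a non-positive $\mu$ gives an infinite point
estimate.  Seasonal summaries report `exp(A)` (the multiplicative
excursion from the seasonal mean at peak) with a delta-method CI, the
phase in months ($12P$), and the peak-to-trough fold change `exp(2A)`.
Both fold metrics are emitted and labelled because either can be meant by
"amplitude" on the linear scale; no choice is silently made.

## Extrapolation scoring

`split_records()` halves the data at the median of $T$ (early/late), or
at random with a seed.  The median rule is the package's choice of
threshold: it yields an approximately equal split without reference to
any particular dataset.  `score_extrapolation()` fits the estimator to
the training half and to everything, evaluates both on the held-out late
half, and reports the RMSE ratio; a well-specified model should score
near 1.  Parameter train/full ratios carry first-order propagated
standard errors that assume independent fits — an approximation (the fits
share the training records) that is flagged in the output.

## Zone/year summary analysis (multimodel inference)

For summary tables (animals per zone and year with mean/min/max burdens),
the land-adjusted mean `ln_mean_cs_c` is modelled by weighted least
squares with weights $n/(\ln\max - \ln\min)^2$, normalised to mean 1 —
approximately inverse-variance.  All formulas over
$\{\mathrm{Time}, \mathrm{Zone}, \mathrm{Time{:}Zone}\}$ respecting
marginality are ranked by $\mathrm{AICc} = \mathrm{AIC} +
2k(k+1)/(n-k-1)$, and `mmi_average()` performs full-model-set averaging
(absent terms contribute zero; conditional averaging by flag) with
Burnham–Anderson unconditional variances and per-term importance.  The
zone factor keeps the most contaminated (Alienation) zone as reference so
that coefficients read as "units higher".

Sign convention: burdens that decline give a negative Time slope; the
ecological decline rate is defined as the **negative** of that slope, so
it is positive under decline and the half-life $\ln 2/\mathrm{rate}$ is
reported with an infinite bound whenever the rate's interval reaches
zero.  Because full-model-set averaging shrinks the averaged slope toward
zero when support is split, the averaged half-life can be much longer
than the best single model's; both are computed and labelled.

A calibration caveat worth knowing: the summary weights are only
*approximately* inverse-variance (the ln range of a cell grows with the
cell's size), so model-based standard errors from the weighted fit tend
to under-cover relative to nominal.  The package reports them as the
method defines them; simulation checks in the test suite document the
achieved coverage rather than asserting nominal coverage.

## The synthetic generator

`generate_fukushima()` emulates the structural features of the
monitoring data: log-normal burdens spanning orders of magnitude,
district and nested municipality random effects on any model parameter,
per-district residual SDs, sinusoidal seasonality, a two-isotope activity
split consistent with the environment term, measurement delays,
below-detection censoring on the linear scale, and a configurable
fraction of gross outliers.  Defaults are the study-scale boar
conditions: $n = 1404$ records over $T \in [0.20, 7.03]$ years, truth
$(Q, \mu, A, P) = (-4.851, 0.173, 0.641, 0.405)$ with $\nu = 1$, unit
ln-scale noise in each of 7 districts, no location random effects and no
outliers unless switched on.  Where the conditions are not pinned down by
the study design, the package fixes realistic values once: sampling times
uniform over the window (an optional seasonal hunting-intensity weight is
available but off by default), measurement delays uniform over 4–55
days, a 10 Bq/kg reporting limit (which censors essentially nothing at
these contamination levels, mirroring the ~1–3% loss in real exports),
outlier shifts $N(0, 8^2)$ on the ln scale — the same "8 robust SDs"
magnitude used for the planted-outlier detection checks — and equal
isotope intercepts $\ln 10^6$ Bq/m², a heavily contaminated area with
the at-release activity ratio of 1.

`generate_chernobyl()` produces zone/year summary tables from per-animal
lognormal draws whose mean follows the zone's decayed land contamination
plus a zone offset and a linear ecological decline; cell sizes are fixed
or shifted-Poisson.  Ground truth (slope, offsets) is returned alongside.

What the generator does **not** emulate: real spatial contamination
patterns (districts are exchangeable labels), diet-driven mechanisms
behind the seasonal cycle (the sine is the data-generating truth, not an
approximation), age/sex structure, measurement error on the activity
scale, or informative censoring.  Passing tests therefore demonstrate
that the estimators recover the model they assume under realistic noise,
hierarchy and contamination — not that the model is a correct description
of any particular field dataset.

## Numerical choices

* $\nu$ is bounded to $[0.1, 10]$; the lower bound keeps the loss term
  identifiable, the upper is a conditioning choice.
* IRLS scale: MAD about the median, floored at
  $10^{-8}(\mathrm{sd}(y)+10^{-12})$ to survive exact fits; IRLS weights
  floored at $10^{-10}$ so the weighted solve stays full rank.
* Convergence: relative coefficient change below $10^{-9}$ (robust) /
  $10^{-10}$ (quantile); non-convergence within the iteration cap is
  flagged on the result and the best iterate returned.
* Exact-line data short-circuit the robust isotope-intercept fit to least
  squares (M-estimation has no scale to iterate on there).
* Ties in restart selection keep the first winner; seeds are mandatory
  arguments wherever randomness enters, and generators restore the global
  RNG state.
* Problem sizes in the tests and the acceptance script are the package's
  own verification profile: 50 oracle fixtures, 200 coverage replicates at
  $n = 1404$, 100 contamination replicates, 500 decay round trips, 50+15
  extrapolation seeds, 100 summary-table seeds — each criterion runs in
  seconds on one CPU.

## Interface

The package's interface is its exported functions — the `run_*` drivers
tie ingestion, fitting, extrapolation and the summary-table arm together
and write CSV/JSON tables when given an output directory — plus
`scripts/acceptance.R`, which recomputes the headline quantities from
scratch.  No shell CLI is shipped; the drivers are the scriptable entry
points.

## Known limitations

* Fixed one-year period, single harmonic; no time-varying amplitude.
* No censoring-aware likelihood for below-detection records.
* Quantile standard errors are bootstrap-only; no rank-inversion
  intervals.
* Mixed-effects random effects use diagonal covariances; no crossed
  effects or spatial correlation.
* Parameter-ratio standard errors in extrapolation scoring assume
  independent train/full fits.
* The summary-table weights are approximate inverse-variance; their
  coverage properties are documented, not corrected.
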
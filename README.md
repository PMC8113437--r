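# radcesium

Time-course modelling of radioactive cesium (¹³⁴Cs + ¹³⁷Cs) burdens in
large omnivorous wild mammals — wild boar (*Sus scrofa*) and Asian black
bear (*Ursus thibetanus*) — after a nuclear accident.

After the Fukushima and Chernobyl releases, tissue burdens in these game
species varied by orders of magnitude between individuals, oscillated with
the seasons (soil-associated foods and fungi raise intake in the cold
months), and declined over the years through a mixture of physical decay
and slower "ecological" loss (cesium migrating into deeper soil, run-off,
decontamination).  Quantifying those components matters both for wildlife
radioecology and for assessing human exposure through game meat.  This
package is for radioecologists and biostatisticians who want to fit,
check, and stress-test that decomposition on monitoring records.

## The model

The natural log of the decay-corrected total radiocesium concentration at
collection time *T* (years since the accident) is modelled as

    LnCs_c = X(T) + Q − μ·T^ν + A·sin[2π(T + P)] + ε
    X(T)   = ln[ exp(L134)·2^(−T/Th134) + exp(L137)·2^(−T/Th137) ]

where `X(T)` is the physically decaying two-isotope environment term
(half-lives 2.0652 y and 30.08 y), `Q` links tissue burden (Bq/kg) to
deposition (Bq/m²), `μ` is the net ecological loss rate — so the
**ecological half-life** is `ln 2 / μ` — and `A`, `P` give the amplitude
and phase of a one-year seasonal oscillation (`ν = 1`, exponential loss,
is the default; `ν = 2` and free `ν` are available).

Estimation machinery:

* **`fit_ols()`** — multi-start nonlinear least squares, with a
  closed-form linearised solution computed alongside (and required to
  agree) since the model is linear in `(Q, μ, A·cos2πP, A·sin2πP)` for
  fixed `ν`;
* **`fit_robust()`** — Huber/bisquare M-estimation by IRLS, restart
  winner chosen by smallest |median residual|;
* **`fit_quantile()`** — pinball-loss fits of the 25th/50th/75th
  percentiles with bootstrap standard errors;
* **`fit_mixed()`** — maximum-likelihood mixed effects (via `nlme`) with
  district/municipality random effects and per-district residual
  variances, after robust-distance outlier filtering;
* **`score_extrapolation()`** — early-half/late-half temporal holdout
  scoring by test-RMSE ratio;
* **`enumerate_models()` / `mmi_average()`** — weighted-regression AICc
  model enumeration and multimodel inference for zone/year summary
  tables, yielding a decline rate and half-life with unconditional
  uncertainties;
* **`generate_fukushima()` / `generate_chernobyl()`** — synthetic data
  with known ground truth for every pipeline stage.

## Worked example

Generate study-scale synthetic boar records (n = 1404 over ~7 years, unit
ln-scale noise), ingest them through the raw-export path (dates plus
per-isotope activities, decay-corrected on read), and fit the model
robustly:

```r
library(radcesium)

env <- environment_spec(log(1e6), log(1e6))   # ln Bq/m2 isotope intercepts
g   <- generate_fukushima(simulation_config(seed = 42))
csv <- tempfile(fileext = ".csv")
write_fukushima_csv(g$records, csv, "raw")

d <- read_samples(csv, "raw")
d$report
#> Filter report: 1404 rows in; removed 0 (0.0%): 0 missing, 0 below detection, 0 unknown species; 1404 in analysis set

fit <- fit_robust(d$records, env, variant = "nu1", n_restarts = 50, seed = 1)
fit
#> robust fit of the burden model (variant nu1), n = 1404
#>    estimate     se
#> Q   -4.7826 0.0596
#> mu   0.1949 0.0143
#> A    0.6567 0.0397
#> P    0.4015 0.0096
#> RMSE = 1.0222; AIC = 71.67; converged: TRUE (50 restarts)
```

The generating truth was `Q = −4.851, μ = 0.173, A = 0.641, P = 0.405`;
every estimate lands within about two standard errors.  The derived
summaries put the science on its reporting scale:

```r
summarize_fit(fit)[c("half_life", "half_life_lo", "half_life_hi",
                     "amplitude", "phase_months")]
#>   half_life half_life_lo half_life_hi amplitude phase_months
#> 1  3.556325     3.109167     4.153707  1.928349     4.817417
```

— an ecological half-life of ~3.6 years (95% CI 3.1–4.2): burdens halve
every few years beyond physical decay alone.  The seasonal peak is
`exp(A) ≈ 1.93`-fold above the annual mean, reached in late winter
(phase shift ≈ 4.8 months).

For summary-only data (zone/year tables with animal counts and mean /
min / max burdens), the weighted-regression multimodel-inference arm:

```r
ch  <- generate_chernobyl(seed = 7, rate = 0.08, sd_ln = 0.5,
                          n_per_cell = 10, poisson_n = FALSE)
res <- run_chernobyl_analysis(ch$records)
res$models
#> Weighted-regression model set (n = 54 ):
#>        model k   aicc delta_aicc akaike_weight
#>    time_zone 5 -36.41       0.00         0.921
#>  time_x_zone 7 -31.49       4.92         0.079
#>         zone 4  95.34     131.75         0.000
#>         time 3 108.33     144.74         0.000
#>         null 2 128.31     164.72         0.000
res$mmi$half_life
#> $estimate
#> [1] 7.726417
#> ...
```

Time + Zone without interaction wins, and the model-averaged decline rate
of 0.0897/y (truth: 0.08) gives a half-life of 7.7 years with its
unconditional 95% interval.

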
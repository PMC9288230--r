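# qexptail

Heavy-tailed statistics of air-pollutant concentrations: q-exponential
tail fitting, model selection and superstatistical synthetic ensembles.

## The problem

Hourly concentrations of NO, NO₂, PM₂.₅ and PM₁₀ at monitoring sites are
not exponentially distributed: their probability densities generically
carry heavy tails, and the tail shape varies enormously between sites and
pollutants. A physically motivated description is superstatistical: on
short time scales concentrations are exponential, `f_λ(x) = λ e^{-λx}`,
but the rate λ drifts slowly with weather and traffic. When λ is
Γ-distributed, the long-run marginal is exactly the **q-exponential**

    f_{q,λ}(x) = (2 − q) λ [1 − λ(1 − q) x]^{1/(1−q)},   1 − λ(1−q)x ≥ 0, x > 0

with entropic index `q` (tail heaviness; power-law tail exponent
`−1/(q−1)` for q > 1, finite support for q < 1, exponential at q = 1) and
width parameter `λ` (inverse concentration scale: larger λ means cleaner
air). For a Γ(a, θ) rate, the marginal has `q = (a+2)/(a+1)` and
`λ_q = θ(a+1)`, while the raw rate fluctuations satisfy
`q = ⟨λ²⟩/⟨λ⟩²` — both conventions are implemented and documented.

`qexptail` implements the full analysis pipeline for monitoring-site
ensembles, for researchers in environmental statistics and statistical
physics:

- the q-exponential distribution (`dqexp`, `pqexp`, `qqexp`, `rqexp`,
  `qexp_mean`, `qexp_loglik`) and its maximum-likelihood estimator
  `fit_qexp()`, a classed model object with the usual methods;
- candidate-model comparison (`fit_tail_family`, `compare_models`):
  exponential, gamma, Weibull, log-normal and q-exponential fitted by MLE
  on the same tail sample and ranked by log-likelihood;
- monitoring-site quality control (`run_qc`): ≥ 8760 hourly points,
  ≤ 15 % below the detection limit (with LOD/2 substitution), no single
  value repeated ≥ 15 % of the time;
- tail extraction at the kernel-density peak (`kde_peak`,
  `extract_tail`) and the per-site composite `fit_site()`;
- site classification and ensemble summaries (`classify_site` — the seven
  environment categories, `beaufort_class` — four wind-force classes,
  `match_weather_station`, `group_lambda_summary`, `scatter_table`);
- a superstatistical synthetic-data generator (`superstat_config`,
  `gen_concentration_series`, `gen_site_ensemble`) with the closed-form
  marginal `marginal_qexp()` as ground truth, so every stage is testable
  without downloading monitoring data.

## Worked example

```r
library(qexptail)

# two years of synthetic hourly NO2 from a slowly fluctuating Gamma rate
cfg <- superstat_config(a = 2, theta = 0.05, window_hours = 168,
                        n_hours = 17520, seed = 5)
marginal_qexp(a = 2, theta = 0.05)
#>     q  lambda
#> 1.3333  0.1500

s  <- gen_concentration_series(cfg)
sf <- fit_site(s, qc = FALSE)
sf
#> site fit syn0001 / no2
#>   tail cutoff x_peak = 2.302 (14372 tail points)
#>   q = 1.3552, lambda = 0.1259; best family: qexponential
#>   raw mean = 23.36, sd = 50.72
```

The fitted entropic index (1.355) recovers the generator's marginal
q = 4/3; sd exceeding the mean (50.7 vs 23.4) is the heavy-tail
signature that rules out a plain exponential. On a 50-site ensemble:

```r
ens <- gen_site_ensemble(50, n_defect_short = 2, n_defect_lod = 2,
                         n_defect_stuck = 2, seed = 7)
sl  <- read_observations(ens$observations, sites = ens$sites, lod = 0.2)
res <- run_pipeline(sl, wind = ens$wind)
res
#> air-pollution tail-statistics pipeline: 50 series, 44 passed QC, 44 fitted
#> mean log-likelihood across sites (best family first):
#> qexponential      weibull    lognormal        gamma  exponential
#>    -65842.37    -66198.89    -66322.14    -66581.19    -67386.37
#> lambda medians by environment category (ascending):
#>                       group n_sites median_lambda
#> 1             urban traffic      11       0.02132
#> 2    suburban/rural traffic       4       0.03356
#> ...
```

The six planted defective sites are exactly the six QC rejections, the
q-exponential attains the highest mean log-likelihood, and the category
medians of λ rank from polluted urban traffic (small λ) to clean rural
background (large λ), the planted ordering.

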
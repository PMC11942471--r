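# effindex

Composite regional fragility indices from administrative count registries.

Public registries publish department-year counts — births by maternal age,
health-insurance affiliations by category, domestic-violence reports by
victim class, deaths by cause — but policy targeting needs one comparable
score per region. `effindex` turns those raw tables into the **Early
Fertility Fragility Index (EFFI)**: it harmonizes the registries onto a
rectangular department-year panel (with linear-interpolation imputation of
missing cells), computes ten epidemiological indicators, Z-score
standardizes them, refines the predictor set by backward elimination under
a Gaussian GLM, aggregates the retained indicators with equal weights

```
EFFI_d = Σ_i w_i · Z_{i,d},   w_i = 1/k,
```

and validates the index with Spearman rank correlations between EFFI and
the relative post-pandemic changes in early fertility rates
(Δ = (x_t − x_{t−1})/x_{t−1} × 100 for IFR, AFR, EFR). It is aimed at
epidemiologists and public-health analysts working with registry-level
panels rather than microdata.

The ten indicators: affiliation shares PIW / PMW / PSW (indigenous,
migrant, subsidized-regime women per 100 affiliated women), fertility
rates IFR / AFR / EFR (births to mothers ≤14, 15–19, ≤19 per 1000
affiliated women in the matching age band), violence shares DVAW / DVAC
(cases against women with male perpetrator, against children ≤18, per 1000
reported cases), and death rates SR / CHR (suicides, homicides of persons
≤19 per 1000 reported deaths).

Because registry microdata cannot ship with the package, a synthetic
generator emits all four registries with a planted per-department latent
fragility factor and a one-year fertility shock, so the entire pipeline is
testable end to end, including recovery of the planted signal.

## Worked example

Generate synthetic registries for 33 departments (2019–2022), run the full
pipeline, and compare the recovered index with the planted truth:

```r
library(effindex)

cfg <- synthetic_config(n_departments = 33, seed = 7)
rec <- recover_synthetic(cfg)

rec$fit
#> <effindex_glm_fit> z_dEFR ~ 1 term(s), family gaussian, n = 33
#>   deviance 3.7672 (null 33.0000), pseudo-R2 0.8858
#> # A tibble: 2 × 5
#>   term        estimate std_error statistic  p_value
#>   <chr>          <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept) -0.00444    0.0607   -0.0731 9.42e- 1
#> 2 PIW          0.933      0.0602   15.5    3.70e-16

rec$validation
#> # A tibble: 3 × 6
#>   pair          rho  p_value     n method          interpretation
#>   <chr>       <dbl>    <dbl> <int> <chr>           <chr>
#> 1 EFFI~z_dIFR 0.656 3.39e- 5    33 t approximation supports_validity
#> 2 EFFI~z_dAFR 0.940 5.22e-16    33 t approximation supports_validity
#> 3 EFFI~z_dEFR 0.941 4.41e-16    33 t approximation supports_validity

rec$spearman_fragility$rho
#> [1] 0.9979947
```

Reading the output: backward elimination against the standardized EFR
change retained one indicator (the planted fragility channels are highly
collinear, so one representative carries the signal); the refined model
explains 89% of the outcome deviance; the index correlates at ρ ≈ 0.94
with the standardized EFR and AFR changes (supporting validity under the
sign rule) and at ρ ≈ 0.998 with the planted latent fragility factor.

For file-based runs, point `run_config()` at the four registry CSVs
(long format: `department, year, category, count`) and call
`run_pipeline()`; every stage is written to CSV alongside a manifest of
checksums. A thin command-line wrapper is installed at
`inst/scripts/effi` (`effi simulate`, `effi run-all`).

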
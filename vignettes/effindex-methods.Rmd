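---
title: "Constructing and validating a regional early-fertility fragility index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating a regional early-fertility fragility index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effindex)
```

## The problem

Adolescent and child fertility concentrates where structural vulnerability
does: where indigenous and migrant populations face barriers to reproductive
health services, where most women depend on a subsidized health-insurance
tier, and where exposure to domestic and lethal violence is high. A single
composite score per region — here called the Early Fertility Fragility Index
(EFFI) — lets analysts rank first-level administrative divisions
("departments") by this bundled risk and check whether the ranking
anticipated the post-pandemic surge in early fertility.

`effindex` implements that workflow end to end on department-year count
tables of the kind public registries publish: births by maternal age band,
health-insurance affiliations by category, domestic-violence reports by
victim class, and deaths by cause.

## Indicators

Ten ratio indicators are computed per department-year from harmonized
counts. Writing $n_{\cdot}$ for counts:

* **Structural inequality** (per 100 affiliated women):
  $\mathrm{PIW} = n_\text{indigenous}/n_\text{affiliated} \times 100$, and
  likewise PMW (migrant) and PSW (subsidized regime).
* **Early fertility** (per 1000 affiliated women in the matching age band):
  $\mathrm{IFR} = n_\text{births, mother} \le 14 / n_\text{affiliated 10–14}
  \times 1000$; AFR for the 15–19 band; EFR pools both bands, so it is
  always a count-weighted mean of IFR and AFR.
* **Domestic violence** (share of all reported cases): DVAW (female victim,
  male perpetrator) and DVAC (victim aged ≤ 18). The scale defaults to
  per-1000, the magnitude at which these shares are conventionally
  tabulated; a per-100 scale is one configuration flag away. (Published
  tabulations of these two indicators are internally inconsistent between a
  per-100 formula and per-1000 values; the package defaults to the scale the
  tabulated values actually use and documents the switch.)
* **Violent death** (per 1000 reported deaths): SR (suicides) and CHR
  (homicides of persons ≤ 19).

Affiliated-women counts serve as the population denominators throughout —
no census denominators are introduced. A zero denominator yields a missing
value, never a silent zero; a subgroup count exceeding its total is an
error, because it can only arise from corrupted input.

Note that "IFR" is a conventional label for fertility of mothers aged 14 or
younger; despite the name it is not an infant-mortality-style rate.

## Harmonization and imputation

Registries are read in long format (department, year, category, count),
department names canonicalized (uppercase, accents stripped, whitespace
collapsed, optional alias map), and pivoted onto the full
departments × years grid. Cells absent from the input are *missing*, not
zero — violence registries contain genuine all-zero series, and conflating
the two would fabricate data. Missing interior cells are filled by linear
interpolation along years within each department; boundary cells use
nearest-value extension, since linear interpolation is undefined beyond the
observed range. Every filled cell is flagged `imputed` in a provenance
table that travels with the panel, and imputation is idempotent and never
touches an observed cell.

## Standardization, segmentation, and the index

Each indicator is Z-score standardized, $(x - \mu)/\sigma$, with the
*population* $\sigma$ (divide by $N$) and one pooled transformation per
indicator across all department-years. Pooling keeps the longitudinal data
on a single scale per indicator; a within-year pool is available as a
sensitivity flag. A constant indicator ($\sigma = 0$) standardizes to all
zeros with a warning, so a degenerate channel drops out of the composite
instead of crashing the run.

Two datasets are then built:

* **longitudinal** — standardized risk indicators (PIW, PMW, PSW, DVAW,
  DVAC, CHR, and by default also SR) for every department-year; fertility
  rates are excluded by construction because they define the outcome;
* **aggregated** — one row per department: each standardized risk indicator
  averaged over the index window (default 2019–2021), joined with the
  relative fertility changes
  $\Delta = (x_{t} - x_{t-1})/x_{t-1} \times 100$ for IFR, AFR and EFR over
  the outcome year pair (default 2020→2021, the pandemic-conception to
  maternity transition) and their standardized versions.

SR sits in the default predictor set even though it is not part of the core
six-indicator risk taxonomy: the refined models this design reproduces
treat it as a candidate, and the set is configurable either way.

The index is the weighted sum
$\mathrm{EFFI}_d = \sum_i w_i Z_{i,d}$ with equal weights $w_i = 1/k$ over
the *retained* indicator set. Retention comes from backward elimination
under a Gaussian identity-link GLM: refit, drop the single predictor with
the largest p-value above $\alpha = 0.05$ (largest-first, one at a time —
simultaneous removal can discard jointly informative predictors), stop when
all remaining predictors are significant. Every drop is recorded in an
audit trail with its p-value and the deviance / pseudo-R²
($1 - \text{residual deviance}/\text{null deviance}$) after removal. A
keep-list can pin predictors that should survive regardless of
significance, and `glm_coefficients` weighting is available for sensitivity
analysis.

### Choice of GLM outcome

Two constructions are implemented because the underlying design is
genuinely open:

* `delta_outcome` (default, recommended): prune predictors against the
  standardized EFR change $Z_{\Delta EFR}$ — the index is then refined
  against the quantity it claims to anticipate.
* `composite_outcome`: form the equal-weight composite of all candidates,
  regress it on its own components, prune, and re-aggregate. The
  first-stage regression is *circular* — the outcome is an exact linear
  combination of the predictors, so its pseudo-R² is identically 1 — and
  the package emits a warning saying so whenever this mode runs. It exists
  to reproduce that near-saturated behaviour faithfully, not as an
  endorsement.

The family is Gaussian with identity link: the outcomes are continuous
standardized quantities, and the family is configurable.

## Validation

Spearman rank correlation between EFFI and each standardized fertility
change, with average ranks for ties and the sign-based reading: clearly
positive supports validity, $|\rho| < 0.1$ (configurable — no canonical
threshold exists for "no correlation") is read as no link, clearly negative
contradicts the framework. Because Spearman correlation is invariant under
strictly increasing transforms, $\rho$ is identical on $\Delta$ and
$Z_\Delta$ — the package exploits this as a cross-module consistency check
in its tests. Two-sided p-values use the exact permutation distribution
(all $n!$ rank permutations) below $n = 10$ and the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation with $n - 2$ degrees of
freedom from $n = 10$ up — exactness where it is cheap, convention where it
is not. With ~33 departments the $t$ path is the operative one. No
multiple-testing correction is applied across the three correlations; none
is conventional for this three-way validation readout, and the omission is
deliberate and documented.

## The synthetic registry generator

Real registry microdata cannot ship with the package, so
`generate_synthetic()` emits the four raw count tables directly in the
input dialect — the pipeline is exercised from the reader onward, never
bypassed. Per department $d$ a latent fragility factor
$F_d \sim N(0, 1)$ drives:

* subgroup counts (indigenous/migrant/subsidized affiliation, violence
  victim classes, suicide/homicide deaths) as Binomial draws with
  logit-linear-in-$F_d$ proportions;
* births as Poisson draws with log-linear-in-$F_d$ rates, plus a one-year
  shock term $\text{shock} \cdot F_d$ (default year 2021) emulating
  pandemic-conception maternities;
* log-normal affiliated-women totals, zero-inflated violence subgroup
  cells (mimicking the genuine all-zero series small departments report,
  and exercising the $\sigma = 0$ and zero-baseline code paths), and
  missing-at-random dropped cells.

Log-linear and logit-linear links are the simplest positive, monotone
structures consistent with the pipeline's monotone-association assumptions.
Defaults describe the high-signal study regime: 33 departments, 2019–2022,
loadings 0.8 on the indigenous, subsidized and child-homicide channels and
0 on the rest, fertility loading 0.3, shock 0.5, rate noise SD 0.05,
zero-inflation 0.08, missingness 0.02. Baseline shares and rates (e.g.
AFR 30 per 1000, suicide 11 per 1000 deaths) sit at magnitudes typical of
published departmental tabulations. Department labels are synthetic
(`D01`, `D02`, …): the generator emulates the *structure* of the
registries, and no output should be read as reproducing any real
department's values.

What the generator does *not* emulate: spatial correlation between
departments, reporting artefacts (underreporting of violence, late birth
registration), demographic trends beyond a small year-to-year population
jitter, and real marginal distributions. Passing recovery tests therefore
demonstrates that the pipeline recovers a planted monotone signal through
realistic count noise — not that the index is valid on real Colombian
registries.

## Numerical choices and degenerate inputs

* Population σ throughout (matching the plain-σ standardization formula);
  tests tolerate either convention only where they say so explicitly.
* Missing ≠ zero at every stage; zero denominators and zero baselines
  propagate as missing with warnings naming the cells.
* Backward elimination breaks p-value ties by column order (stable,
  deterministic); an all-eliminated model returns the intercept-only fit
  with a warning.
* Constant predictor columns are dropped with a warning before fitting;
  genuinely collinear designs abort naming the offending columns.
* All pipeline randomness flows from one top-level seed;
  (configuration, seed) determines every artifact byte-for-byte, and the
  run manifest records MD5 checksums so reruns can be compared cheaply.

## Verification scale

The shipped tests run the recovery study at 50 replicates of 33
departments, the pruning null calibration at 1000 replicates of n = 100,
and oracle comparisons (closed-form least squares, brute-force Spearman,
exhaustive permutation enumeration) at small n — sizes chosen so the whole
suite re-runs in about a minute while keeping Monte-Carlo bands tight
enough to detect real miscalibration. The recovery bar for the high-signal
regime (median Spearman between recovered index and planted fragility above
0.8) derives from an independent channel-level simulation of the same
generative regime, not from the pipeline itself.

## Known limitations

* The index is correlational; nothing here supports causal readings.
* Backward elimination among collinear fragility proxies typically retains
  one representative of a correlated cluster — the index then rests on
  fewer channels than were planted, which is expected behaviour, not
  signal loss (the recovered score still tracks the latent factor).
* Per-predictor retention under the null sits slightly above the nominal
  α (selection inflation intrinsic to stepwise procedures, ~5.5% at
  α = 5%).
* The two-mode outcome design reflects an unresolved ambiguity in how the
  refinement regression is posed; `delta_outcome` is the defensible
  default, `composite_outcome` is provided for comparability and is flagged as
  circular at run time.
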
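---
title: "Methods: net-benefit evaluation of bone-scan staging strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: net-benefit evaluation of bone-scan staging strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonedca)
```

## The question the package answers

A staging bone scan at prostate cancer diagnosis detects skeletal
metastases that change treatment, but scanning everybody is wasteful and
produces false positives. Eleven published selection rules — three
continuous risk equations (Chybowski, Ho, Wang), five categorical models
(O'Sullivan, Briganti, Lai, the ISUP grade grouping and the five-tier
Gnanapragasam/Cambridge grouping) and three guideline stratifications
(AUA 2018, EAU 2020, NCCN 2019) — disagree about who to scan. `bonedca`
evaluates them head to head on net benefit,

$$\mathrm{NB}(p_t) = \frac{TP}{n} - \frac{FP}{n}\cdot\frac{p_t}{1-p_t},$$

across threshold probabilities $p_t \in [0.01, 0.10]$, i.e. preference
ratios 1:99 through 1:9, or a number-willing-to-test (NWT $= 1/p_t$) of
100 down to 10. A strategy's curve is compared pointwise; the
`optimal_strategy_map()` reports the argmax per grid point, merging runs
into segments. NWT is displayed as $\lfloor 1/p_t \rfloor$: the floor
convention reproduces all conventional printed boundaries (100, 40, 33,
14, 13, 10), and a representation-tolerance of $10^{-9}$ is added before
flooring so that binary representations of thresholds such as 0.01 do not
floor to 99.

Key modelling conventions, each chosen once:

* Inequality thresholds are read exactly as their sources print them:
  `PSA > 10` is strict, `GS >= 4+3` inclusive.
* The staging window is 20 weeks = 140 days with an inclusive boundary
  (a scan on day 140 is a staging scan).
* A continuous model scans at predicted risk $\ge p_t$ (inclusive).
* Ties in the optimal map go to the strategy scanning fewer patients; at
  equal net benefit the scanning burden is the only differentiator.
* The Wang decision score is
  $D = -6.40 + 2.39\,[\mathrm{T4}] + 0.87\ln(\mathrm{PSA}+1)
  + 0.93\,[\mathrm{GS}\ge 4{+}3] + 2.169$, and the shipped strategy
  follows the printed direction *scan when $D < 0$* even though every
  coefficient is risk-increasing; `model_registry(wang_direction =
  "inverted")` flips it, and no silent guess is made about the source's
  intent.
* Ho's equation and Chybowski's risk graph are not reproduced in the
  validation literature this package follows; their continuous forms must
  be supplied via `model_registry(continuous_forms = ...)`, and only
  their fixed strategies (PSA cut-offs, nodal involvement) ship as
  defaults. Requesting an unavailable continuous form is an explicit
  error, never a fallback.
* The five-tier grouping's Group 5 (Gleason 9–10, T4, or two of
  {Gleason 8, PSA > 20, T3}) comes from the model's development
  publication rather than the validation source and is replaceable via
  the `group5` argument. The Strategy-1 description circulating in print
  ("any two of GS 3+4, PSA 10–20 or T1–T2") is treated as a typographical
  anomaly; groups follow the development scheme.
* "EAU high-risk only" is encoded as PSA > 20, Gleason sum ≥ 8 or
  T ≥ T3, which keeps it strictly nested inside the full EAU 2020 scan
  rule — a property the tests assert.
* "T2–3 disease" in the Briganti rule means T2a–T3c inclusive.

## Validation metrics

Calibration regresses the (imputed) binary outcome on
$\mathrm{logit}(\hat p)$: the slope should be 1; the intercept of the
offset model (slope fixed at one) should be 0, with positive values
meaning under-estimated risk. Predictions are clipped to
$(\varepsilon, 1-\varepsilon)$, $\varepsilon = 10^{-6}$, before the logit;
boundary risks are otherwise unaddressed by the sources. Calibration is
only defined where a model yields numeric predicted risks: continuous
models directly, categorical models through configured development-study
per-group positivity rates (`categorical_predicted_risk()`). Models with
three or fewer distinct predicted-risk levels are excluded (the default
registry ships only the single overall development rates as documented
placeholders, so categorical calibration activates only when the user
supplies per-group rates). Guideline strata publish no numeric risks and
are always excluded from calibration; their AUC uses the ordinal stratum
rank as score. AUC is the rank-based concordance with ties counted half
and a DeLong variance; it is pooled on the raw scale (pooling the logit
would be defensible too, but the raw scale keeps the estimate in $[0,1]$
interpretable alongside single-dataset values).

All metrics are computed inside each imputed dataset and combined by
Rubin's rules: pooled estimate = mean, total variance = within +
$(1+1/m)\,$between, with Barnard–Rubin small-sample degrees of freedom
when a complete-data df is supplied and the classic large-sample formula
otherwise.

## The imputation engine

The analysis treats the unscanned majority as missing outcome data. No
chained-equations package is assumed; `mice_impute()` implements the
cycle directly:

* **Variables**: log PSA, percent positive cores, ISUP grade group,
  T-stage rank, nodal stage, scan outcome.
* **Methods**: predictive-mean matching (k = 5 donors, Bayesian linear
  parameter draw; donors guarantee imputed categories stay in their
  observed support) for continuous and ordinal variables; Bayesian
  logistic draws for binary variables. The per-variable methods are this
  package's defaults — declared, not inferred from any source.
* **Predictors**: every other modelled variable plus age, diagnosis
  year, treatment setting and survival encoded as
  $(\log(\text{months}+1), \text{event})$ — a standard encoding of a
  censored outcome in imputation models.
* **Visit sequence**: increasing missingness, ties alphabetical.
* **Reproducibility**: one master seed, with named substreams per
  dataset; observed cells are never altered, and a cohort with no
  missing cells passes through unchanged.
* A conditional fit that fails degrades to a marginal draw and is logged
  in the returned object's `warnings`, never silently.

Unresolvable indeterminate scans are set to `none` by
`reclassify_indeterminate()` and imputed together with the never-scanned
patients. The Kaplan–Meier diagnostic (`km_diagnostic()`, via the
`survival` package) compares observed-positive against imputed-positive
survival (and likewise negatives): agreement supports, though never
proves, the missing-at-random assumption.

Reference scale is m = 100 datasets × 100 iterations; the package default
is m = 5 × 10, and the test suite runs m ≤ 5 with 2–5 iterations so the
whole suite stays within minutes. With a single incomplete variable one
sweep is already exact; the scaled-down settings trade only
between-imputation granularity, not correctness, and the Rubin identities
are tested exactly at any m.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` states a world resembling a population registry
cohort of ~10,000 newly diagnosed patients:

* **Predictors**: age normal (mean 67.9, truncated 34–98); PSA
  log-normal with median 8.2 ng/mL; grade-group frequencies 36.5 / 26.5 /
  16.2 / 13.0 / 7.8 %; T-stage split 63.6 / 28.7 / 5.1 / 2.7 % across
  T1/T2/T3/T4; 5% nodal positivity; Beta-distributed core percentages
  with median ≈ 33%; 45% privately treated.
* **Latent outcome**: scan positivity is logistic in log PSA, grade
  group, T-rank and nodal stage. The intercept (−6.2669) was fixed once
  by `calibrate_positivity_intercept()`, root-finding on a 200,000-record
  predictor sample so that expected positivity *among scanned patients*
  is 8.7%; the positivity of never-scanned patients is then an emergent
  consequence of the same latent model rather than an asserted number.
* **Selective scanning**: scan probability depends on a coarse clinical
  risk stratum and treatment setting (0.13–0.62 public, lower privately),
  yielding ≈ 38% scanned; 3.6% of performed scans are indeterminate, 90%
  of those resolvable by follow-up.
* **Missingness**: missing-at-random given treatment setting and risk
  stratum — the two mechanisms a registry of this kind actually exhibits
  (selective staging of higher-risk patients; restricted private-sector
  data). Default cell probabilities imply marginals near 40% (PSA), 77%
  (T-stage), 76% (nodal), 17% (cores), 2.4% (Gleason). MNAR is out of
  scope.
* **Survival**: exponential, baseline 0.0021/month (≈ 88% five-year
  survival) with hazard ratio 6 for scan-positive disease (≈ 47%
  five-year survival), administrative censoring uniform on 6–174 months.
  Nothing in the evaluated sources specifies survival distributions; the
  exponential form exists so the KM diagnostic has signal.

A green test on this world establishes that the pipeline's algebra,
pooling and decision logic are correct under known truth. It does not
establish registry realism: joint predictor correlations (e.g. PSA–grade
dependence), temporal trends, cause-specific mortality and
model-specific real-cohort AUC/calibration values are all outside what
the generator states, and real-cohort results are not reproduced here
because no such registry is public.

## Numerical and testing choices worth knowing

* The calibration-recovery experiment (50 seeds, n = 10,000, m = 5)
  draws outcomes from the Wang model's own predictions and masks ~20% of
  them at random given PSA. The world is restricted to Gleason 3+4/4+3,
  stages T1–T3 and PSA away from zero so the model's linear predictor is
  linear in the imputation model's covariates: with the step terms (T4,
  GS ≥ 4+3) active, the conditional models are uncongenial with the
  outcome-generating mechanism and pooled slope intervals under-cover —
  an informative fact about imputation-model congeniality, but not what
  the experiment is meant to measure. Coverage is asserted at the
  nominal level minus three binomial Monte-Carlo standard errors.
* The mis-calibration demonstration deflates a model's predicted odds
  fourfold (systematic under-estimation, the direction most published
  models err in). Deflation makes thresholding the continuous
  predictions too conservative, so the model's own broader recommended
  fixed strategy overtakes its decision curve at tolerant thresholds.
  Odds *inflation* does not produce a reversal on the 0.01–0.10 grid —
  the over-broad continuous curve simply approaches scan-all — which is
  why the constructed experiment uses deflation.
* Net-benefit pooling across imputed datasets is the simple mean:
  counts are linear in patients, so mean-of-NB equals NB-of-mean-counts.
* Percentages in cohort summaries round half away from zero to one
  decimal; `percent_mode = "truncate"` exists for tables that truncate
  instead.
* All delimited outputs are written with full numeric precision, and the
  run manifest embeds the configuration at 17 significant digits, so a
  reloaded configuration re-runs to byte-identical outputs.

## Limitations

The generator's marginals are stated, not fitted; no attempt is made to
match real joint distributions. Only the printed fixed strategies of Ho
and Chybowski are evaluated unless their continuous forms are supplied.
Decision curves carry no confidence bands. Alkaline-phosphatase-based
models are out of scope, as is any cost-effectiveness extension or
PSMA-PET comparison.
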
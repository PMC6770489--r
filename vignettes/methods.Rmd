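---
title: "Modelling the burden of iron-deficiency anaemia from intake and requirement distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the burden of iron-deficiency anaemia from intake and requirement distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irondaly)
```

## The model

`irondaly` estimates, for a national population stratified by gender, age
class and menstrual/menopausal status, the prevalence of dietary iron
deficiency (ID), the number of iron-deficiency-anaemia (IDA) cases by
severity, and the resulting annual burden in disability-adjusted life years
(DALY). Three modelling hypotheses underpin the chain:

1. iron deficiency arises when absorbed dietary iron does not cover the
   physiological requirement;
2. the ratio between ID and IDA prevalence in a stratum is constant, in
   particular across consumption scenarios;
3. adding highly bioavailable (heme) iron to the diet reduces IDA.

Per stratum, absorbed iron intake across people follows a lognormal
distribution $X \sim \mathrm{LogN}(\mu, \sigma)$ (on the absorbed scale,
mg/day) and the individual requirement follows a normal distribution
$R \sim N(m_R, s_R)$, the average-requirement value and spread published by
EFSA. The ID prevalence is the full-probability quantity

$$\mathrm{Prev.ID} = P(X < R) = E_R\!\left[F_X(R)\right],$$

with $F_X$ the lognormal CDF. The rest of the chain is multiplicative:

$$\mathrm{Prev.IDA} = \mathrm{Prev.ID} \times \mathrm{Prop.IDA}, \qquad
  \mathrm{NB.IDA}_s = \mathrm{Pop} \times \mathrm{Prev.IDA} \times
  \mathrm{Alloc}_s, \qquad
  \mathrm{DALY} = \sum_s \mathrm{NB.IDA}_s \, w_s,$$

where $\mathrm{Prop.IDA}$ is the per-stratum proportion of deficiencies
presenting as anaemia, $\mathrm{Alloc}_s$ allocates the anaemic fraction to
mild/moderate/severe bands, and $w_s$ is the severity's disability weight.
No mortality term is included (there are no national IDA fatality data), and
the disability duration is one year, so DALY equals annual YLD. No age
weighting or discounting is applied.

Severity allocation is closed-form: with haemoglobin
$H \sim N(m_H, s_H)$ g/dL and WHO thresholds $t_{\text{mild}} >
t_{\text{mod}} > t_{\text{sev}}$, anaemia is $H < t_{\text{mild}}$ and, for
example, the moderate fraction is
$[\Phi(z(t_{\text{mod}})) - \Phi(z(t_{\text{sev}}))] / \Phi(z(t_{\text{mild}}))$
with $z(t) = (t - m_H)/s_H$. The same allocation is applied to IDA as to
all-cause anaemia.

## Separating uncertainty from variability

A second-order (two-dimensional) Monte Carlo keeps epistemic uncertainty
apart from biological variability:

* **Outer loop** (default `n_unc = 1000` iterations): one draw of the intake
  parameters $(\mu, \sigma)$ per iteration, from their uncertainty
  description. When running from the packaged table, each parameter is drawn
  from an independent normal centred on the point estimate with
  sd = (CI$_{hi}$ − CI$_{lo}$)/(2 × 1.96) — the minimal assumption when only
  a point estimate and a 95% CI are published. When running from survey
  records, the draws are nonparametric bootstrap replicates, which also
  preserve the correlation between the two parameters.
* **Inner loop** (default `n_var = 10000` iterations): requirement draws
  $r_j \sim N(m_R, s_R)$. The prevalence for an outer iteration is
  $\tfrac1{n_{var}}\sum_j F_X(r_j)$ — intake variability is integrated in
  closed form through the CDF (a Rao-Blackwellised estimator), which is
  strictly lower-variance than sampling both sides and mirrors how the
  model is defined. Negative requirement draws, possible for the wide
  menstruating-women distribution $N(1.41, 0.76)$, contribute exactly zero
  (intake is positive) and are deliberately retained: truncating or
  redrawing them would bias female prevalences upward.

Requirement and haemoglobin distributions carry variability only and are
not perturbed in the outer loop. Disability weights are the opposite: they
are treated as pure uncertainty, drawn once per outer iteration and shared
across strata, because a weight is a property of the health state rather
than of a stratum. Sharing widens the aggregate interval relative to
independent per-stratum draws, which is the intended interpretation.
Everything downstream of the prevalence (cases, DALY, totals) is computed
per outer iteration and summarised at the end as a mean and equal-tailed
95% interval; totals are summed within iterations first, so the interval
of the total reflects the shared-weight correlation.

### Numerical choices

* **Stratified streams.** The CI-based parameter sampler and the
  disability-weight stream use stratified (Latin-hypercube) inverse-CDF
  draws with independent random permutations per parameter. The marginal
  distributions are exact; the benefit is that the mean of each stream is
  pinned to its expectation, so output *means* drift very little from seed
  to seed. With plain draws the seed-to-seed drift of mean DALY at
  `n_unc = 1000` is dominated by the weight stream (~0.7%), uncomfortably
  close to the 1% three-seed stability margin this model is expected to
  meet; with stratification the observed maximum relative deviation over
  three seeds is ~0.4%, dominated by the inner loop.
* **Truncation.** Weight draws are truncated below at zero (the mild weight
  $N(0.005, 0.002)$ has ~0.6% negative mass; weights live in $[0,1]$).
  Non-positive `sdlog` draws are likewise handled by truncation of the
  sampling distribution, which is distributionally identical to the
  redraw-until-positive rule; for the shipped CIs the affected mass is
  at most ~5 × 10⁻⁶.
* **Reproducibility.** One root seed; every stratum (and the weight stream)
  gets a deterministic child seed, so strata are reproducible independently
  and insensitive to evaluation order. `id_prevalence_point()` with
  `req_sd = 0` returns the closed-form CDF exactly without consuming random
  numbers.
* **Degenerate inputs.** A haemoglobin distribution with (numerically) zero
  anaemia probability makes the allocation undefined; it is returned as all
  zeros with a warning. A zero-variance intake sample is a fitting error,
  as is any non-positive intake value.

## The packaged parameter set

The package ships a JSON configuration for metropolitan France (2005-2007
dietary survey era): 17 strata — 7 male (with a merged 12-17 adolescent
class), 7 premenopausal female (12-14 assumed non-menstruating, 15-17
menstruating with adult-female needs), 3 postmenopausal female (25-44,
45-64, 65-74). Per stratum it records the population count, the absorbed
intake lognormal parameters with their 95% CIs, the requirement normal, the
ID-to-IDA proportion, the haemoglobin normal and the severity thresholds;
disability weights are shared (mild $N(0.005, 0.002)$, moderate
$N(0.058, 0.012)$, severe $N(0.164, 0.030)$).

Two values deserve comment:

* **Per-100,000 denominator.** The published national rates are consistent
  with a reference population of 61.8 million (the strata themselves sum to
  ~53.9 million because the model covers ages 3-74 and excludes pregnant
  women). The denominator is therefore a config constant,
  `total_reference_population = 61,800,000`, and can be overridden.
* **Severity thresholds.** The threshold table in the source material is
  typographically damaged, so the package ships a canonical reconstruction
  of the WHO bands: children 3-6 use 10.9/9.9/7.0 g/dL
  (mild/moderate/severe upper bounds), 7-11 use 11.4/10.9/8.0, females 12+
  use 11.9/10.9/8.0, males 12-17 use 11.9/10.9/9.0 and males 18+ use
  12.9/10.9/8.0. Each choice was verified against the published per-stratum
  DALY values through the closed-form chain. The severe band is numerically
  negligible (fractions below 10⁻³) for every shipped haemoglobin
  distribution, so the residual ambiguity in the severe thresholds does not
  move any result.

A known limitation of the source data: the printed male intake parameters
for 18-24 (identical to the female entry, presumably a duplication), 25-44
and 45-64 are internally inconsistent with the published male prevalences —
no computation from the printed inputs reproduces 9%, 5% and the "450
(360-460)" case interval for those strata. The package transcribes the
printed inputs faithfully rather than calibrating to the outputs; the
affected cells are the only published values the test suite does not
reproduce, and the national totals are insensitive to them at the reported
precision.

## Survey ingestion

When individual records are available, `fit_survey()` reproduces the
processing chain assumed by the model: resolve missing pregnancy/menopause
answers (under 18: not pregnant; menopause unknown with negative pregnancy:
decided by age 50; pregnancy unknown with negative menopause: treated as
pregnant; pregnant women excluded), map records to the stratum grid (women
15-24 forced premenopausal, 65-74 forced postmenopausal, 25-64 split by the
resolved answer), convert to absorbed intake with flat coefficients (10%
for ages 3-11, 16% for adolescents and adult males, 18% for adult women),
and fit the per-stratum lognormal by maximum likelihood
($\hat\mu$ = mean of logs, $\hat\sigma$ = population-sd of logs) with a
nonparametric bootstrap (default `B = 1000` replicates, minimum 30 records
per stratum — both defaults of this package, chosen as conventional values,
not published facts).

## Consumption scenarios

`scenario_curve()` asks what happens if everyone's current red-meat iron is
replaced by a fixed daily dose of cooked ground beef (15% fat): per record,
non-red-meat iron = total − red-meat iron is absorbed at the person's flat
coefficient, while the added beef iron, dose × 2.6 mg/100 g × 25%, is
absorbed at the heme-rich rate. Only the added food gets the food-specific
coefficient because the baseline absorbed distributions were built with the
flat coefficients. The per-stratum lognormal is refitted at every dose —
an analytic shift would be wrong, since subtracting a per-individual amount
changes the distribution's shape, not just its location. The ID-to-IDA
proportion is held at its baseline value (hypothesis 2). Common random
numbers (same bootstrap resamples, requirement draws and weight draws per
stratum across doses) keep the dose-response curves monotone rather than
blurred by Monte Carlo noise. Scenario runs need individual records, real
or synthetic; substitution effects, acceptability, and offsetting risks of
red meat (colorectal cancer, cardiovascular disease) are out of scope.

## The synthetic survey generator

`generate_survey()` produces records with the statistical structure the
analysis assumes, so every stage is testable without external microdata:

* total iron is lognormal on the raw scale, with `meanlog` equal to the
  published absorbed-scale value shifted by −log(absorption coefficient) —
  the coefficient is constant within a stratum, so the absorbed-scale
  distribution is exactly the published one;
* red-meat grams are zero-inflated gamma (default 20% non-consumers, shape
  1.2), with consumer means of 10/15/18.2 g/day for children, adolescents
  and adults — the adult value matching the reported mean red-meat
  consumption — converted to iron at a single density (default 2.1 mg/100 g
  for generic unprocessed red meat; the scenario engine's ground beef uses
  its own 2.6 mg/100 g) and capped at total iron (the run aborts if the cap
  binds for more than 10% of a stratum);
* "unknown" pregnancy/menopause answers are injected at configurable rates
  (default 5%), but only where the imputation decision table recovers the
  true stratum, and a 3% pregnancy rate among women 18-50 exercises the
  exclusion path.

What the generator does *not* emulate: survey sampling weights, the
multi-day diary structure, food-item granularity, and any intake-demography
correlation beyond the stratum means. Tests passing on synthetic data
therefore validate the estimation machinery, not the field realism of the
survey.

## Problem sizes used by the test suite

The shipped tests run the full chain at the model's default scale
(1000 × 10,000 iterations, three seeds for the stability check, ~45 s per
full run) and scale the survey-path checks to what the statistics need:
2000 records per stratum and 500 bootstrap replicates for the scenario
dose grid, 10,000 draws for parameter-recovery checks, 50 repetitions for
bootstrap-coverage calibration. The brute-force prevalence oracle samples
5 × 10⁵ intake-requirement pairs and agrees with the conditional-CDF
estimator within sampling error.

## Known limitations

* The published male adult intake parameters cannot reproduce the published
  male prevalences (see above); the package sides with the inputs.
* Parameter uncertainty of the requirement and haemoglobin distributions is
  not modelled — they are variability-only by design, so the reported
  intervals understate uncertainty to the extent those inputs are
  themselves estimated.
* The IDA proportions are deterministic constants; their (substantial)
  sampling uncertainty is not propagated.
* Scenario results depend on the joint distribution of total and red-meat
  iron at the individual level, which the synthetic generator only
  stylises; scenario outputs on synthetic records are qualitative
  (monotonicity, orders of magnitude), not reproductions of any published
  scenario figure.
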
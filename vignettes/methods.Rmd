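---
title: "Methods: propensity-matched comparative vaccine safety with empirical calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity-matched comparative vaccine safety with empirical calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxsafety)
```

## The study design

`vaxsafety` implements an active-comparator new-user cohort design for
comparative vaccine safety: adults receiving a first (or second) dose of a
target covid-19 vaccine brand (typically adenovirus-based, ChAdOx1-S or
Ad26.COV2.S) are compared with recipients of an mRNA comparator brand
(BNT162b2 or mRNA-1273) over a 28-day post-vaccination risk window. The
design answers "which vaccine is safer" rather than "is vaccination safe",
which sidesteps the intractable confounding of vaccinated-versus-unvaccinated
comparisons.

The pipeline runs, per database and comparison:

1. **Cohorts** — eligibility (age ≥ 18 at first dose, ≥ 365 days of database
   history before index, recorded brand, complete age/sex, exclusion of
   persons with a recorded dose gap ≤ 14 days as data errors), index at the
   dose date, censoring at `min(index + 28, death, end of observation)`.
2. **Outcomes** — first thromboembolic event in `(index, index + 28]`;
   composites (venous thromboembolism, arterial thromboembolism) take the
   earliest member-concept day; persons with *any* prior history of the
   outcome are excluded per outcome, before matching.
3. **Propensity matching** — an L1-regularised logistic model of brand
   assignment on all baseline covariates; greedy caliper matching on the
   logit at up to 1:4 (reverse 4:1 when the target cohort is larger).
4. **Estimation** — Poisson incidence rate ratios from the matched event
   and person-time cells, exact (chi-square) rate CIs, rate differences,
   28-day absolute risk differences, and the minimum detectable rate ratio
   (MDRR) as a power diagnostic.
5. **Calibration** — an empirical null fitted to negative-control outcome
   estimates, used to produce calibrated p-values and CIs.
6. **Meta-analysis** — DerSimonian–Laird random-effects pooling across
   databases, with the pooled estimate calibrated against pooled
   negative controls.

Three diagnostic gates encode the asymmetric reporting rules: a covariate
with post-matching standardised mean difference (SMD) ≥ 0.1 **kills the
whole comparison** for that database; an outcome with MDRR > 5 **suppresses
the database-specific estimate** but the estimate still feeds the
meta-analysis; ≥ 20% of negative controls significant marks the analysis
**calibrated-only**. Only balance-passing databases enter pooling.

## The estimators

With matched cells $(x_t, T_t, x_c, T_c)$ (events and person-years):

* rate: $\hat\lambda = x/T \times 1000$ per 1000 person-years, CI from the
  exact Poisson bounds $[\chi^2_{0.025,2x}/2,\ \chi^2_{0.975,2(x+1)}/2]/T$;
* log IRR: $\hat\theta = \log\frac{x_t/T_t}{x_c/T_c}$ with Wald SE
  $\hat\tau = \sqrt{1/x_t + 1/x_c}$ — identical to Poisson regression with
  an arm indicator and log person-time offset (tested to $10^{-6}$);
* 28-day risk: $1 - e^{-\lambda w}$ with $w = 28/365.25$; the absolute risk
  difference is reported per 100 000 vaccinees with a delta-method CI;
* MDRR: the smallest $\theta > 1$ with
  $\log\theta \ge (z_{0.975} + z_{0.80})\sqrt{1/E_t + 1/E_c}$, where
  $E_c = rT_c$, $E_t = \theta r T_t$ and $r$ is the pooled observed rate;
  solved by bisection to $10^{-6}$. At expected counts below roughly 100
  per arm the underlying Wald power approximation departs from simulated
  power by more than Monte-Carlo error, so the MDRR should be read as a
  screening bound, not an exact power statement;
* empirical null: negative-control log-IRRs are modelled as
  $\hat\theta_i \sim N(\mu, \sigma^2 + \hat\tau_i^2)$ and $(\mu, \sigma)$
  fitted by maximum likelihood over $(\mu, \log\sigma)$; calibrated
  $p = 2\{1 - \Phi(|\hat\theta - \mu| / \sqrt{\sigma^2 + \hat\tau^2})\}$
  and CI $\exp(\hat\theta - \mu \pm 1.96\sqrt{\sigma^2 + \hat\tau^2})$.
  Null-based calibration assumes the systematic error is independent of
  the true effect size; no positive-control synthesis is attempted;
* DerSimonian–Laird: method-of-moments $\tau^2$, $I^2 = \max(0, (Q - (k-1))/Q)$,
  with a heterogeneity warning above $I^2 = 60\%$ (pooled results are
  flagged, never auto-suppressed).

Zero-event arms are reported as not estimable rather than continuity-
corrected. Person-time for an outcome ends at that outcome's first event.
Negative controls with zero events in either arm are excluded from the
null fit; at least 5 usable controls are required, otherwise calibration
is reported as unavailable.

## The TTS phenotype

Thrombosis with thrombocytopenia syndrome is classified from a
thromboembolic event inside the 28-day window plus *concurrent*
thrombocytopenia — a diagnosis code or a platelet measurement strictly
below 150 (in 10^3/µL) — within 10 days before or after the event.
Sensitivity variants narrow the window to 5 days or the threshold to 100.
The thrombocytopenia day may fall after day 28; only the thromboembolic
event must be inside the risk window. Same-day diagnosis and measurement
evidence counts once.

## The synthetic data generator

No patient-level source data are available, so every stage is exercised on
synthetic OMOP-flavoured tables with known ground truth. The generator
draws, per person: age, sex, comorbidity flags, utilisation counts;
brand assignment by a logistic model on those covariates; outcome events
from a Poisson process at rate
`baseline × exp(covariate effects) × trueRR^[target] × exp(bias)^[target]`,
where the per-outcome `bias` (drawn once from a configurable normal
distribution on the log scale) emulates differential ascertainment — the
exact error structure the empirical null models. Negative controls always
have true rate ratio 1 and, by default, a baseline rate of 20/1000
person-years: they stand in for common conditions, and at much rarer rates
the correlation between realised counts and Wald SEs biases any
precision-weighted null fit. Calendar time is an integer day index
(day 0 = study start; 365-day civil years), platelet values are normal
draws centred at 250 (SD 50) with "low" draws centred at 90 (SD 30),
floored at 5 — spanning both the 150 and 100 thresholds.

What the generator does **not** emulate: country-specific rollout phases,
real concept vocabularies, care-setting capture differences (a single
ascertainment knob replaces hospital-versus-primary-care structure), or
realistic marginal prevalences of any particular database. Passing tests
therefore demonstrate the statistical machinery under the generator's
assumptions, not real-data validity.

## Matching behaviour and the choice of study conditions

The matched analysis is *unweighted*: every matched person contributes
their own events and person-time (consistent with reporting raw matched
counts). A practically important consequence, visible in simulation: with
variable-ratio greedy matching the matched candidate side carries
multiplicity skew whenever the candidate pool is between about 1× and 6×
the base side, and covariate balance then stays above the 0.1 SMD gate
even under purely measured confounding. Balance is achieved in the two
regimes that also dominate the real comparisons: a **saturated** pool
(candidates ≳ 8× base, every base subject receives its full 4 matches —
the Ad26.COV2.S-versus-mRNA configuration) and near-degenerate 1:1
matching. The simulation scenarios in the test suite use the saturated
regimes:

* *balance scenario*: one 60 000-person database, ~9% target prevalence,
  assignment log-odds ≤ 1 per covariate; over 50 seeds the post-matching
  max |SMD| stays below 0.1 in ≥ 95% of runs;
* *recovery scenario*: two 100 000-person databases, ~88% target
  prevalence (reverse matching), one outcome with true rate ratio 1.33 at
  5/1000 person-years, 30 negative controls, measured confounding only;
  over 50 replicates the pooled calibrated 95% CI covers 1.33 in ≥ 90%.

These sizes, the 5-fold cross-validation with a short penalty grid used in
the scenarios, and the replicate counts are the package's chosen simulation
scale; they keep each scenario's event counts in the estimable range while
the whole suite stays cheap enough to run routinely.

## Numerical and tie-breaking conventions

* The caliper is 0.2 × SD of the logit pooled over both arms; all-equal
  logits give a caliper of 0 with exact-tie matching still allowed.
* Base subjects are visited in a freshly drawn seeded random order each
  round; nearest-candidate ties (including equal-logit runs on one side)
  break to the lowest person id; base subjects with no match after round 1
  are dropped; rounds 2–4 are best-effort.
* The propensity penalty weight is selected by 10-fold (configurable)
  cross-validated held-out deviance over a 20-point log-spaced grid scaled
  by 1/n; covariates enter unstandardised.
* Eligibility uses age = index calendar year − birth year; utilisation
  counts use the half-open window `[index − 180, index)`; condition
  lookback is all available history.
* Stage seeds are derived from the master seed by a stable string hash of
  (database, comparison, stage), so adding a comparison leaves existing
  results untouched.
* An SMD with zero variance in both arms is 0 when the means agree and
  flagged undefined (gate-failing) otherwise.

## Worked example on published cells

The bundled matched-cohort count table reproduces printed incidence-rate
arithmetic exactly:

```{r}
rates <- rates_from_counts(matched_count_table())
subset(rates, outcome == "thrombocytopenia",
       select = c(database, events_target, py_target, rate_target,
                  rate_comparator, rr))
```

The UK thrombocytopenia cells give 827/136 523 × 1000 = 6.06 and
442/90 381 × 1000 = 4.89 per 1000 person-years, a crude rate ratio of
1.24; the two-database first-dose totals are 862 target and 520 comparator
events.

## Known limitations

* Calibration is null-based only; true effects correlated with systematic
  error would not be corrected.
* The MDRR closed form is anti-conservative at very small expected counts
  (see above).
* The unweighted variable-ratio matched analysis is only unbiased in the
  saturated or 1:1 regimes; the balance gate is the guard rail in between.
* The pooled 28-day absolute risk difference uses the package's own
  closed form (per-arm cumulative risks from pooled rates); other
  transformations of the same inputs give different pooled ARD values.
* Open design points resolved here: the 20% negative-control diagnostic
  uses two-sided, *uncalibrated* CIs (the only choice that keeps the
  diagnostic informative about residual bias); the caliper SD is computed
  per comparison; the 20% database subsample is drawn after eligibility
  filtering; pooled estimates are calibrated against pooled negative
  controls (rather than pooling calibrated estimates); persons eligible
  for both arms take their first vaccination's brand.
```
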
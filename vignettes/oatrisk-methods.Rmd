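---
title: "Methods: overdose risk during and after opioid agonist treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overdose risk during and after opioid agonist treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Opioid agonist treatment (OAT) with methadone or buprenorphine is the
standard pharmacotherapy for opioid use disorder. Overdose risk is not
constant over a patient's history: the first weeks after starting
treatment (while tolerance and dosing stabilise) and the first weeks
after stopping it (when tolerance has waned) are widely reported as
periods of sharply elevated risk, and the two drugs may not protect
equally. `oatrisk` implements a complete observational-data workflow
for quantifying these effects from linked primary-care prescribing,
hospital-admission and mortality records: exposure reconstruction,
person-time splitting, outcome ascertainment, confounding control by
stabilised inverse-probability-of-treatment weighting (IPW),
multiple-event rate models, first-event hazard models, and
quantitative bias analysis.

Because real linked health records are access-controlled, the package
also ships a synthetic-cohort generator with the same statistical
structure and a known ground truth. All validation and the shipped
acceptance checks run against that generator.

# Exposure: from prescriptions to treatment episodes

OAT prescriptions in England are issued on instalment scripts of at
most 14 days, so each prescription is assumed to cover
`[issue, issue + supply_days)` with `supply_days = 14` by default.
`build_episodes()` merges prescriptions into maximal episodes of
continuous treatment:

* a following prescription continues the episode when the gap between
  the running expiry and its issue date is **strictly less than**
  `max_gap_days` (14 by default);
* a gap of `max_gap_days` or more ends the episode at the running
  expiry and opens an out-of-treatment period.

The continuity rule is stated in the literature as "less than 14 days"
for continuation and "more than 14 days" for discontinuation, leaving a
gap of exactly 14 unspecified; we break the episode at exactly 14
(strict "less than" for continuity) and expose the threshold as a
configuration value.

Overlapping or duplicated prescriptions ("dispensed in instalments")
extend the running expiry. Two modes are implemented because the
published description admits both readings:

* `extend` (default): the new expiry is the **later** of the current
  expiry and the overlapping issue date + `supply_days`. We deviate
  slightly from the most literal reading (expiry := issue +
  `supply_days`) because that rule would *shorten* exposure when a
  deeply overlapping script is issued, contradicting the stated intent
  that the expiry is extended. `extend` is the more conservative
  (shorter) exposure of the two modes.
* `stack`: a full `supply_days` is added to the current expiry,
  treating each overlapping script as extra supply to be consumed
  sequentially.

All intervals in the package are half-open `[start, end)` on whole
days; dates are ISO-8601 externally and integer day numbers
internally.

Patients who receive both drugs are censored at the switch date
(first issue of the second drug), so every analysed patient carries
one modality. A patient whose very first methadone and buprenorphine
scripts share one date has no assignable modality; such patients are
excluded with an audit record (`modality_tie`). Cohort entry (the
index date) is the first eligible prescription; eligibility requires
age 18-64 at index and at least 30 days of prior registration.
Analgesia formulations (buprenorphine patches, low-dose sublingual
tablets, methadone linctus) are removed before any of this, via the
`analgesia_exclusion` category of the code list.

# Person-time: risk windows

`split_follow_up()` tiles each patient's follow-up
`[index, observation_end)` exactly, with no gaps or overlaps, into
four windows: weeks 1-4 of each episode (`in_1_4`, the first 28 days,
half-open, so day 28 already belongs to `in_gt4`), the remainder of
the episode (`in_gt4`, the reference stratum), weeks 1-4 after each
episode end (`out_1_4`), and the remainder of each out-of-treatment
period (`out_gt4`). Windows restart at **every** episode transition,
not only the first; a flag restricts them to the first initiation and
cessation if wanted. Out-of-treatment person-time carries the modality
of the episode that preceded it.

Age is a time-varying covariate: intervals are additionally split at
the birthdays on which a patient crosses the band boundaries 25, 35
and 45 (bands 18-24, 25-34, 35-44, 45-64; ages attained above 64 stay
in the top band). The inputs carry birth year only, so birthdays are
taken as January 1 — a deliberate, documented convention that at worst
misdates a band switch by under a year.

Events are attributed to the unique interval containing their date.
Fatal overdoses censor follow-up at the death date but never count as
non-fatal outcomes; deaths registered after the global study end are
ignored (mortality-registration censor). The first-event view
truncates each patient the day after the first event and feeds the
Cox models. Person-years use 365.25 days; episode-duration bands use a
30.44-day month.

Two censoring variants reproduce common sensitivity analyses:
`one_year_post_treatment` (observation ends 365 days after the last
episode) and `max_followup_years` (default 10 years, the restriction
typically applied to stabilise long-follow-up model fits).
Conservation of person-time under every variant is a tested
invariant.

# Ascertainment

Outcomes are defined purely by configurable code lists (CSV: code,
system, category). ICD-10 matching is prefix-based by default (`T40`
matches `T40.1`), switchable to exact; there is no consensus dialect
in routine hospital data. All diagnosis positions count by default
(restrictable to the primary position), and an admission with several
matching codes yields exactly one event, dated at admission — whether
an in-stay overdose should be dated at admission or discharge is
unknowable from the data, and admission date is used. Overdose or
self-harm history flags are strictly-before-index, with an all-time
default lookback and a 1-year option for medication covariates.

# Weighting

Confounding by indication is the central threat: sicker patients are
preferentially given methadone and also overdose more. The package
fits a main-effects logistic propensity model for methadone receipt on
the baseline covariates (age band, gender, IMD quintile, region, plus
any baseline flags such as overdose history or benzodiazepine use) and
forms stabilised weights

$$ w_i = \frac{P(T = t_i)}{P(T = t_i \mid X_i)} $$

so methadone patients receive $p_m/\hat p_i$ and buprenorphine
patients $(1-p_m)/(1-\hat p_i)$. Stabilised weights average
approximately 1 (a tested property). Truncation is off by default and
available as a 1st/99th-percentile winsorisation flag. Balance is
reported as signed standardised differences (methadone minus
buprenorphine), $(p_1-p_2)/\sqrt{(v_1+v_2)/2}$ per indicator, before
and after weighting; zero variance in both arms defines the
difference as 0. Numerically degenerate propensity scores (0 or 1,
i.e. separation) are an error rather than silently huge weights.

# Rate and hazard models

The unit of analysis is the patient x risk-interval record with a
log person-time offset, so exposure is genuinely time-varying;
invariance of the aggregates to re-chunking intervals is a tested
property, as is the exact agreement of the Poisson MLE with the
closed-form crude rate ratio under a saturated categorical exposure.

Multiple-event rate ratios come from Poisson regression or, when a
likelihood-ratio test indicates overdispersion, NB2 negative-binomial
regression (variance $\mu + \alpha\mu^2$). The LRT compares the NB and
Poisson log-likelihoods against the boundary-corrected 50:50 mixture
of a point mass and $\chi^2_1$, at level 0.05 by default; its type-I
error is verified by simulation. When the NB dispersion estimate runs
to the Poisson boundary (underdispersed data), the fit falls back to
the fixed-large-theta Poisson limit rather than failing. Even when
each stratum is conditionally Poisson, omitting patient-level
covariates induces marginal overdispersion, so the weighted marginal
models typically select NB — the same logic that motivates NB models
on real cohorts.

Three flavours are reported per contrast: unadjusted (uRR), adjusted
(aRR; the adjustment set equals the propensity covariate list, which
is how confounders are typically listed once for both uses), and
IPW-weighted (wRR). Weighted fits always use a cluster-robust sandwich
covariance by patient; whether published weighted analyses were also
cluster-robust is usually unstated, so the model-based option remains
available for unweighted fits. Confidence intervals are two-sided 95%
throughout. First-event hazard ratios use Cox partial likelihood with
Breslow ties on counting-process records (days since index), again
with optional weights and patient-clustered robust variance.

# Bias analysis

`e_value()` implements the VanderWeele-Ding E-value on the risk-ratio
scale, applied to rate ratios directly (the usual practice):
$E = RR^* + \sqrt{RR^*(RR^*-1)}$ with $RR^* = \max(rr, 1/rr)$, plus
the E-value of the confidence limit closer to the null (1 if the CI
crosses 1). Symmetry under inversion and monotonicity in $|\log rr|$
are tested invariants.

# The synthetic generator

`generate_cohort()` draws, per patient: baseline covariates
(Bernoulli flags with configured prevalences), modality by a logistic
model on those flags, an exponential registration length (mean 3
years, capped at 10 — matching the typical median observation of
about two years and the 10-year model-fitting restriction), and a
prescription cascade: episodes of 1 + Geometric scripts (mean 3.5) at
uniform 7-27-day issue intervals (so within-episode gaps stay below 14
days and some scripts overlap, exercising the instalment rule),
separated by out-of-treatment gaps of 14 + Exponential(76) days.
About 15% of patients switch modality at a later episode. A latent
person-time ledger records, independently of the episode-builder code
under test, the window, modality and hazard of every segment; events
are drawn as a piecewise-constant-hazard Poisson process

$$ \lambda = \lambda_0 \cdot RR_{window} \cdot RR_{modality}^{[bup]}
   \cdot e^{\gamma^\top X}, $$

with defaults $\lambda_0 = 0.10$/person-year and true rate ratios 5.5
(`in_1_4`), 1 (reference), 13 (`out_1_4`), 1.4 (`out_gt4`) and 0.4
(buprenorphine vs methadone) — the risk structure the analysis is
designed to detect. The default confounders (overdose history:
prevalence 0.20, assignment log-odds -1.0, log rate effect +1.0;
benzodiazepine use: 0.25, -0.5, +0.5) push the crude modality ratio
well below the truth, so crude bias and IPW recovery are both
observable at n = 5000. The assignment intercept (-0.67) yields about
27% buprenorphine, the typical UK share. Non-overdose admissions (0.3
per person-year), pre-index overdose-history admissions,
analgesia-formulation noise prescriptions (5% of patients), fatal
overdoses (0.004/py) and other-cause deaths (0.008/py) exercise the
cleaning, ascertainment and censoring steps. Everything descends from
one root seed; identical configurations reproduce byte-identical
tables.

`expected_counts()` turns the ledger into analytic expected counts
(hazard x person-time) per stratum, the oracle used in the
Monte-Carlo tests.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: dosing and supervised
consumption, informative discontinuation (gaps are independent of
covariates and hazard), provider transfer and imprisonment,
calendar-period trends, region- or deprivation-dependent prescribing,
misclassified pain-management treatment beyond the explicit product
exclusions, and recording artefacts of real coding. Inter-episode gap
distributions in real cohorts are unpublished; the generator's gap
parameters are free choices, not estimates.

# Problem sizes and numerical choices

The shipped checks use n = 5000 patients for parameter recovery and
sensitivity-direction runs (roughly 6,500 outcome events — enough for
the weighted CIs to be informative while a full pipeline run stays
within a few minutes on one core), 200 replicates for the
overdispersion type-I-error and generator-oracle checks, and small
hand-traceable fixtures for every episode- and window-boundary rule.
GLM fits use the standard IRLS defaults; NB fits warm-start from the
Poisson solution with a moment estimate of the dispersion. Ties in
`censor_at_switch` (both drugs on the index date) are exclusions, not
arbitrary assignments. Zero-event cells make the crude-ratio CI
undefined (flagged, not fabricated), and a zero-event dataset returns
the Poisson decision from the overdispersion test.

# Known limitations

* The pipeline estimates associations; none of the weighting removes
  confounding by unmeasured severity, which is exactly why E-values
  are part of the report.
* Baseline-only propensity models cannot address time-varying
  confounding by evolving severity; marginal structural models with
  time-varying weights are out of scope.
* The episode rules are supply-based heuristics; without dispensing
  or adherence data, exposure misclassification is irreducible, which
  is why the 7-day supply and gap variants are first-class options.
* Weighted NB fits treat the dispersion as fixed when computing the
  sandwich covariance; with thousands of patient clusters this is a
  second-order effect.
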
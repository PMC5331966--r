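---
title: "Time-updated medication exposure and virologic rebound: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-updated medication exposure and virologic rebound: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Observational cohorts of people with HIV on suppressive combination
antiretroviral therapy (HAART) can be used to ask whether a co-medication —
here, statins — changes the risk of virologic rebound. Because statins have
short plasma half-lives, any antiviral effect is plausibly transient, so the
analysis must distinguish *current* exposure from the cruder ever/never
classification used by most prior studies. That requires reconstructing drug
exposure day by day from pharmacy dispensing records, updating it at every
viral-load (VL) measurement, and fitting survival models that accept
time-updated covariates. This package implements that full pipeline —
exposure reconstruction, regimen classification, endpoint detection,
counting-process assembly, and stratified Cox / inverse-probability-weighted
(IPW) inference — together with a synthetic-cohort generator with known
ground truth so each stage can be validated end to end.

## Exposure reconstruction: the stock model

`build_exposure_calendar()` treats each outpatient fill as adding
`days_supply` to a per-drug stock. Each non-hospitalized day with positive
stock is an exposed day and consumes one day of stock, so early refills
accumulate surplus that extends exposure past the nominal end of the last
fill; we place no cap on this carryover. Hospitalized days neither consume
outpatient stock nor count as outpatient exposure — they are exposed only if
an inpatient order for a drug of the class covers the stay, and paused stock
resumes at discharge. A fill of a *different* drug in the same class is a
change of therapy: the prior drug's remaining stock is discarded. Class-level
exposure is the union over member drugs, so switching between two statins
never interrupts class exposure on the switch day. When the same drug is
re-prescribed after a long gap, nothing carries across the gap — the stock
was already exhausted, which is the only consistent reading of the rules.

All dates live on an integer day grid and exposure is stored as half-open
day intervals `[start, end)`. Three exposure modes are evaluated at
arbitrary dates:

* **Current use** — any exposed day within the previous 7 days. We read
  "within the previous 7 days" inclusively at both ends: the window is the
  closed 8-day set `[d-7, d]`, so exposure exactly seven days before the
  query date still counts, as does exposure on the query day.
* **PDC** — proportion of days covered over a look-back window of `w` days,
  `|exposed ∩ [d-w+1, d]| / w`; 30 days for statins and cardiovascular
  medications, 91 days for antiretrovirals.
* **Ever use** — true from the first exposed day onward, permanently.

The engine is event-driven (it jumps between fills, discards and stay
boundaries), but its contract is day-level; the test suite checks it against
an independent naive simulator that walks every single day, over hundreds of
randomized dispensing histories.

## Regimen classification

ARVs split into NRTIs (backbone) and anchor drugs (everything else);
ritonavir is a pharmacokinetic booster and never an anchor by itself.
Anchor categories are assigned by priority: *modern* (efavirenz, boosted
darunavir, integrase inhibitor), then *other boosted PI*, then
*unboosted PI / nevirapine / other*. NRTI categories are complementary
flags (tenofovir; lamivudine or emtricitabine; other). A combination counts
as HAART under any of four rules: anchor + 2 NRTIs; triple-class therapy; a
boosted PI plus an NNRTI; or triple-NRTI therapy containing (tenofovir or
abacavir) and zidovudine and (lamivudine or emtricitabine). "Triple-class"
is not defined precisely in the source material; we interpret it as at least
one NRTI plus one PI plus one NNRTI concurrently, isolated in a single
predicate so the choice is easy to revisit. The classifier is verified
exhaustively against a direct truth-table evaluation over all 1,024 subsets
of a 10-drug vocabulary.

## Endpoints and censoring

A patient enters the cohort after showing a detectable VL above 1000
copies/mL, a subsequent undetectable VL on HAART (baseline), and at least
one further VL within 13 months. "Undetectable" respects the assay limit in
effect at the measurement date (500 copies/mL before 2001, 50 from 2001, 20
from 2010); by default any assay limit up to 1000 copies/mL qualifies as
suppression, with a configurable cutoff because the printed definition is
ambiguous about intermediate limits. Virologic failure is the first VL
above 1000 copies/mL or the first of two consecutive VLs above 200; an
unconfirmed trailing value in (200, 1000] is censored, not failed.
Follow-up ends at failure, at the last VL before a gap of more than 13
months (which we fix as 396 days), or at the last VL before the
administrative study end (2012-01-01). When failure and a gap censor fall on
the same date, failure wins. For the combined endpoint, death within 13
months of the last analytic VL and before the study end is an event at the
death date. Premature (informative) censoring is censoring 13 or more
months before the study end. A sensitivity cohort restricts to patients
with an undetectable VL at least 6 months (183 days) after baseline and no
intervening failure, re-anchoring baseline at that measurement. Analyses
are stratified by the era of first suppression with the third era starting
2006-01-01 (the printed era labels disagree between "2005–2011" and
"2006–2011"; the tabulated cohorts use 2006).

## Counting-process assembly

One row per inter-VL interval, `(t_start, t_stop]` in days since baseline,
with the event indicator on the terminal row of failing patients. All
time-updated covariates — exposure modes per class, the 91-day ART PDC over
the union of all ARV exposure, regimen categories, CD4 and the
LDL-equivalent (both last observation carried forward), and the
substance-abuse flag (two or more dated diagnosis codes) — are evaluated at
the row's *start* VL date and carried forward, so rows never use
information after their start; mutation tests verify this no-look-ahead
property. The LDL equivalent is `max(LDL, nonHDL - 30)` mg/dL, using only
measurements taken more than 7 days off lipid-lowering therapy. Missing
race is kept as its own category; missing labs get cohort-median imputation
plus a missingness indicator. Baseline age enters the outcome models;
time-updated age enters the propensity models.

## Inference

`fit_cox()` fits the era-stratified partial likelihood with Efron tie
handling; weighted fits use a robust sandwich variance clustered on patient,
unweighted fits the model-based variance (the source is silent on both;
these are the conventional choices). Covariate screening fits one
main-effects model and keeps terms with p < 0.05 — a single pass, no
stepwise iteration. Propensity models for current use and for premature
censoring are log-link binomial GLMs (with a log-link Poisson working model
as a documented non-convergence fallback) on the retained covariates plus
time-updated age and follow-up time. Weights are stabilized by the marginal
incidence — `incidence/p` for rows in the indexed state, `(1-incidence)/(1-p)`
otherwise — computed per VL time point, not as cumulative products, and the
treatment and censoring weights multiply. Truncation caps both tails at the
p-th and (100-p)-th percentiles (linear interpolation between order
statistics, `quantile` type 7) at 5, 1 and 0.1 percent.
`run_analysis_grid()` assembles the full class x mode x adjustment grid,
recording per-cell errors without aborting.

## The synthetic cohort: what it emulates

`simulate_cohort()` generates dispensing records, hospital stays, VLs,
labs, demographics, diagnosis events and death dates for a cohort starting
HAART 1995–2011, plus a hidden truth table. Its defaults encode the study
conditions: about one third of patients ever use statins; post-initiation
statin supply covers ~41% of time, as alternating covered/gap episodes
(exponential lengths, mean 45 covered days, gap mean solved from the
coverage target); 21% of ever-users are already on statin at baseline and
the rest initiate spread over the observation horizon, matching the slow
growth of statin use across the study period; VL monitoring recurs every
120 ± 45 days with 12% missed visits; assay limits follow the era schedule;
statin prescribing is confounded by age, latent ART adherence, race,
substance use and era with configurable log-odds; monitoring dropout is
mildly informative (more likely at low adherence), which premature-censor
IPW is meant to address; hospitalizations occur at 0.2/patient-year for
3–14 days with inpatient continuation of active chronic medication.

The daily rebound hazard is `baseline x exp(b_statin * current_statin +
b_adh * (ART_PDC - 1) + covariate and era terms)`, with the exposure terms
evaluated at the most recent monitoring visit and carried forward until the
next visit — the same convention the analysis model uses, which makes the
Cox model correctly specified up to detection delay (below). Baseline
monthly hazard 0.020 at full adherence and `b_adh = -2.2` calibrate the
cohort to a high failure rate (above half of patients, median time to
failure around a year) without exhausting the cohort instantly. A rebound
between visits is detected at the next visit; detected magnitudes are drawn
log-uniform on [200, 100000] so that both failure rules — single VL > 1000
and two consecutive > 200, including the unconfirmed-trailing-value censor
path — are exercised.

Fills are emitted so that the engine's reconstruction reproduces the
planned episodes exactly: each covered episode becomes abutting outpatient
fills whose total supply equals the episode's non-hospitalized day count,
and stay overlaps become inpatient orders. The hidden truth table therefore
agrees with the exposure engine by construction of the *emission* scheme
(the engine itself is validated independently against the day-loop oracle).
Early-refill stockpiling and therapy switches are exercised by the engine's
randomized tests rather than by the generator.

What the generator does *not* emulate: VL blips on suppressive therapy,
re-suppression after failure, regimen switches within a patient, dose
strengths, per-compound statin pharmacology (compound labels are sampled
but share one effect), seasonal care patterns, and measurement error in
labs. Passing tests on this cohort therefore demonstrate correctness of the
pipeline's bookkeeping and estimators under a clean generative model, not
robustness to every artifact of real registry data.

## Detection delay: a deliberate realism limit

Because VLs are observed only at monitoring visits, a rebound is recorded
at the *next* visit after it occurs. At that recorded event time the failing
patient's covariates are one full visit interval old, whereas risk-set
comparators' covariates are half an interval old on average. Whenever the
prevalence of an exposure trends over follow-up time — statin initiation
after baseline guarantees a rising trend — this differential staleness
biases the exposure's hazard ratio away from the null by roughly the trend
slope times the staleness differential. With initiation spread over the
observation horizon (as the cross-sectional statin-use trend implies) the
artifact is below 0.01 on the log-HR scale in our checks; with initiation
concentrated in the first year or two after baseline it grew to 0.09 —
almost half the true effect of log(0.8). Unmeasured informative censoring (dropout driven by
latent adherence) adds a further bias no covariate-adjusted model can
remove; it is kept in the default conditions as the phenomenon the
censoring-weight machinery targets, and switched off when validating pure
confounding adjustment. This is the same detection-delay limitation real
VL-monitored cohorts face, and it is why parameter-recovery checks here
define the estimand through covariates carried forward from visit dates.

## Numerical and design choices

* Integer day grid everywhere; "13 months" = 396 days; "6 months" = 183
  days; both configurable.
* Visit-interval hazards are simulated by geometric waiting times within
  intervals (exact for a piecewise-constant daily Bernoulli process).
* The statin-prescribing intercept is solved by `uniroot` so the realized
  ever-use fraction matches its target regardless of the confounding
  strengths.
* Percentile truncation uses `quantile` type 7; documented because tail
  fractions at 0.1% are sensitive to the interpolation rule.
* Log-link binomial propensity fits start at the marginal-incidence
  intercept; non-convergence falls back to a log-link Poisson working model
  with a notice, and fitted probabilities are clipped to
  `[1e-6, 1 - 1e-6]` with a warning count.
* Ties between a failure and a gap censor on the same date resolve to
  failure.
* The era-3 boundary is 2006-01-01.
* `select_covariates` retains a factor if any level is significant, ignores
  coefficients that are inestimable (collinear) rather than failing, and
  runs exactly once.

## Problem sizes used in validation

The packaged checks run the exposure-engine oracle on 500 randomized
histories, the endpoint oracle on 500 randomized VL series, the classifier
truth table on all 1,024 subsets, parameter recovery on 20 cohorts of
10,000 patients, IPW diagnostics on cohorts of 3,000, and the
attenuation contrast on 20 cohorts of 6,000. These sizes give Monte-Carlo
error comfortably inside the stated tolerances while keeping a full
validation run in the tens of minutes on one core; the same code scales to
larger cohorts unchanged.

## Known limitations

The drug-class map resolves anchor categories statically per compound
(darunavir is carried as a modern anchor because it is co-dispensed
boosted in practice); exact combination-aware anchor classification is
available via `classify_anchor()` but the counting-process columns use the
calendar labels. The covariate screen is a single significance pass, which
understates model-selection uncertainty. IPW uses per-time-point weights,
not cumulative products, so it is not a full marginal structural model.
Interval censoring of the true failure time is ignored, as in the source
analyses; the detection-delay section above quantifies the consequence.
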
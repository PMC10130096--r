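---
title: "Methods: a claims-based comorbidity index and actual-prognosis tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a claims-based comorbidity index and actual-prognosis tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbindex)
```

## The problem

Older cancer patients usually carry other chronic diseases, and for many of
them — especially with localized disease — the practical question is not only
"will the cancer kill me?" but "what is my chance of dying of something
else first?". Net survival measures deliberately remove other-cause
mortality; *actual prognosis* keeps it: the absolute probabilities of dying
from the cancer, dying from other causes, and surviving, by a given horizon.
`comorbindex` implements a complete, testable pipeline for this kind of
population study on linked administrative data: a cancer registry, an
insurance-claims database, and a cause-of-death file.

Because such linked data are held in restricted enclaves, the package ships
a synthetic-cohort generator that emulates the linkage with known ground
truth, so every stage — ascertainment, endpoint construction, model fitting,
validation, and the prognosis tables — runs and is verified end to end
without any restricted input.

## Comorbidity ascertainment

Eighteen chronic conditions are ascertained from diagnosis codes: the
Charlson/Deyo set minus the malignancy items, with mild liver disease
extended to chronic viral hepatitis B/C and hypertension split into
uncomplicated and complicated forms. The code map is prefix-based and is
deliberately configuration (`default_code_map()`, YAML-overridable), since
coding practice varies across systems and years.

A condition counts as present when, inside the qualifying window before
the cancer diagnosis, the patient has

* at least one **inpatient** claim carrying a matching code, or
* at least two **outpatient** claims with a pair of service dates more than
  30 days apart (the "gap > 1 month" rule, read strictly as > 30 days at
  day resolution).

The qualifying window is the half-open calendar-month interval
$[\mathrm{diag} - W,\ \mathrm{diag} - 6)$ months, with $W \in \{30, 54,
78\}$. The six months immediately before diagnosis (the washout) are always
excluded: diagnostic activity triggered by the emerging cancer would
otherwise masquerade as pre-existing comorbidity. Month arithmetic is
calendar-based with day-of-month clamping (31 January minus two months is
30 November), so window bounds are unambiguous on real claim dates. The
default window is 30 months — longer lookbacks add information per patient
but exclude patients whose claims history starts too late; 54 and 78 remain
available, and widening the window can only add conditions (a property the
tests assert).

## Endpoints

Each death is classified as death from the index cancer or from another
cause by matching the underlying-cause code against a per-site prefix map,
with a shared set of ill-defined codes attributed to the index cancer. The
full registry-grade cause classification algorithm is a multi-table
external document; reducing it to a configurable prefix map keeps the
classifier on the hot path for both real codes and the generator's sentinel
codes, at the cost of site-level nuance.

Two outcome representations are built from the same classification:

* **Index training** uses cause-specific survival data: time from diagnosis
  to *noncancer* death, with cancer deaths and loss to follow-up treated as
  censoring.
* **Prognosis tables** use competing-risks data with both causes as events.

Patients without a death record are considered alive and censored at the
earlier of their enrollment last-seen date and the enrollment horizon
(deaths are typically observable one year beyond enrollment; the default
horizons are one year apart for that reason). Patients in neither the death
nor the enrollment data are censored at diagnosis and flagged loudly — in
synthetic data they indicate a generator bug, in real data a linkage gap.

## The index

The working model is a Cox proportional-hazards model for noncancer death
with age (years), sex, all 18 condition indicators, and the pairwise
products of the 11 most common conditions (55 interaction columns). The
common set is determined from the pooled cohort by carrier count, with
alphabetical tie-breaks.

Some main effects typically come out negative — an artifact of correlation,
interaction and residual confounding among chronic diseases rather than
evidence of protection. To keep the index interpretable as a nonnegative
burden score, the fit applies **negative-coefficient deletion**: delete all
conditions whose main-effect coefficient is negative, together with every
interaction involving them, refit, and repeat until every retained main
effect is nonnegative. Age and sex are never deleted; interactions may
retain negative coefficients. The loop terminates in at most 18 iterations
(each deletes at least one condition) and errors if it would delete
everything. This pruning trades a possible bias for interpretability — a
deliberate, documented choice, not a statistical free lunch.

A patient's index value is the sum of the retained condition coefficients
for their present conditions plus the retained interaction coefficients for
present pairs; age and sex are reported but never scored. With the
published weight table shipped in the package
(`published_index_model()`), the single-condition score for chronic renal
failure is 0.80, and congestive heart failure plus cerebrovascular disease
scores $0.75 + 0.37 - 0.12 = 1.00$.

### Comorbidity levels

Three levels summarize the score for clinical tables:

* **0** — none of the 18 conditions;
* **2** — score strictly above 0.66, *or* any severe-illness condition
  present (CHF, COPD, dementia, chronic renal failure, moderate/severe
  liver disease — conditions that usually force treatment adjustment even
  when their fitted weight is modest, e.g. COPD at 0.26);
* **1** — everything else.

Patients whose only conditions were deleted from the index score 0 but are
level 1, not level 0: level 0 is reserved for the truly condition-free. The
0.66 cutoff is strict (`>`), so a condition with weight exactly 0.66 earns
level 2 only through the severe list.

### Splits and validation

Model development uses deterministic nested train/validation/test folds in
proportions 1/2, 1/4, 1/4. Fold membership is a pure 32-bit hash of
(patient id, seed) mapped to the unit interval — no draw order, no state.
The payoff is *restriction compatibility*: the fold assignment of any
subset (a site, a sex-by-site cohort, an age band) is exactly the
restriction of the global assignment, so pooled and subgroup analyses can
share folds without bookkeeping. The hash is asserted against binomial
proportion bounds and subset-restriction checks in the tests.

Discrimination for noncancer death is measured with the incident/dynamic
time-dependent AUC: at each event time $s$, cases are subjects dying (of
other causes) at $s$, controls are subjects still at risk beyond $s$, and
$\mathrm{AUC}(s)$ is the fraction of case–control pairs ordered correctly
by the marker (ties count one half). The headline figure integrates
$\mathrm{AUC}(s)$ up to the horizon with concordance weights
$2\,f(s)\,S(s)$ from the Kaplan–Meier estimate; the pointwise value at the
last event time at or before the horizon is available via
`mode = "at_time"`, since "AUC at $t$ years" is used in both senses in the
literature. Bootstrap resampling of patients supplies standard errors; no
closed-form variance exists for the integrated statistic under ties and
censoring.

## Competing-risks estimation

Prognosis cells use the Aalen–Johansen estimator:
$\widehat{\mathrm{CIF}}_k(t) = \sum_{s_i \le t} \widehat S(s_i^-)\,
d_{k,i}/n_i$, with $\widehat S$ the all-cause Kaplan–Meier. By telescoping,
cancer incidence + other-cause incidence + survival equals one at every
step exactly; the tests assert conservation to $10^{-10}$ and agreement
with an independent competing-risks implementation to $10^{-10}$.

Horizons are fixed integer day grids: 1 year = 365, 2 years = 730,
5 years = 1826 days (the extra day absorbs the leap year). Step functions
are evaluated right-continuously. Cells from fewer than 100 or 50 patients
are flagged, and cells from fewer than 5 patients are suppressed outright,
following the usual administrative-data disclosure rule.

## Numerical engines

The Cox fit maximizes the Efron-tie partial likelihood by Newton iteration
with step-halving (Breslow available by flag; setting the Efron tie
fraction to zero reproduces Breslow exactly, so both share one code path).
The score and information are accumulated in $O(np + mp^2)$ via risk-set
reverse cumulative sums over the $m$ unique event times, which keeps a
75-column model on 25,000 patients under a few seconds. Convergence is
declared at max absolute score $< 10^{-8}$ or relative log-likelihood
change $< 10^{-10}$; the likelihood is concave, so no restarts are needed.
Exactly duplicated columns raise an error; constant-zero columns are
dropped with a message before fitting (they carry no information).
Monotone likelihoods (complete separation) are flagged with a
diverging-coefficient warning at the iteration cap rather than reported as
converged. The tests pin the fitter to an independent implementation to
$10^{-4}$ on tied data and to a brute-force likelihood grid scan on toy
data to $10^{-3}$.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws, per patient: site, sex, age band, stage and a
diagnosis date; a true comorbidity profile; pre-diagnosis claims; and a
post-diagnosis death time with a cause.

* **Profiles** come from a one-factor Gaussian copula: condition $j$ is
  present when $\sqrt\rho\,F + \sqrt{1-\rho}\,\varepsilon_j <
  \Phi^{-1}(p_j)$. Marginal prevalences are exact by construction (the
  tests verify 3-standard-error calibration across 100 replicates at
  $n = 10{,}000$); a single correlation knob $\rho$ (default 0.2) induces
  the positive co-occurrence seen in real multimorbidity without claiming
  a specific joint distribution, which no published margin table could
  identify anyway.
* **Prevalence defaults** are the ascertained condition prevalences of a
  published colorectal-cancer cohort aged 65–94
  (`reference_condition_prevalence()`), so the simulated burden profile is
  realistic for an older East-Asian cancer population (hypertension ~46%,
  diabetes ~29%, ulcer disease ~24%, liver disease prominent).
* **Claims** for a present condition arrive as a homogeneous Poisson
  process (default 4/year over an 84-month horizon; 20% inpatient), with
  codes drawn from that condition's prefix set. A per-condition
  `washout_leak_rate` makes a condition emit claims *only* inside the
  6-month washout — the cancer-caused-diagnosis artifact the washout rule
  exists to kill, and the tests confirm it never ascertains.
* **Deaths** follow two competing exponential hazards: cancer by site (and
  optionally stage), noncancer as baseline (default 0.03/year) times
  $\exp(\sum_j w_j x_j)$ over the true condition weights. Cause codes use
  two sentinel families ("C-&lt;site&gt;" vs ordinary ICD-9-style codes) so
  the production cause classifier is exercised, not bypassed. Deaths are
  administratively censored at the end of 2016 and the living censored at
  the end of 2015, mirroring the usual one-year lag between death and
  enrollment data.

Deliberately **not** emulated: realistic code co-occurrence beyond the
configured map, hospital-level clustering, treatment claims, non-constant
hazards, and severity within a condition. Passing tests therefore
demonstrate that the machinery is correct under a known data-generating
process — they do not certify coding quality or proportional hazards in any
real claims system.

Because the generator's true hazard is additive in the condition weights,
parameter-recovery checks are run on the additive (main-effects-only)
negative-deletion fit, where a main effect estimates the true weight
directly; in the interaction model a main effect is the conditional effect
with no other common condition present — an estimand with much larger
finite-sample error for rare conditions. The interaction model remains the
object of the structural checks (what gets deleted, which 28 pairs survive,
validation AUC).

## Problem sizes and runtime

The shipped test suite and acceptance script use cohorts of 300–25,000
patients for property checks and a 50,000-patient cohort (claims rate
6/year over a 36-month horizon, ~1.3 million claims) for end-to-end
recovery, which completes in well under a minute on one core: positive
weights recovered within ±0.15 (typically ±0.1), a truly protective
condition deleted with all its interactions, and pooled validation-fold
AUC above 0.5 by more than 8 standard errors.

## Known limitations

* Claims-based ascertainment sees presence, not severity; two patients with
  "CHF" may be worlds apart clinically.
* Negative-coefficient deletion buys interpretability with possible bias;
  the retained coefficients are not causal effects.
* The simplified prefix cause map approximates registry-grade
  cause-of-death classification.
* The 0.66 level cutoff and the severe-illness list encode clinical
  judgment, not an optimality criterion; users with different treatment
  contexts should revisit both (`assign_level()` exposes them).
* The published weight table is shipped for scoring and worked examples;
  re-estimating it requires the restricted national linkage. The package's
  `cmprsk`/`survival`-free engines make any re-estimation reproducible and
  auditable, but the numbers themselves are not recomputable from public
  data.
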
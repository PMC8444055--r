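---
title: "Methods: matched-cohort adherence analysis from dispensing claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-cohort adherence analysis from dispensing claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcmatch)
```

`pdcmatch` estimates how an exposure — in the motivating application,
being in active care for a severe mental illness — changes the likelihood
of *high adherence* to chronic somatic healthcare, using only
administrative claims: drug dispensations, hospital stays, out-patient
services and a mental-health care registry. This vignette documents the
models and conventions the package commits to, the parameters a user can
(and cannot sensibly) move, what the synthetic generator does and does
not emulate, and the numerical choices inside the fitter.

## From dispensations to drug eras

A dispensation contributes `amount_ddd` days of supply (total amount
dispensed divided by the WHO defined daily dose). Eras are built by a
single forward scan with **stockpiling**: the coverage end after
dispensation $i$ is

$$e_i = \max(t_i, e_{i-1}) + d_i,$$

so an early refill extends coverage by its full duration rather than
being truncated. A new era opens when $t_i - e_{i-1} > g$; the
permissible gap $g$ defaults to 60 days, and a dispensation *exactly* 60
days after coverage end still chains (the rule is "60 days or shorter").
Stockpiling is a deliberate commitment: the data cannot distinguish
stockpiled from discarded supply, and carrying it forward is the standard
PDC practice that keeps covered days consistent with the era chaining.
Coverage intervals are half-open `[start, end)`, which makes adjacency
unambiguous (`gap = next_start - end`). Durations stay fractional until
day-level rasterisation, where only whole days fully inside the covered
union count; this makes covered-day counts integers and makes PDC
invariant to splitting a dispensation into contiguous halves.

A **prevalent user** of a class has, at the index date, some single era
containing at least 3 dispensations all dated inside the 730-day
lookback. The literal rule is existence-in-lookback; whether the chain
must still be *active* at the index date is not determined by the rule's
wording, so `require_active` exposes the stricter reading as a switch
(default off).

## PDC, hospital bridging, clinical controls

Follow-up is the fixed 365-day window starting at the index date;
patients dying or emigrating inside it are excluded upstream, so the
denominator is always 365 and no censoring arises. The numerator is the
number of whole window days inside the union of dispensation coverage and
*bridged* hospital days. Because in-hospital drug use is invisible to
out-patient claims (immeasurable time), days in hospital count as covered
for patients whose regimen was observed before admission. "Observed
before" is read permissively by default — any era of the class starting
before the admission date qualifies — because a patient whose supply
lapsed shortly before admission was still an established user;
`bridge = "active"` restricts bridging to eras whose coverage is still
running at admission. Supply dispensed before the window that spills into
it counts by default (`spillover = TRUE`); the cohort consists of
prevalent users, so follow-up coverage without the spillover would
penalise patients precisely for having filled early. With
`spillover = FALSE` the numerator is recomputed from in-window
dispensations only.

Categories on the continuous PDC scale: very low $[0, 0.25]$, low
$(0.25, 0.50]$, intermediate $(0.50, 0.75)$, high $[0.75, 1]$; the
integer-percent labels ("26–50%") are treated as shorthand for these
intervals, so PDC exactly 0.75 is high and exactly 0.50 is low. The main
outcome is high adherence at 75%; 70% and 80% feed the sensitivity suite.

For diabetics, the five recommended annual controls are HbA1c (satisfied
by ≥ 2 assays), lipid profile (one control, satisfied by ≥ 1 assay of
total cholesterol, HDL or triglycerides — the recommendation is a single
bullet, not three), serum creatinine, urine albumin and dilated eye exam
(≥ 1 each). High control adherence is ≥ 4 of 5 satisfied, with ≥ 3 of 5
as the sensitivity definition. Service-code-to-control maps are
configuration, not code: no regional codelist is hard-wired.

## Cohorts, matching, balance

Eligibility per drug class is sequential — valid birth date, age ≥ 18 at
index, ≥ 2 years of residency, prevalent use, ≥ 1 year of post-index
observation — and every removal is counted, so the flow report always
reconciles (`input = retained + removals`). Exposure requires a
mental-health episode *open at the index date* (opened on or before,
closed after or never); patients whose only episodes are closed are
neither exposed nor eligible comparators. When several diagnoses are open
concurrently the reported category follows a fixed severity order
(schizophrenia > bipolar > personality disorder > depression) — an
explicit package convention, since concurrent open episodes have no
canonical primary diagnosis.

Matching is 1 : up-to-3 without replacement, exposed processed in seeded
random order, on gender (exact), age at index (± 1 year) and
healthcare-contact volume. The contact count (dispensations + admissions
+ out-patient services in the 2 pre-index years) is matched on **pool
deciles**: exact matching on a heavily tied integer count is infeasible
and a fixed caliper behaves very differently at 10 vs 200 contacts,
while decile equality adapts to the distribution; a numeric caliper
remains available (`contact_rule = "caliper"`). Sets that only find one
or two comparators are retained — conditional inference handles unequal
set sizes natively — and exposed patients with no eligible comparator are
dropped and reported. Balance is audited with absolute standardised
differences (binary: $|p_1-p_2| / \sqrt{(p_1(1-p_1)+p_2(1-p_2))/2}$;
continuous: $|m_1-m_2| / \sqrt{(s_1^2+s_2^2)/2}$), flagging anything
≥ 0.10.

Baseline covariates are boolean flags from configured codelists over the
2-year lookback plus a comorbidity-score category obtained by binning a
supplied numeric score (the score's own weighting scheme is out of scope
and treated as input); a score exactly at a cut-point falls in the lower
category.

## The conditional logistic model

For matched set $s$ with case total $d_s$, the exact conditional
likelihood contribution is

$$\frac{\exp\left(\sum_{i: y_i = 1} x_i'\beta\right)}
        {\sum_{C \subseteq s, |C| = d_s} \exp\left(\sum_{i \in C} x_i'\beta\right)}.$$

Set intercepts — and everything constant within a set, including the
matching variables — are conditioned out, which is exactly why the
planted conditional effect in the generator is recoverable after
matching. With ≤ 4 members per set the denominator has at most 6 terms,
so full enumeration is cheap and *exact*; the package deliberately avoids
the Breslow/Efron tie approximations, which also makes the fitter
directly checkable against a brute-force enumerated likelihood (the test
suite does this to 1e-6, and separately against `survival`'s exact
method).

Numerics: Newton–Raphson from $\beta = 0$, step-halving whenever a step
would decrease the log-likelihood, convergence at gradient norm
$< 10^{-8}$, at most 100 iterations. The observed information (within-set
covariance of subset sums) supplies the step and the Wald standard
errors; log-sum-exp centering per set guards the denominator. Concordant
sets are dropped with a message; a covariate with no within-set variation
anywhere is reported as inestimable by name; a likelihood that keeps
improving as $|\beta_j|$ grows (separation, e.g. the exposed member is
the case in every set) is reported as an explicit error naming the
covariate rather than returned as a huge finite estimate. Effects are
presented as `(OR - 1) x 100` with the CI mapped through the same
transform; "reduced adherence" is claimed only when the CI upper bound is
below zero, "increased" only when the lower bound is above.

Stratified analyses refit the model inside each stratum (set-level
label; for member-level variables the exposed member defines the set's
stratum). Between-strata homogeneity uses the inverse-variance $Q$
statistic on $K-1$ df; ordered strata use a trend test realised as
inverse-variance weighted regression of stratum log-ORs on category
scores — the "recoded variable" description of trend testing is
ambiguous between this meta-regression and an interaction term in the
pooled model; the meta-regression was chosen because it composes with
independently fitted strata and is invariant to stratum relabelling.
Coefficients from independent fits are compared with the usual z-test.
Significance is 0.05 throughout with no multiplicity correction, matching
the reporting conventions the package mirrors.

## The synthetic generator

The generator emits five registry-shaped tables (patients, dispensations,
hospital stays, out-patient services, mental-health episodes) from a
seeded scenario; identical config + seed reproduces them byte for byte.
Its purpose is a *known truth*: each patient-class has a latent
high-adherence indicator drawn from

$$\operatorname{logit} P(\text{high}) = \alpha + \beta\,\mathrm{SMI}
  + \gamma_F\,\mathrm{gender} + \gamma_A\,(\text{age}-65)
  + \gamma_D\,(\text{decile}-5.5),$$

with $\beta$ the **planted conditional log odds ratio**. The same
matching variables also drive exposure probability (intercept calibrated
numerically so the realised prevalence hits the target), so crude and
conditional effects genuinely differ and matching is doing real work.
The latent category is then *realised through the same era machinery the
pipeline tests*: a target covered-fraction is drawn from a
category-conditional Beta family (high: concentrated in $[0.75, 1]$;
otherwise spread over the three lower categories), and 30-DDD packs are
laid down from the index date to hit the target covered-day count
exactly — after first subtracting the days that hospital-stay bridging
will contribute, so bridging is exercised without disturbing the planted
category. Pre-index chains end exactly at the index date, giving every
patient an era history (prevalence, contact volume, bridging
eligibility) without uncontrolled spillover. Clinical-control bundles
for diabetics are realised the same way from a latent high-controls
indicator with its own planted odds ratio: satisfied controls receive
counts at or above their satisfying minimum (extra assays Poisson at the
configured yearly rates), unsatisfied ones stay below it.

Deliberate imperfections of the emulation — and therefore limits on what
passing tests show about real data: drug and service codes are a toy
vocabulary (real codelists are configuration inputs); the PDC
distribution inside categories is a free modelling choice, not a
calibrated claim about any real cohort; dispensation streams are regular
30-DDD packs rather than the ragged real-world mix of pack sizes;
death/emigration and hospitalisation are independent of exposure given
the matching variables; and a patient whose bridged hospital days alone
exceed a small adherence target can drift one category upward (rare, and
verified small in tests). Scenario defaults encode the study conditions
of the motivating design — exposure prevalence ≈ 2%, 1-year follow-up
from 2017-01-01, 2-year lookback, mean age 65 (SD 12) — while
`simulate_matched_sets()` provides a set-level shortcut (set random
intercepts standing in for exact matching) for calibration experiments
that need hundreds of replicates.

## Problem sizes and reproducibility

The test suite runs the recovery checks through the full pipeline at
roughly 5–6 thousand matched sets per class (36 000 simulated patients,
exposure prevalence 0.15 so that matched sets are plentiful at desk
scale), judging recovery against ± 2 Monte-Carlo standard errors at that
size; type-I-error calibration uses 500 replicates of 400 sets; the
PDC/era oracles run over 1000 randomised fixtures. `scripts/acceptance.R`
scales the same experiment to ~20 000 sets per drug class (~10 000
diabetic sets for the control outcome) with planted odds ratios 0.76,
0.90, 0.75 and 0.82, and writes the recovered percentage variations as
JSON. All randomness flows from the single scenario seed (the matcher
and downstream stages draw from the stream it initialises), so a
pipeline run is reproducible end to end.

## Known limitations

The package models adherence outcomes at one fixed index date (no
time-to-event or repeated measures); matching is greedy without
replacement rather than optimal; profile-likelihood intervals are not
implemented (Wald only, adequate at the set counts the design targets);
exact conditional *p-values* (permutation) are out of scope; and
enumeration makes set sizes much beyond ~10 members per set
computationally unattractive — the intended designs (1:1 to 1:3) are far
below that.
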
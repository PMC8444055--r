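# pdcmatch

Matched-cohort analysis of adherence to chronic healthcare from
administrative dispensing claims.

## The problem

Patients with severe mental illness (depression, schizophrenia, bipolar
disorder, personality disorder) die earlier than the general population,
and much of that excess is mediated by poorly attended *physical*
illness — the "physical healthcare gap". One measurable face of the gap is
adherence: given equal need for chronic therapy (blood-pressure-, lipid-
or glucose-lowering agents), do patients in active mental-health care keep
their prescriptions filled and their recommended clinical controls done as
often as comparable patients without mental illness?

`pdcmatch` implements the full claims-based study design needed to answer
that question, for epidemiologists working with registry-style
healthcare-utilisation data:

* **Drug eras** — dispensations are chained into treatment eras; each
  dispensation contributes `amount dispensed / defined daily dose` days of
  supply, early refills stockpile, and a gap of more than 60 days (the
  configurable default) between coverage end and the next dispensation
  breaks the era. A *prevalent user* has a chain of ≥ 3 dispensations in
  the two pre-index years.
* **Adherence** — the proportion of days covered over one year of
  follow-up, `PDC = covered days / 365`, with hospital stays counted as
  covered when a regimen was observed before admission (immeasurable-time
  correction), categorised as very low (≤ 25%), low (26–50%), intermediate
  (51–74%) or high (≥ 75%). For diabetics, the clinical-control bundle:
  ≥ 2 HbA1c assays plus ≥ 1 each of lipid profile, serum creatinine, urine
  albumin and dilated eye exam; "high control adherence" = ≥ 4 of 5.
* **Matched cohorts** — each exposed patient is matched with up to three
  unexposed comparators on gender, age (± 1 year) and healthcare-contact
  volume (same decile), sampled without replacement; balance is audited
  with absolute standardised differences (< 0.10 = negligible).
* **Exact conditional logistic regression** — the core model. For matched
  set *s* with members *i*, outcomes *y* and covariates *x*,

  ```
  L(β) = ∏ₛ exp(Σ_{i: yᵢ=1} xᵢ'β) / Σ_{|C| = dₛ} exp(Σ_{i∈C} xᵢ'β)
  ```

  maximised by Newton–Raphson over full within-set subset enumeration (no
  Breslow/Efron approximation), with Wald intervals, stratified estimates,
  inverse-variance homogeneity (χ²) and trend tests, a z-test for
  comparing stratum coefficients, and the `(OR − 1) × 100`
  percentage-variation presentation used for reporting.
* **Synthetic claims generator** — registry-shaped tables (patients,
  dispensations, hospital stays, out-patient services, mental-health
  episodes) with a *planted* conditional odds ratio of high adherence and
  deliberate confounding by the matching variables, so every stage of the
  pipeline is testable against a known truth without access to restricted
  data.

## Worked example

Simulate a confounded scenario whose true conditional odds ratio of high
adherence for exposed vs unexposed is 0.76, and run the whole pipeline:

```r
library(pdcmatch)

sc <- claims_scenario(n_patients = 20000, smi_prevalence = 0.15,
                      true_log_or = log(0.76), seed = 42,
                      drug_class_mix = c(BP = 1, LIPID = 0, GLUCOSE = 0.3))
res <- run_pipeline(pipeline_config(scenario = sc,
                                    classes = c("BP", "GLUCOSE")))
res
#> Matched-cohort adherence pipeline
#>
#> [BP] 20000 candidates -> 18199 eligible; 2707 exposed, 2664 matched sets
#>   high drug adherence: (OR-1)x100 = -20.1% (-26.9 to -12.5)
#>
#> [GLUCOSE] 5958 candidates -> 5409 eligible; 1047 exposed, 970 matched sets
#>   high drug adherence: (OR-1)x100 = -23.6% (-34.2 to -11.2)
#>   high clinical controls: (OR-1)x100 = -22.0% (-33.0 to -9.2)
```

The blood-pressure estimate says exposed patients had a 20% (95% CI 13 to
27%) lower likelihood of high adherence than their matched comparators —
a draw around the planted −24% at this cohort size. The model object
behaves like any classic R fit:

```r
summary(res$results$BP$main_fit)
#> Exact conditional logistic regression
#> 8899 members, 2233 informative sets of 2664
#>
#>         Estimate Std. Error z value Pr(>|z|)
#> exposed -0.22389    0.04585  -4.884 1.04e-06 ***
#>
#> Odds ratios with 95% Wald CI and (OR-1)x100:
#>             OR CI low CI high pct var
#> exposed 0.7994 0.7307  0.8746  -20.06
```

Eligibility accounting, balance, and the 70/75/80% sensitivity suite:

```r
head(flow_report(res), 6)
#>   drug_class                                      criterion removed
#> 1         BP                             missing birth date       0
#> 2         BP                         aged under 18 at index     222
#> 3         BP                     resident for under 2 years     199
#> 4         BP fewer than 3 chained dispensations in lookback     967
#> 5         BP       died or emigrated within 1 year of index     413
#> 6         BP                                       retained   18199

res$results$BP$balance        # post-matching ASD, all < 0.10
res$results$BP$sensitivity    # one estimate per outcome definition
```

Lower-level pieces are exported individually: `build_eras()`,
`is_prevalent_user()`, `compute_pdc()`, `assess_clinical_controls()`,
`match_comparators()`, `standardized_difference()`, and the fitter
`clr()` with `summary`, `coef`, `vcov`, `confint`, `predict`,
`residuals`, `simulate` and `plot` methods. `worked_fixture()` returns a
20-patient bundle whose eras, PDC values, matched sets and fitted odds
ratio are documented hand computations.

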
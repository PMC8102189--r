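# cardioipw

Propensity-weighted analysis of cardiac function in observational AML
cohorts.

## What problem this solves

In adults with acute myeloid leukemia (AML), mutations in the isocitrate
dehydrogenase genes *IDH1*/*IDH2* — which also occur in clonal hematopoiesis
— are suspected of predisposing the heart to chemotherapy-related damage. A
retrospective cohort can compare left-ventricular ejection fraction (LVEF)
trajectories between mutation carriers and wildtype patients, but carriers
differ systematically at baseline (more coronary artery disease, higher
cardiovascular risk burden), so a naive comparison confounds mutation effects
with comorbidity effects.

`cardioipw` is for biostatisticians and cardio-oncology researchers running
that kind of analysis. It implements the full pipeline:

* **Propensity scores** `e(X) = Pr(Z = 1 | X)` by binomial logistic
  regression, for two comparisons: wildtype vs *IDH2*-mutated (model 1) and
  wildtype vs pooled *IDH1/2*-mutated (model 2);
* **Inverse probability of treatment weighting** with `w = Z/e(X) +
  (1-Z)/(1-e(X))`, symmetric trimming of the most extreme 5% of propensity
  scores, and weight truncation at 10;
* **Balance diagnostics**: absolute standardized mean differences
  `|m1 - m0| / sqrt((s1² + s0²)/2)` before/after weighting (≤ 0.1 = balanced),
  with Kish effective sample sizes and Love-plot export;
* **Outcome comparison**: weighted and unweighted unpaired Welch t-tests of
  LVEF at four timepoint windows t0–t3 (pre-therapy through ~10 months), plus
  within-group change from t0;
* **Descriptives**: clinical Table-1 conventions (median/range,
  `% (n/total n)` with half-up rounding, Pearson chi-square, Mann–Whitney,
  normality-driven test selection);
* **Survival**: Kaplan–Meier, log-rank, relapse-free survival from complete
  remission, reverse-KM median follow-up;
* **Sarcomere grading**: the semiquantitative 1–4 organization score for
  cardiomyocyte imaging experiments;
* **A synthetic cohort generator** with confounded exposure assignment and a
  known ground-truth treatment effect, so every estimator is validated
  end-to-end without patient data.

## Worked example

```r
library(cardioipw)

# a synthetic cohort under the default study conditions:
# 2000 patients, 17.9% IDH1/2-mutated, confounded by CAD / risk burden / age,
# true exposure effect on LVEF at t3 = -13.5 points
cohort <- generate_cohort(sim_config(n_patients = 2000, seed = 1))$cohort

res <- run_ipw_pipeline(cohort, models = "model2", convention = "ess")

bal <- res$model2$balance
cat("max weighted SMD:", round(max(bal$smd_weighted), 3), "\n")
cat("unbalanced before weighting:", sum(bal$smd_unweighted > 0.1), "covariates\n")
eff <- res$model2$outcomes_weighted
eff[eff$timepoint == "t3", c("mean_exposed", "mean_control",
                             "mean_difference", "ci_low", "ci_high")]
```

```
max weighted SMD: 0.043
unbalanced before weighting: 8 covariates
  mean_exposed mean_control mean_difference ci_low ci_high
4        41.48        55.11          -13.64 -15.18   -12.1
```

Eight covariates are visibly imbalanced in the raw cohort (the generator
assigns exposure preferentially to patients with cardiac comorbidity);
after weighting every standardized difference is below the 0.1 balance
threshold. The weighted t3 contrast estimates that mutation carriers sit
13.6 LVEF points below wildtype patients about 10 months into therapy
(95% CI −15.2 to −12.1) — recovering the configured ground truth of
−13.5 points, while the naive unweighted contrast on the same cohort
(−15.5 points) overstates the effect because sicker patients are
over-represented among carriers.

`run_ipw_pipeline(..., outdir = "out")` additionally writes, per model, the
weights table, balance TSV, timepoint-effect tables, descriptive Table-1,
propensity model JSON, survival summary, and a manifest with the trimming /
truncation bookkeeping.

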
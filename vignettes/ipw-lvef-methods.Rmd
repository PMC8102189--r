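---
title: "Methods: propensity-weighted analysis of LVEF decline in AML cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity-weighted analysis of LVEF decline in AML cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioipw)
```

## The problem

Somatic mutations in the isocitrate dehydrogenase genes *IDH1* and *IDH2*
occur both in clonal hematopoiesis and in acute myeloid leukemia (AML), and
the mutant enzymes produce the oncometabolite R-2-hydroxyglutarate, which has
been implicated in cardiomyopathy. A retrospective AML cohort can ask whether
carriers of an *IDH1/2* mutation lose more left-ventricular ejection fraction
(LVEF) during cytotoxic therapy than wildtype patients — but mutation status
is not randomized: carriers may differ in age, coronary artery disease (CAD),
cardiovascular risk burden, and treatment. `cardioipw` implements the
standard observational-epidemiology answer: estimate each patient's
probability of carrying the mutation given baseline covariates (the
propensity score, PS), reweight patients by inverse probability of treatment
weighting (IPW) into a pseudo-population in which measured covariates are
independent of mutation status, verify that balance with standardized mean
differences, and then compare weighted LVEF trajectories.

Because patient-level data of this kind are not publicly deposited, the
package ships a synthetic cohort generator that reproduces the *statistical
structure* of such a study, so every estimator can be validated against a
known ground truth.

## Estimand and weighting

For patient $i$ with exposure $Z_i \in \{0, 1\}$ (mutation carrier) and
covariates $X_i$, the propensity score is $e(X_i) = \Pr(Z_i = 1 \mid X_i)$,
estimated by binomial logistic regression (IRLS via `glm`, run to a tight
convergence tolerance with at most 100 iterations; we verify in tests that
the score equations $\sum_i (Z_i - \hat e_i) = 0$ and
$\sum_i X_{ij}(Z_i - \hat e_i) = 0$ hold to $10^{-6}$). The ATE weights are

$$ w_i = \frac{Z_i}{\hat e_i} + \frac{1 - Z_i}{1 - \hat e_i}, $$

so each group is reweighted to the covariate distribution of the full cohort.
Two comparisons are supported: **model 1** (wildtype vs *IDH2*-mutated,
*IDH1* carriers excluded) and **model 2** (wildtype vs pooled
*IDH1/2*-mutated).

Two guards against extreme weights are applied in this order:

1. **Trimming** (`trim_extreme_ps`, default fraction 0.05): the
   $\lfloor 0.025\,n \rfloor$ patients with the lowest and the highest PS are
   flagged and carry zero weight downstream. The total 5% is interpreted as
   symmetric 2.5% per PS tail — the usual reading of "removing the most
   extreme 5% propensity scores" — and both the fraction and the
   interpretation are configurable, since one-sided or weight-based variants
   exist in the literature. Boundary ties are broken by patient id so reruns
   are identical. Trimmed patients are *flagged, not deleted*: unweighted
   analyses still see the full cohort.
2. **Truncation** (`truncate_weights`, default cap 10): remaining weights are
   capped at 10. Both operations are idempotent.

Because the exposure effect in the generator is homogeneous (the same for
every patient), trimming and truncation change the weighting but not the
estimand, which keeps the bias checks below interpretable.

## Balance diagnostics

For each covariate (continuous) or indicator level (categorical, one row per
non-reference level, mirroring per-category balance plots), the absolute
standardized difference is

$$ \mathrm{SMD} = \frac{|m_1 - m_0|}{\sqrt{(s_1^2 + s_0^2)/2}}, $$

with weighted means and frequency-weight variances
($\sum w (x - m)^2 / (\sum w - 1)$); for binary indicators the variance is
$p(1-p)$. A weighted SMD $\le 0.1$ counts as balanced. A degenerate binary
split (one group all positive, the other all negative) reports `Inf` with a
warning rather than being dropped, because it signals a separation-like
pathology. Effective sample sizes use Kish's formula
$(\sum w)^2 / \sum w^2$.

## Outcome analysis

Echo measurements are timestamped in months from diagnosis and assigned to
four windows: `t0` = [−6, 0.5) months (pre-therapy), `t1` = [0.5, 4),
`t2` = [4, 8), `t3` = [8, 14) — so `t3` is centered near 10 months after
diagnosis. Exact window boundaries belong to study-specific supplementary
material, so these defaults are deliberately config-exposed. Within a window
a patient contributes at most one measurement (nearest the window center by
default, ties to the earlier echo); panels are unbalanced — patients may
appear at any subset of timepoints.

Group contrasts use an unpaired Welch t-test on the (weighted) samples, with
frequency-weight moments. Two degrees-of-freedom conventions are
implemented, because weighted two-sample testing is genuinely
underdetermined in this design:

* `"frequency"` (default): $n_g = \sum w$, the convention of
  frequency-weighting statistics packages. It reproduces what a typical
  clinical analysis reports, but it treats a patient with weight 5 as five
  independent patients, so its intervals are too narrow when weights vary.
* `"ess"`: each group's weights are rescaled to sum to the Kish effective
  sample size. This is the convention the package's own validation uses,
  since it is the one that can achieve near-nominal confidence-interval
  coverage; the simulation suite confirms coverage inside [0.90, 0.98] at
  n = 2000 over 200 replicates.

Within-group change compares each post-therapy timepoint's sample against
the same group's `t0` sample, again unpaired (the echo subsets differ per
timepoint); a paired sensitivity variant on the intersection is available.
No multiplicity adjustment is applied across timepoints or models, matching
common practice of reporting per-timepoint p-values. Timepoints with fewer
than two contributing patients per group are flagged non-estimable instead
of raising.

## Descriptive statistics and survival

`cohort_table1` reproduces clinical Table-1 conventions: median and range for
continuous variables, `% (n/total n)` with half-up rounding to one decimal
for categorical ones (base R's banker's rounding would not reproduce printed
tables), Pearson chi-square without continuity correction for categorical
comparisons (Yates correction by flag), and t-test vs Mann–Whitney selection
driven by Shapiro–Wilk / Lilliefors normality checks at 0.05.

Survival uses the product-limit estimator and the log-rank test
(`survival::survfit`/`survdiff` behind the package's interface, with
hand-written oracles in the test suite keeping the checks independent).
Overall survival runs from diagnosis to death; relapse-free survival from
documented complete remission (CR), with relapse *and* death in CR as
failures; both `cr_time` and `rfs_time` are stored as months from diagnosis
and the RFS clock is their difference. The KM median is the first time the
curve reaches 0.5 or below; fixed-horizon rates (24, 60 months) are read with
the $S(t^-)$ convention at exact event times. Median follow-up uses the
reverse Kaplan–Meier method (censorings as events).

## Sarcomere grading

The semiquantitative grading of cardiomyocyte sarcomere organization maps the
organized area fraction to grades 1–4 with bins [0, 0.10), [0.10, 0.50),
[0.50, 0.90], (0.90, 1]. Only the grade-4 boundary (strictly above 90%) is
unambiguous in the verbal scheme; whether 10% itself is grade 1 or 2 is not
decidable from the wording, so the lower boundaries follow the half-open
convention and are exposed via `breaks`. Grade distributions between
treatment conditions are compared with the same Pearson chi-square used for
the clinical tables.

## The synthetic cohort generator

`generate_cohort(sim_config())` emulates the data structure the analysis
assumes, with defaults fixed to the study conditions:

* **Cohort**: 363 patients by default; exposure prevalence 17.9% with an
  IDH1:IDH2 split of 26:39; age truncated-normal (60, 14) on [18, 90]
  (median 60, range matching an adult AML population); ~58% male; CAD,
  risk-factor burden, valvular disease, heart failure and cardiac medication
  with age- and comorbidity-linked prevalences near the published marginal
  rates; lognormal blood counts; cytogenetic risk 22/55/24%.
* **Confounded assignment**: exposure is Bernoulli with logit linear in
  age, CAD, high cardiovascular risk burden, heart failure, valvular
  disease and cardiac medications (CAD carrying the largest log-odds, 1.4);
  the intercept is calibrated by root-finding so the realized assignment
  probabilities average exactly to the target prevalence. Default
  probabilities stay inside (0.02, 0.85), so positivity holds; configs that
  break it trigger a warning.
* **Outcome**: per-patient LVEF trajectory = random intercept
  (mean 58.5, SD 6) + timepoint decline + exposure-by-timepoint interaction +
  confounder effects + measurement noise (SD 4). The control arm declines
  3.1 points by `t3` and exposure adds 13.5 points of decline, so the
  control arm runs 58.5 → 55.4 and the exposed arm 58.5 → 41.9 — the
  published trajectory anchors. Both arms share the same baseline
  distribution, so the pre-therapy effect is exactly zero and the true `t3`
  effect equals the group difference, −13.5 points. (The published exposed
  baseline is 0.7 points above control; that gap cannot coexist with a zero
  pre-treatment causal effect, and we prioritize the causal calibration —
  the choice that makes estimator validation meaningful.) Moderate
  confounder-outcome effects (CAD −4, high risk burden −2.5, age −1.5 points
  by `t3`) are the default; the validation suite amplifies them (−12/−8/−4)
  when it needs *strong* confounding to demonstrate naive-estimator bias.
* **Missingness**: echoes are available per timepoint with probability
  0.35–0.5 (missing completely at random by default), echoing cohorts where
  echocardiography is routine-care rather than protocol-driven; hematologic
  labs carry 15% missingness; assignment covariates are complete.
* **Survival**: exponential death (rate 0.014/month, 5-year survival ≈ 43%),
  censoring (0.0076/month, median follow-up ≈ 91 months ≈ 7.6 years) and
  relapse (0.0294/month from CR, 2-year RFS ≈ 49%) with CR in 66.4% of
  intensively treated patients.

One integer seed drives the whole cohort; replicate studies advance the seed
deterministically. What the generator does **not** emulate: informative echo
missingness (an `echo_availability` switch exists but sicker-patients-get-
more-echoes selection is not the default), correlations among comorbidities
beyond the age/CAD links above, measurement-device drift, competing risks,
and any transcriptomic or imaging raw data. Passing tests on this generator
therefore demonstrate estimator correctness under a correctly specified PS
model with MCAR outcome missingness — not robustness to the misspecification
real cohorts can exhibit.

## Validation problem sizes

The test-suite checks run at sizes chosen to keep Monte-Carlo error small
relative to the asserted tolerances: single-cohort checks at n = 2000
(balance: every weighted SMD ≤ 0.1 while ≥ 1 unweighted SMD exceeds it), and
the causal-recovery study over 200 replicates of n = 2000 (mean IPW `t3`
estimate within ±1 LVEF point of −13.5, CI coverage within [0.90, 0.98],
naive bias beyond 2 points under strong confounding). Closed-form checks
(2×2 logistic fits, SMD hand values, product-limit and hypergeometric
log-rank oracles, exact Mann–Whitney enumeration) run at desk scale.

## Known limitations

* The PS model must be correctly specified; no machine-learned or
  regularized propensity estimation is provided.
* Weighted inference is approximate: the ESS convention is a first-order
  correction, not a survey-design variance estimator (no linearization or
  replicate weights).
* Trimming changes the target population whenever effects are heterogeneous;
  the package reports it in the manifest but does not re-standardize.
* Rare binary covariates in small cohorts can separate the logistic model;
  the fit aborts with an explicit error advising covariate removal rather
  than silently returning boundary estimates.
```{r session}
sessionInfo()
```
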
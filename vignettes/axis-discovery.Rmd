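---
title: "Discovering and validating latent physiological axes in multi-cohort biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating latent physiological axes in multi-cohort biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Routine clinical biomarkers (blood counts, electrolytes, liver enzymes,
lipids, inflammatory proteins) are usually studied one at a time, but they are
jointly regulated: a latent physiological gradient can move many of them at
once. This package implements a pipeline for detecting such gradients as
principal axes of a standardized biomarker panel, and — because principal
components carry no built-in p-values — for validating them by *replication*:
refitting the axis in independent populations, demographic subsets, and random
mutually exclusive partitions of the data, and asking whether the re-projected
scores all correlate above a same-axis threshold (default r > 0.9).

An axis is a unit-norm linear combination of per-cohort standardized markers
maximizing explained variance, orthogonal to preceding axes. Its *variance
fraction* is the eigenvalue divided by the number of markers p; an axis is
conventionally informative when this exceeds 1/p (`informative_ratio()`).
Marker contributions are summarized by *loading importance*,
|loading| / sum(|loadings|), non-negative weights summing to one. The leading
axis in aging panels of this kind is a multi-system gradient linking
red-cell/iron markers and inflammation with (inversely) albumin and calcium —
"integrated albunemia" — and the second a metabolic-syndrome-like gradient;
the package names nothing by position, but orients every axis so scores
increase with age.

## Transformation protocol

All analyses operate on per-cohort standardized values:

1. **Normality transform.** For each (cohort, marker), `choose_transform()`
   picks identity, log(x + shift) or sqrt(x + shift) by minimizing absolute
   sample skewness; shift = max(0, 1e-6·SD − min) keeps the domain positive.
   Ties favor the least aggressive family (identity, then sqrt, then log).
   The chosen family is stored in the `transform_spec`, so stored axes can
   score new individuals exactly.
2. **Sex stratification.** Flagged markers (estradiol by default) are centered
   and scaled within each sex observed in the cohort, so each individual is
   scored relative to members of their sex. With a single-sex cohort this
   reduces to ordinary standardization; an observed sex level with no usable
   values is an error. Within-stratum means are exactly 0 and SDs exactly 1 on
   the fitting data; the pooled SD can differ slightly from 1 — this is a
   property of stratified standardization, and is deliberately not "fixed".
3. **Standardization.** Values map to (f(x + shift) − center)/scale with the
   n−1 SD; transforms are fitted separately per cohort because native units
   differ (albumin is g/dL in two built-in cohort profiles and percent of
   total protein in the third, precisely to force this machinery to be used).
4. **Complete cases.** PCA cannot use missing cells; each analysis keeps only
   rows complete on its marker set and reports per-cohort attrition counts.

Transforms are refit on each analysis input (e.g. first visits only) rather
than reusing baseline fits; the spec object records what was fitted, keeping
every analysis self-describing.

New data can fall outside a stored transform's domain: values at or below
−shift are an error under log (the transform is undefined and the input is
almost certainly mis-united), while under sqrt they are set missing with a
warning and then drop out of complete-case analyses.

## The synthetic-cohort generator

Real panels of this kind come from restricted-access cohort studies, so the
package ships a generator that emulates their statistical structure and gives
every downstream stage a known truth:

- **Two factors.** Marker m's standardized score is
  S_m = λ_m1·F1 + λ_m2·F2 + ε_m. The default configuration has 43 markers
  with realistic per-cohort native means/SDs; F1 loads at |λ| = 0.6 on a
  12-marker cluster (hemoglobin, hematocrit, RBC, iron, MCH, MCHC, IL-6 and
  platelets positive; albumin, albumin–globulin ratio, calcium and RDW
  negative), F2 on lipids, glucose and CRP. Residual SDs default to
  sqrt(1 − λ²) (0.8 for the F1 cluster), making each marker's standardized
  variance exactly 1.
- **Native scales.** Gaussian markers are mean + SD·S; right-skewed markers
  (CRP, IL-6, ferritin, triglycerides, hormones, …) are lognormal with
  moment-matched parameters, exp(μ + σ·S). The marginal families are a
  generator choice — cohort studies report means and SDs, not shapes.
- **Age dynamics.** F1 = β0 + β1·age + β2·age² + b_i + w_it with a
  between-subject intercept b_i (SD 0.8) and visit noise w (SD 0.6). The
  default trend (β0 = 0.22, β1 = −0.025/yr, β2 = 0.00032/yr²) is J-shaped
  with a minimum near age 39 and late-life acceleration. Its amplitude is
  deliberately modest: per-cohort standardization removes cohort-level marker
  means, so any between-cohort mean component of F1 (an all-elderly cohort
  sits higher on the trend) is invisible to the axis scores. With a large
  trend the pooled score–truth correlation is bounded well below the
  within-cohort correlation; the default keeps pooled recovery of F1 above
  0.9 at the default sizes while preserving the acceleration that trajectory
  models must detect. F2 is age-flat.
- **Cohorts.** Three profiles: an all-female elderly cohort (ages 65–100,
  3 visits, 1.5-year gaps), an all-age single-visit cohort (21–95) that
  exercises the cross-sectional fallback in trajectory fitting, and an
  all-age two-visit cohort (21–96). Default sizes (250/650/300 subjects,
  2000 scheduled visits) keep the full test suite fast; stability analyses
  use a 3200-observation variant.
- **Outcomes.** Death times are exponential from study entry with hazard
  h0·exp(logHR·F1_entry) on the age timescale (defaults 0.03/yr and 0.1 per
  unit); visits scheduled after death are dropped, which keeps the panel
  invariant "death age ≥ last visit age" true by construction. Frailty (0–5)
  and comorbidity (0–13) counts are truncated Poisson with log-rates linear
  in per-visit F1; a diabetes-like flag is Bernoulli in F2 with a 5%
  ambiguous-code rate.
- **Missingness** is completely at random per (cohort, marker); the default
  rate is 0 (analyses are complete-case, so MCAR only thins the data).

What the generator does *not* emulate: informative dropout, recruitment bias,
cohort-specific assay drift, non-monotone marker–factor links, or any joint
structure beyond first/second moments plus the two-factor geometry. Passing
tests therefore show the pipeline recovers the structure it assumes, not that
real cohorts satisfy those assumptions.

## Axis engine: numerical choices

`fit_axes()` computes the correlation-scale decomposition via the SVD of the
re-centered, unit-scaled matrix (the test suite cross-checks it against an
explicit eigendecomposition of the sample correlation matrix to 1e-8).
Fit-time column centers/scales are stored on the model and applied before any
projection, so self-projection reproduces fit-time scores exactly and score
variance equals the eigenvalue.

Eigen-solver sign ambiguity is resolved deterministically (largest-|loading|
marker positive); scientific orientation comes from `orient_axis()`, which
flips the axis iff the score–age Pearson correlation is negative and falls
back to the sign rule when |r| < 1e-6 or ages are absent. A consequence worth
knowing: for an axis genuinely unrelated to age, orientation is decided by a
near-zero correlation and is effectively arbitrary per subset — stability
statistics are only meaningful for age-related axes (as here) or after some
other consistent orientation.

Loading importance uses |loading| in the numerator: the phrase "loading
divided by the sum of absolute loadings" is ambiguous about sign, but
importance weights are stacked as non-negative bar heights, which forces the
absolute value. This was a genuinely open choice and is recorded here.

`reduce_axis()` formalizes "trial and error" marker elimination as greedy
backward selection: repeatedly drop the non-required marker whose removal
(after refitting the PCA and re-orienting against the full-axis scores) least
reduces |r|, down to the target size. The reduced model is a *refit* on the
final marker set, not a truncation of the full loadings — the reduced clinical
score must be computable from 14 measurements alone. `clinical_reference()`
pools all cohorts into one reference population before fitting, because a
bedside score cannot ask which study the patient came from.

## Stability machinery

`null_distribution()` characterizes pure sampling variation: partition the
complete observations into k = 10 random exclusive subsets, fit the axis in
each, re-project all versions onto the *full* matrix (correlations across
disjoint subsets are undefined otherwise), and summarize the C(10,2) = 45
pairwise correlations by mean, minimum and interquartile range (25th/75th
percentiles, linear interpolation); repeat and average. Subsets smaller than
markers + 1 are skipped with a logged reason rather than erroring, since
demographic strata can be tiny. If demographic-subset correlations are no
worse than this random-partition null, population differences need no
biological explanation.

## Trajectories and outcome models

Axis-score age trajectories are mixed models with fixed linear/quadratic age
terms and a subject-level random intercept — random slopes and quadratics are
not offered (they add little and destabilize convergence in panels with 1–3
visits). Estimation is REML via `nlme::lme` with likelihood-based 95%
intervals; the estimation method is recorded on every fit. Populations where
every subject appears once (or where the mixed fit fails) degrade to ordinary
least squares with a flag. `trajectory_curve()` draws parameters from the
normal approximation to the fit and reports the pointwise 2.5th/97.5th
percentile band. A quadratic fitted over a wide age range necessarily bends
down at young ages to produce late-life acceleration; the `age_range`
argument supports the young-age linear re-fit that checks whether that early
decline is real (in the generator it is not).

Mortality uses Cox proportional hazards with **age as the timescale**: each
visit contributes an interval (entry age, exit age], left-truncated at entry,
exiting at the next visit (censored) or at death. Age is thereby controlled
by construction, and the non-independence of visits within subjects does not
bias the partial likelihood. A death recorded before a later visit is a
data-consistency error, never silently reinterpreted. Count outcomes (frailty
0–5, comorbidity 0–13) use linear or Poisson regression — linear for
interpretability, Poisson as the technically appropriate check; both control
for age with a cubic B-spline basis (default 5 interior knots at age
quantiles; knot details matter little, and linear control gives essentially
the same answers). A subject random intercept is added when visits repeat and
dropped automatically for baseline-only data. Binary disease flags use
logistic regression, with ambiguous codes assigned positive by default
(alternatives: negative, or 0.5 on a linear 0–0.5–1 scale). Effects are per
unit score and compound exponentially (`compound_hazard(1.1, 5)` = 1.1^5 ≈
1.6). Multiple testing across the outcome battery is handled by reporting
`expected_false_positives(m, alpha)` and by replication across cohorts, not
by Bonferroni — many of the models are redundant by design.

The Cox pseudo-R² exposed in results is the one `survival::summary.coxph`
reports (a Cox–Snell-type quantity); it is labeled as such and no equivalence
to other R² variants is claimed.

## Problem sizes and determinism

Default analysis sizes — 2000 scheduled visits for recovery and association
checks, 3200 complete observations with 20 stability replicates, 50
trajectory-coverage and 20 survival-recovery simulation replicates — were
chosen so the full suite completes in minutes on one core while keeping
Monte-Carlo error well inside the asserted margins. Every random stage
(generation, partitioning, parameter draws) takes an explicit seed, derives
child seeds deterministically, and restores the caller's RNG state, so
identical (config, seed) pairs give byte-identical panels, bundles and
summaries.

## Known limitations

- Missingness is MCAR only; the complete-case protocol is the point, but
  informative missingness in real panels would bias both axes and attrition
  counts.
- The stability null assumes exchangeable observations; it partitions visits,
  not subjects, so subjects with many visits can appear in several subsets
  (matching the procedure it implements).
- Bayesian credibility intervals of the original trajectory methodology are
  approximated by REML likelihood intervals; the contract is method-agnostic
  and the method label travels with every fit.
- No rotated/sparse PCA variants, no probabilistic PCA, no competing risks,
  no time-varying Cox coefficients.
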
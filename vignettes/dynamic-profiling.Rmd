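---
title: "Dynamic profiling: staged clustering and risk curves for longitudinal biomarker cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic profiling: staged clustering and risk curves for longitudinal biomarker cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynprof)
```

# The problem

Severe traumatic brain injury (TBI) patients arrive with an admission
Glasgow Coma Scale (GCS) score, accumulate serial cerebrospinal-fluid
(CSF) readings of a 13-mediator inflammatory panel during intensive care,
and are scored months later on the Glasgow Outcome Scale (GOS, 1–5;
1 = death). Admission severity alone is a weak predictor of outcome, and
a single regression fitted at discharge says nothing about how a
patient's risk *evolves* while data are still arriving. Dynamic profiling
addresses exactly that: it re-stratifies the cohort after every round of
biomarker readings and reads each patient's mortality risk off the
cluster they currently occupy.

The method makes few distributional assumptions. It assumes (i) that
patients who are similar in severity, demographics and inflammatory
trajectory have similar outcome risk — similarity being Euclidean
distance in a standardized feature space; (ii) that cluster-level death
fractions are meaningful estimates of member-level death probability,
which requires clusters of non-trivial size; and (iii) that the *shape*
of a mediator series, summarized by a few polynomial trend coefficients,
carries the outcome-relevant information even when series lengths differ.

# Stages, clusters, weights

A **round** is the *i*-th interval after injury in which mediator
readings were collected; it is the discrete time axis of the method. The
data never state how readings of different mediators group into rounds,
so the package defaults to the *ordinal* scheme — a patient's *j*-th
available reading of each mediator is round *j* — which is what makes a
patient with twelve reading rounds produce twelve profiling stages. A
time-binned alternative (`assign_rounds(scheme = "time_binned")`, round =
floor(time/width)+1, default width 24 h) is available for cohorts whose
sampling is clock-regular.

Clustering proceeds in stages over the patients with known outcome:

* **Stage −1** — features: the standardized GCS score only.
* **Stage 0** — GCS plus the clinical/demographic variables (age in
  years, sex, and the four binary flags: infection, bleeding, surgical
  decompression, subarachnoid hemorrhage).
* **Stage i ≥ 1** — GCS, the significant clinical variables, the
  orthogonal polynomial trend coefficients of each mediator over rounds
  1..i−1 (degree at most d), and the 13 raw concentrations (pg/mL) of
  round *i*.

The trend degree is capped at d regardless of stage, so the feature
dimension is bounded by 1 + n_clinical + 13(d+1) + 13 and is constant
once i ≥ d + 2; at earlier stages the history is shorter than d + 1
points and the maximal common degree min(d, i−2) is used instead — one
cannot take a quadratic trend through two points.

Each stage's partition uses k-means with Hartigan–Wong updates, keeping
the best within-cluster sum of squares over `n_restarts` (default 25)
random starts; on instances small enough to enumerate, the test suite
checks the winner against the exhaustive optimal partition. The number of
clusters defaults to k = 3, appropriate for cohorts of a few dozen
patients — with n ≈ 27 and k much larger, cluster death fractions
degenerate toward 0/1 singleton noise. A spectral variant is provided
(`method = "spectral"`): Gaussian affinity with bandwidth set to the
median pairwise distance, symmetric-normalized Laplacian, top-k
eigenvector embedding with row normalization, then k-means in the
embedding. The construction details are standard practice and each choice
is a function argument rather than a constant.

Every cluster carries a **weight**: the red-flag count (members with
GOS = 1), the mean GOS, and the sample standard deviation of GOS (n−1
denominator; 0 for singletons). The red-flag fraction `red_flags/size` is
the cluster's empirical death probability. A Beta(α, β) prior over that
probability — encoding medical expertise external to the data — updates
conjugately: posterior Beta(α + red flags, β + size − red flags), whose
mean always lies between the prior mean and the empirical fraction.

## Numerical choices

* **Standardization.** GCS points, years of age, 0/1 flags, trend
  coefficients and pg/mL concentrations share one metric space, so every
  feature column is z-scored per stage; the moments are stored in the
  partition so an incoming patient is placed on the same scale.
  Zero-variance columns are centered and left unscaled.
* **Label canonicalization.** k-means labels are arbitrary, so clusters
  are relabeled deterministically: by ascending mean GCS at stage −1 and
  by ascending death probability (ties: descending mean GOS, then first
  centroid coordinate) afterwards. Identical runs therefore produce
  identical label sequences.
* **Ties and degenerate input.** Nearest-centroid assignment breaks exact
  ties toward the lower canonical label. Fewer distinct rows than k is an
  error, not a silent 1-point cluster.
* **Missing readings.** A patient missing any round-i mediator reading is
  excluded from stage i and their risk curve skips that stage; nothing is
  imputed. Within the trend history, a mediator series shorter than the
  stage's effective degree keeps its computable coefficients and carries
  0 — "no detectable trend" — for the rest, keeping columns aligned
  across patients.

# Orthogonal polynomial trends

For a series of n values over rounds 1..n, the basis is the
Gram–Schmidt orthonormalization of 1, t, t², … over the discrete index
grid (`trend_basis()`), i.e. discrete orthogonal polynomials, with the
degree-0 column 1/√n. Coefficients are plain projections
`t(B) %*% y`. Unit-norm columns mean a linear coefficient extracted from
a 5-point series and one from an 8-point series live on the same scale,
which is the point: series of unequal length become comparable. The basis
is index-based, not clock-time-based, because rounds are the method's
time axis; a weighted-orthogonality variant over actual sampling times is
deliberately out of scope. The pool-size arithmetic 10 + 13(d+1) implies
the level term T0 belongs to the predictor pool, so it is included.
Degrees above 4 are refused: with a few dozen patients and series of at
most ~13 points, higher-degree trends are noise amplifiers. Optional
smoothing is a centered moving average of window 3 with shrinking end
windows; it defaults to off, since abrupt mediator excursions are signal
the higher-degree terms are meant to capture, not noise to remove.

# The outcome model

The binary outcome is a configurable binarization of GOS, because two
conventions coexist in this setting: *low/high* (GOS ≤ 3 poor vs ≥ 4
favorable — the headline split) and *survival* (GOS = 1 vs > 1, the
semantics of a fitted-probability-of-survival table). Fits are
maximum-likelihood logistic or probit regressions via IRLS
(`stats::glm`), reported as term / estimate / SE / t (t = estimate/SE,
checked to 1e−9 in the tests). With a few dozen patients and strong
predictors the likelihood can separate completely; separation is
detected (fitted probabilities at 0/1 or exploding coefficients) and the
model is refitted with a small ridge penalty (1e−4·‖β‖², intercept
unpenalized) so estimates and SEs stay finite, with the flag preserved in
the fit object.

The candidate pool (10 clinical + 13(d+1) trends) cannot be fitted
jointly at n ≈ 27, so selection is two-stage: marginal screening fits
each mediator's trend block (and the clinical block) separately, keeping
terms with |t| ≥ `t_cut`; the pooled survivors then undergo backward
elimination, dropping the least significant term until all |t| ≥ `t_cut`.
The default `t_cut = 1.5` is deliberately permissive — at these sample
sizes a |t| ≈ 1.6 quadratic term can be clinically meaningful — and it is
a knob, not a constant, because no published selection rule exists to
pin it down. The 80/20 train/test split is stratified on the binarized
outcome (largest-remainder allocation) so small test sets are not left
without deaths. A proportional-odds variant on the full 5-level GOS
(`fit_gos_ordinal()`, via `MASS::polr`) accompanies the binary model,
which remains the primary deliverable.

The retained model terms feed back into profiling: `run_pipeline()`
passes the selected clinical variables and trend columns to the stage
features as the "statistically significant" subsets. Called directly,
`profile_cohort()` defaults to using all variables, which keeps the
module self-contained.

# Curve matching and the leave-one-out protocol

The closeness of two risk curves is the absolute difference of the areas
under them — trapezoidal, against the stage index with unit spacing,
matching the round-based x-axis of the curves — up to the chosen horizon.
Curves of unequal length are compared on their common stages only; this
is the minimal assumption when one patient's series ended early, and each
match records the horizon used. The predicted class of an incoming
patient is the binarized GOS of the closest database curve; exact ties
resolve by majority class among the tied matches, and a residual tie
predicts Low, the conservative direction in a mortality context.

The leave-one-out evaluation removes one patient, rebuilds every stage
partition from the remainder (same seed, so all differences come from the
removal), walks the held-out patient through the partitions as an
incoming patient to obtain their curve, predicts at their last reading
round, and scores against their true class. Because a patient's feature
rows do not depend on who else is in the partition, feature tables are
computed once and each fold only re-standardizes and re-clusters — the
protocol is identical to a full rebuild, just not quadratic in cost.

Two decisions here were genuinely open:

* **Binarization for scoring.** The generator draws survivor GOS
  uniformly from {2,3,4,5}, independent of the mediator dynamics (the
  cohort description gives only the range). Under the low/high rule the
  Low-vs-High split *within survivors* is therefore unpredictable in
  principle, capping any method's success rate well below what the
  mortality signal supports. The default scoring rule for
  `loo_success_rate()` is therefore *survival*, the class the dynamics
  actually inform; both rules are exposed via `gos_rule`.
* **The random baseline.** Assigning Low/High by a fair coin succeeds at
  exactly 50% regardless of class imbalance, so the null experiment is a
  structureless cohort (`effect_scale = 0`) with labels drawn uniformly
  (`death_fraction = 0.5`). The test suite checks that the pipeline's
  leave-one-out rate is statistically indistinguishable from 50% there,
  and materially above it when the generator's outcome effects are on.

# What the generator emulates — and what it does not

`simulate_cohort()` reproduces the *structure* the method relies on:
a 7/27 death fraction; admission GCS from class-specific truncated
normals (survivors 6.0, non-survivors 5.6, sd 1.0, range 3–8 — a severe
cohort); ages around 34/37.9; mildly outcome-informative clinical flags;
4–13 reading rounds per patient at roughly daily spacing; 5% missing
readings; and log-normal mediator concentrations with class-dependent
linear/quadratic trends on the log scale over normalized time in stay.
Non-survivor elevations default to 0.8–1.5 log units by end of stay on
TNF-α, IL-6, IL-8, IL-10, IL-1β and MIP-1α, with within-series log-noise
sd 0.5 — order-of-magnitude realistic for CSF cytokine panels in severe
TBI, and chosen once as the generator's stated model. `effect_scale`
multiplies all outcome-dependent trends (0 erases the signal entirely).

The generator deliberately does **not** model inter-mediator correlation
beyond the shared class effect, detection limits or censoring, clinical
interventions that perturb trajectories mid-stay, or any mechanistic
inflammation dynamics; survivor GOS is independent of the biomarkers. A
passing test suite therefore demonstrates that the pipeline recovers the
kind of signal it assumes — monotone outcome-dependent log-trends in a
right-skewed panel — not that real TBI cohorts carry such signal, and not
that the particular success rate on synthetic cohorts transfers to any
real cohort.

# Problem sizes and reproducibility

The test and acceptance workloads are sized for a laptop-scale run:
orthonormality sweeps over all series lengths up to 20 and degrees up to
4; brute-force k-means verification up to 9 points; 1000-case sweeps for
the curve pseudometric and Beta-posterior properties; 50 replicates of
n = 200 for coefficient coverage; and 20 independent synthetic cohorts of
n = 40 for the leave-one-out evaluation in each of the signal and null
conditions. All randomness flows through explicit integer seeds — the
generator seed fixes the cohort bit-for-bit, the profiling seed fixes the
restarts — so every reported number is reproducible from the recorded
configuration.

# Known limitations

* Cluster death fractions from k = 3 clusters on a few dozen patients are
  coarse (steps of ~1/10); risk curves are step functions with visible
  jumps, and late stages with few remaining patients can produce extreme
  0/1 probabilities.
* The ordinal round scheme treats each patient's j-th reading as
  contemporaneous with every other patient's j-th reading, which is only
  approximately true under irregular sampling.
* Backward elimination by |t| at n ≈ 27 is unstable across splits; the
  retained term set should be read as one defensible model, not the
  model.
* Common-support curve comparison silently shortens the comparison window
  for patients with early truncation; a patient with only the stage −1/0
  points is matched on almost no dynamic information.
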
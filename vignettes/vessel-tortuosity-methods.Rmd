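---
title: "Methods: vessel tortuosity quantification and ISS modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vessel tortuosity quantification and ISS modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseltort)
```

This vignette documents the models, numerical choices and limitations behind
`vesseltort`. The package measures how tortuous a stented vessel segment is
— through Frenet–Serret curvature, torsion and the distance metric (DM) of
its centerline — and provides the downstream statistical and
machine-learning stages that relate those measurements to a binary in-stent
stenosis (ISS) outcome.

## Free-knot regression splines

A vessel centerline arrives as an ordered sequence of noisy 3D points
(mm). To evaluate curvature and torsion, which involve third derivatives,
the points are first given an analytic representation: a parametric
B-spline fitted by least squares **jointly over the coefficients and the
interior knot positions** (`fit_free_knot_spline()`).

* Points are pre-parameterized by chord length on [0, 1]; chord length is
  invariant under rigid motion, which matters below.
* Knots are inserted greedily at the parameter of largest residual; after
  every insertion all interior knots are re-optimized by Nelder–Mead in a
  log-gap parameterization (which keeps them ordered), with the
  coefficients profiled out by linear least squares at every candidate.
* The number of knots is selected by generalized cross-validation
  (`criterion = "gcv"`, the default): `GCV(k) = mean(RSS) / (1 - p/n)^2`
  with `p = k + degree + 1` coefficients per coordinate. AIC and a fixed
  knot count are available behind the same argument, so an alternative
  selection rule can be swapped in without touching the optimizer.

Numerical safeguards, all of which were forced by observed failure modes of
the plain recipe:

* **Minimum knot separation** of 1.5 data spacings. Knots closer together
  than the data cannot be resolved and produce wild end derivatives; the
  constraint enters the optimizer as a graded penalty rather than a cliff so
  the simplex can slide back into the feasible region.
* **Canonical-frame fitting.** The fit is performed in a PCA frame with
  deterministic axis signs (anchored on the endpoint vector, then the third
  moment, then the first point) and the canonical coordinates quantized to
  12 significant digits. Inputs that differ only by a rigid motion then
  follow bit-for-bit the same knot search, making fitted curvature/torsion
  profiles rigid-motion invariant to ~1e-10 relative rather than ~1e-4 (the
  knot search contains argmax and simplex comparisons that are otherwise
  sensitive to last-bit differences). Residual-norm ties in the knot
  proposal are quantized to 8 significant digits and resolved by position.
* **Rank fallback.** If an optimized knot configuration yields a
  rank-deficient design, the fit falls back to uniform fixed knots with a
  warning.

**Degree.** The default is cubic, the conventional choice, and sufficient
for curvature. Torsion involves the third derivative, which for a cubic
spline is piecewise constant; its accuracy is then first order in the knot
spacing and plateaus around 1e-2 relative on a 200-point helix. When
torsion accuracy matters, fit with `degree = 5`: the quintic's smooth third
derivative recovers helix torsion to better than 1e-3 absolute at the same
sample size. The geometry tests and the acceptance script use quintic fits
for exactly this reason.

## Curvature, torsion, DM

`geometry_profile()` samples the fitted curve at points **uniform in arc
length** (the parameter-to-arc-length map is built by quadrature of |r′|
on a dense grid and inverted monotonically) and evaluates

κ = |r′ × r″| / |r′|³, τ = ((r′ × r″) · r‴) / |r′ × r″|².

Both expressions are invariant under reparameterization, so they are
evaluated directly in the spline parameter. Choices:

* **Torsion is reported as |τ|.** Mean/max/range summaries of a signed
  torsion would cancel between left- and right-handed twist, and chirality
  is irrelevant to tortuosity burden; the signed profile is retained in the
  `tau_signed` column for callers who need handedness.
* **Degeneracy rule.** Where |r′ × r″| < 1e-8 |r′|³ (locally straight curve,
  Frenet frame undefined) torsion is set to 0. The threshold is
  dimensionally a curvature of 1e-8 mm⁻¹, far below anything measurable on
  a vessel.
* **Summaries** (`tortuosity_metrics()`): means are arc-length-weighted
  (trapezoid weights over the profile); since sampling is uniform in arc
  length this coincides with the plain mean up to endpoint treatment, but
  the weighting is stated so the choice is explicit. `L` is computed by
  adaptive quadrature of |r′|, `l` as the endpoint Euclidean distance, and
  DM = l/L ∈ (0, 1].

On noiseless analytic curves the pipeline recovers closed forms (helix
κ = a/(a²+b²), τ = b/(a²+b²); semicircle DM = 2/π); the tests assert these
at 1e-3 or tighter. On noisy points the spline absorbs rather than
interpolates the noise (residual RMS ≈ the noise SD), but **extreme-value
summaries remain noise-sensitive**: maximum curvature on a noisy centerline
is biased upward by residual wiggle, most visibly near the curve ends. This
mirrors what centerline software produces on real vessels, where printed
maximum-curvature summaries greatly exceed the means; consumers comparing
groups should prefer means or compare like with like (same fitting settings
on all vessels).

## Centerline extraction

`extract_centerline()` implements the maximal-inscribed-sphere definition
of a centerline on a desk scale, without a full Voronoi diagram:

1. The mesh must be a single open tube: exactly two boundary loops, no
   non-manifold edges (checked; branching is rejected with a topology
   error).
2. A cutting plane marches from one end ring, normal to a smoothed running
   tangent, with step `step` (default 0.5 mm — sub-voxel at rotational
   angiography scale). Each section is traced as a closed loop through the
   face connectivity; sections that clip an open end do not close and stop
   the march, as do jumps longer than 2.5 steps or direction reversals
   (which occur when the plane slides onto a neighbouring turn of a coiled
   vessel).
3. Each centerline point **maximizes the inscribed-sphere radius over its
   cross-section plane**: the point of the plane farthest from the mesh
   surface (vectorized point-to-triangle distances, Nelder–Mead over the
   two in-plane coordinates). The 2D alternative — the Chebyshev center of
   the section polygon — is degenerate under plane tilt (a tilted cut of a
   tube is elongated and the inscribed circle slides along its major axis);
   the 3D sphere objective is well-posed and this switch reduced the torus
   benchmark error by two orders of magnitude.
4. Two refinement passes re-cut every section with tangents taken from a
   free-knot spline fitted to the current centerline. Inscribed-sphere
   centers are highly sensitive to plane tilt on curved tubes, so tangents
   must come from a smoother, not from finite differences of the raw march.

On synthetic cylinders, torus segments and helical tubes the extracted
points stay within 2% of the tube radius of the generating curve, and the
DM of an extracted helical centerline is within 1% of the generating
segment's. `clip_segment()` then cuts the stent-implantation segment between
the projections of two landmark points, interpolating the exact projection
points, orienting proximal→distal (controllable by
`normalize_orientation`), and warning when a landmark is farther than a
stated distance from the curve.

## Stenosis

Percent stenosis is 100 × (1 − vessel/stent). The formula is stated with
the vessel diameter in the numerator ratio so that narrowing gives positive
percentages; a vessel wider than the stent yields a negative value, which
is reported unclamped so data-entry reversals remain visible. The ISS
threshold is a strict `> 25%` (exactly 25% is "none") and `> 50%` grades
severe, with severe counting as ISS in the binary outcome.

## Synthetic cohorts

`make_cohort()` draws per-patient tables whose marginals match the summary
statistics of a published 62-patient flow-diverter cohort (35.5% ISS,
79% complete occlusion, 75.8% female):

* Strictly positive, right-skewed metrics (maximum curvature 5.3 ± 8.9,
  aneurysm sizes, path length L) are lognormal, moment-matched to the
  printed mean ± SD — an SD exceeding the mean implies strong skew, which a
  normal cannot reproduce without negative mass.
* DM (0.5 ± 0.2) is logit-normal on (0, 1), with (μ, σ) found by numerical
  moment matching (quadrature + optimization, memoized).
* Symmetric-looking features (age 54.2 ± 9.2, BMI 25.1 ± 3.7, torsion
  summaries) are normal. Height, which appears as a predictor but has no
  published summary, is drawn as Normal(162, 7) cm — a realistic choice for
  a 75.8%-female adult cohort.
* `range_curvature` duplicates `max_curvature` exactly: on real vessels the
  minimum curvature of a segment is essentially zero, so the two summaries
  coincide; the duplication gives the collinearity filter a guaranteed
  target. Range torsion is max torsion minus a small half-normal minimum.
* The ISS outcome follows logit P = α + Σ βx with default coefficients
  +log(1.084) per maximum-curvature unit, log(0.01) per DM unit and +0.7
  for hypertension — risk up with curvature and hypertension, down with DM.
  α is calibrated by root-finding on the realized features so the expected
  prevalence equals the request; over 500 replicates the mean simulated
  prevalence is within ±0.02 of the target (asserted in tests). The
  complete-occlusion outcome is drawn independently of all features, since
  no tortuosity association is modelled for it.

What the generator does **not** emulate: correlations between tortuosity
metrics and demographics, measurement error in diameters, site effects, or
any nonlinearity in the outcome model. Tests passing on these cohorts
verify that the analysis stack recovers known structure; they do not verify
that real vessels satisfy that structure.

## Inference stage

* Continuous variables: two-sided **pooled-variance** t-test (Welch behind
  a flag). Binary variables: Pearson chi-square **without continuity
  correction**, switching to Fisher's exact test when any expected cell
  is < 5. These variants reproduce the reference p-values recomputable from
  published 2×2 counts (e.g. hypertension × ISS, p = 0.067); Yates
  correction does not.
* Screening threshold 0.1, no multiple-testing correction at either stage —
  the conventional two-step screen-then-model protocol.
* Collinearity: pairs with |Pearson r| > 0.9 are collapsed, keeping the
  smaller univariate p (ties keep the earlier column). The threshold is a
  package choice — declared, not inferred — set so that exactly duplicated
  metric columns are collapsed; with a chain of mutually collinear features
  exactly one survives.
* Logistic regression by `stats::glm`, Wald 95% CIs on the OR scale.
  Extreme fitted probabilities alone are not treated as failure (heavy-
  tailed predictors saturate legitimately); an error is raised only when a
  predictor actually separates the classes (named in the message) or the
  IRLS fails to converge.
* ROC: AUC by midrank Mann–Whitney (identical to the trapezoid over all
  thresholds; asserted against brute-force pair counting at n ≤ 50), cutoff
  by Youden's J.

## ML benchmark

`run_benchmark()` executes: z-scoring (population-SD convention),
borderline-SMOTE, stratified split (default 20% test), RFE, per-model grid
search by stratified k-fold CV (default 10), final refit and test metrics
at probability cutoff 0.5.

* **SMOTE placement.** `"train_only"` (default) learns the z-transform,
  oversampling and RFE on the training side only; provenance bookkeeping
  records every synthetic point's parents so the no-test-leakage property
  is testable. `"before_split"` oversamples the whole dataset before
  splitting; it is kept as a first-class mode because published protocols
  sometimes preprocess first, but it is optimistic — test rows leak into
  training neighbourhoods — and the mode choice is recorded in the output.
* **Borderline-SMOTE variant 1**: a minority point is a synthesis seed when
  between k/2 and k−1 of its k nearest neighbours (any class) are majority;
  all-majority neighbourhoods are noise and never seed. Synthetic points
  interpolate seed→minority-neighbour segments until exact balance.
* **RFE** drops the feature with the smallest |coefficient| under refitting;
  aliased (duplicated) columns drop first, ties break by column order.
* **Reported columns**: `cv_auc_mean` (±t-interval across folds) is the
  mean *in-fold* (training) AUC, `val_auc` the mean held-out-fold AUC, then
  test AUC/accuracy/sensitivity/specificity. Training AUCs exceeding
  validation AUCs is expected optimism, and no ordering between them is
  asserted. The CI construction across folds is a labelled package choice.
* All randomness derives from the config seed; identical seeds give
  bitwise-identical reports (asserted), with `ranger` and `xgboost` pinned
  to one thread and per-fit derived seeds.

## Problem sizes in the test-suite

The suite exercises: 200-point analytic curves; tube meshes at
circumferential resolutions 8–32 around 60–150-point centerlines; cohorts
of n = 62 (reference scale), 400–500 (recovery and coverage simulations at
200 replicates) and 2000 (large-n OR recovery); 100-seed SMOTE property
sweeps; and benchmark runs with all five model families at n = 400 with
compact grids. These sizes keep every statistical check at its stated
replicate count while the full suite runs in a few minutes on one core.

## Known limitations

* Maximum-curvature and maximum-torsion summaries from noisy centerlines
  are upward-biased by residual wiggle (see above); DM and the means are
  far more stable.
* The centerline extractor assumes an unbranched tube with two open ends;
  bifurcations, sac remnants and capped reconstructions are rejected rather
  than handled.
* The inscribed-sphere center search is local (Nelder–Mead from the section
  centroid), which is appropriate for near-circular vascular lumens but not
  for strongly non-convex cross-sections.
* Cohort features are drawn independently (apart from built-in duplicates
  and l = DM × L), so estimators that exploit feature correlation are not
  stress-tested.
* Synthetic-data AUCs and odds ratios validate the machinery, not any
  clinical claim.
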
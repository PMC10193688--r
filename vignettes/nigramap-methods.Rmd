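---
title: "Template-based voxelwise contrast-ratio analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based voxelwise contrast-ratio analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nigramap)
```

## The problem

Neuromelanin-sensitive MRI (NM-MRI) shows the substantia nigra pars
compacta (SNpc) as a hyperintense structure because neuromelanin shortens
T1. In idiopathic Parkinson's disease (IPD) the nigrosome subregions lose
neuromelanin signal earliest and most severely — nigrosome 1 (N1,
posterolateral) first, then nigrosome 2 (N2, anteromedial) — so the
contrast ratio (CR) between nigral tissue and a reference region is a
candidate early biomarker. Manual per-subject ROI drawing is the usual way
to measure CRs, and it is the dominant source of inter-rater variability:
diseased SNpc loses the very hyperintensity that defines the ROI.

`nigramap` implements the template-based alternative end to end: all
subjects are spatially and intensity-normalized into a common template
space; a voxelwise two-sample comparison between patients and controls
defines, once, the subregions that actually discriminate; those fixed
template-space ROIs are then applied identically to every subject, removing
the rater from the measurement loop. The package also implements the full
diagnostic evaluation used downstream of such a measurement (group tests
with a normality gate, ROC/AUC with DeLong intervals, pairwise AUC
comparisons, LOOCV operating points, laterality concordance), and a
synthetic midbrain phantom generator that provides ground truth for every
stage.

## The measurement model

**Contrast ratio.** For an ROI $R$ and reference region $F$ on a volume $I$,

$$\mathrm{CR}(R) = \frac{\overline{I}_R - \overline{I}_F}{\overline{I}_F}.$$

The defining identities — CR $=0$ at equal means, CR $=1$ at twice the
reference mean, invariance under any positive global rescaling — are tested
directly. The literature it belongs to does not agree on a single reference
region (midbrain tegmentum and crus cerebri are both used); here the
reference is a configurable template-space mask, and the phantom places it
in homogeneous midline tissue that disease effects never touch.

**Volume-weighted combination.** The headline marker combines the two
nigrosome ROIs per side with weights proportional to their template-space
volumes:

$$\mathrm{CR}_{N1+N2} =
\frac{\mathrm{CR}_{N1}\,a_{N1} + \mathrm{CR}_{N2}\,a_{N2}}
     {a_{N1} + a_{N2}}.$$

The weights are the fixed template ROI volumes, identical for every
subject — a template-based analysis measures one area per ROI, not one per
subject. The combined value is therefore always bounded by its two
components, which is asserted per subject in the tests.

## Spatial normalization and the template

Registration is rigid only (6 degrees of freedom): the analysis operates
within a narrow midbrain field of view on images of one modality, and the
contract that matters is recovering the subject's misalignment to
sub-voxel accuracy, not inter-subject morphing. The optimizer minimizes
mean squared error over a three-level scale-space pyramid (Gaussian
smoothing at full resolution with the level-scaled sigma, then
downsampling by factors 4, 2, 1) with Nelder-Mead at each level,
warm-started from the previous level and restarted with a fresh simplex
when the iteration cap is hit. Initialization is a fixed 27-point grid of
rotations (−4/0/4 degrees per axis) evaluated at the coarsest level, the
best three refined — there is no random initialization anywhere, so
registration is bit-reproducible.

Four numerical choices matter and were settled by construction rather
than tuning against outcomes:

* **Out-of-view handling.** The metric compares out-of-view samples
  against the background level (0) instead of excluding them. Excluding
  voxels makes the averaging set — and hence the objective — discontinuous
  in the transform, which manufactures a spurious local minimum at exactly
  grid-aligned transforms (background voxels with zero error drop out of
  the denominator as soon as the transform moves off-grid).
* **Metric smoothing, in scale-space order.** Both images are smoothed
  identically before the metric is evaluated: the phantom is piecewise
  constant, so the raw trilinear MSE landscape is full of kinks that
  stall simplex and gradient methods alike. Smoothing happens at full
  resolution *before* block-mean downsampling — the reverse order leaves
  edge artifacts in the downsampled images that displace the metric
  optimum at fractional offsets.
* **Boundary shell.** A 3-sigma shell at the grid boundary is excluded
  from the metric. Smoothing smears content toward the edge, where
  comparison against the out-of-view fill would penalize every
  non-identity transform and pin the optimizer at identity; the excluded
  set depends only on the grid, so the objective stays continuous.
* **Sampling stride.** At the finer levels the metric is evaluated on a
  stride-2 subgrid: full-resolution content at an eighth of the cost.

The template is built by iterative registration and averaging: register
all intensity-normalized volumes to an initial reference, average, then
re-register to the current average. The initial reference is the voxelwise
median of the unregistered inputs — robust to a single outlying subject and
invariant to input order, which the suite checks to $10^{-6}$ of the
dynamic range. The default is 2 re-registration iterations (3 passes in
total); identical aligned inputs are a fixed point. CRs are measured in
template space on the spatially normalized subject volumes — masks fixed,
images moved — which is the convention of a template-based analysis;
`map_rois_to_subject()` provides the inverse (native-space) convention but
is not the default path.

Intensity normalization divides each volume by its reference-region mean,
making the reference mean exactly 1 everywhere and leaving every CR
unchanged (CR is scale-invariant by construction). The operation is
idempotent. During template construction, before a reference mask is
meaningful, volumes are provisionally scaled by their foreground mean;
the final normalization is reference-based.

## Voxelwise mapping and ROI definition

The group comparison is a pooled-variance two-sample t statistic per voxel
inside the analysis mask (SNpc plus a 2-voxel margin). Family-wise error
is controlled by max-T permutation: group labels are permuted (1000 draws
by default, seeded), the maximum absolute statistic over the mask is
recorded per permutation, and the corrected p-value of a voxel is the
fraction of permutations (plus the observed labeling) whose maximum meets
or exceeds its statistic. This choice is exact under group exchangeability
and — unlike parametric random-field or cluster-extent corrections — can be
validated by simulation, which the acceptance suite does: under the
exchangeable null the fraction of replicates with any corrected-significant
voxel must lie inside the binomial 95% interval around 0.05. No smoothing
is applied to the maps before testing.

ROI extraction keeps voxels with corrected $p <$ 0.05 where controls
exceed patients (the regions of interest are signal-*loss* regions; the
direction is fixed globally and never auto-flipped), labels 26-connected
components, splits them at the template midsagittal plane (components
touching the plane go to the side of their centroid), and names the
posterolateral component N1 and the anteromedial one N2 by projecting each
component centroid, relative to that side's SNpc centroid, onto the
posterolateral direction. A side with a single component gets N1 plus a
warning; a side with none is a warning; an empty map is a hard error.
Per-side N1 should be larger than N2 — violation warns rather than errors,
since it is a property of the data, not a precondition.

## The diagnostic evaluation

* **Group comparisons.** Shapiro-Wilk on each group at $\alpha = 0.05$
  gates each region into a two-sided Welch t-test (both groups compatible
  with normality) or a two-sided Mann-Whitney U test — mirroring the mixed
  mean±SD / median(IQR) reporting style such studies use. Welch rather
  than pooled: it is the safer default and coincides asymptotically under
  equal variances. The Mann-Whitney p is computed by exact enumeration of
  the permutation distribution of U (ties included) when both groups have
  at most 8 subjects, and by the tie-corrected normal approximation with
  continuity correction otherwise. Bonferroni adjustment multiplies by the
  number of regions compared and caps at 1.
* **ROC/AUC.** The classification rule is fixed: lower CR means disease.
  The AUC is computed by the rank (Mann-Whitney) method with ties counted
  one half, so AUC $\cdot n_1 n_2$ equals the U statistic exactly — an
  identity the acceptance suite checks against brute-force pair counting.
  The 95% CI is DeLong (Wald on the AUC scale, clipped to $[0,1]$); paired
  AUC differences between regions use the DeLong covariance of the
  placement values with Bonferroni over pairs. pROC serves as an
  independent cross-check in the tests, never as the implementation.
* **Operating point and LOOCV.** The threshold maximizes Youden's J, ties
  broken toward higher specificity. Leave-one-out refits the threshold on
  each fold of $n-1$ subjects and classifies the held-out subject;
  cross-validated sensitivity and specificity pool the held-out calls.
  Because CR scores themselves are not refit per fold, the AUC of the
  pooled held-out scores equals the apparent AUC; this identity is
  reported with a note rather than hidden.
* **Laterality.** A patient's dominant symptom side is the side whose
  per-side motor score exceeds the other by at least 2 points, otherwise
  indeterminate. Degeneration is contralateral to symptoms, so the
  dominant side should coincide with the side of the *higher* N1 CR;
  association is Fisher's exact test on the 2×2 table of determinate
  patients.

## The phantom: what it emulates, and what it does not

The generator renders a parametric midbrain on a 64×64×48 grid of 0.8 mm
isotropic voxels: a foreground ellipsoid at intensity 100, bilateral SNpc
crescents at 120 (canonical CR 0.2 against the reference, matching the
control-group CR range of NM-MRI studies), posterolateral N1 and
anteromedial N2 sub-ellipsoids (left N1 larger than right, mirroring the
left-dominant ROI volumes template studies report), a never-diseased
reference region in anterior midline tissue, and fixed internal landmarks
(cerebral-aqueduct, red-nucleus and crus-cerebri surrogates). The
landmarks exist because a featureless ellipsoid leaves rigid *rotation*
nearly unidentifiable — a real midbrain has gradient content in every
direction, and the registration contract (recovery within 1° / half a
voxel) is only meaningful when the data support it.

All geometry is analytic (ellipsoids), so a rigidly misaligned subject is
rendered by evaluating the anatomy at transformed coordinates — the
simulation contains **no interpolation**. This matters for the
apply-then-recover registration oracle: generating the moving image by
resampling would blur it anisotropically relative to the crisp fixed
image and displace the true metric optimum by up to a degree, corrupting
the oracle itself.

Patient subjects draw one fractional deficit per region per side
(N1, N2, remaining SNpc — independent draws, truncated at zero), apply
`1 - deficit` multiplicatively inside the region, and add an extra
`asymmetry_boost` on the side contralateral to the simulated dominant
symptom side (assigned uniformly at random, with per-side motor scores
generated to match). Controls receive only nuisance effects. Every subject
gets a log-normal global intensity scale (SD 0.1), a rigid perturbation
(SD 2° / 1 mm per axis — within the ±6°/±3 mm envelope the registration is
validated on), and additive Gaussian noise (SD 4, i.e. SNR 25 against
background; magnitude-MRI noise is Rician and a Rician mode is provided,
but at this SNR the Gaussian approximation is accurate and keeps the
closed-form oracles simple).

Default effect sizes — deficit means 0.036 (N1), 0.032 (N2), 0.004
(remaining SNpc), between-subject SD 0.03, boost 0.02 — were chosen once,
from the closed forms of the deficit model, to land group CR values,
effect sizes and the AUC ordering in the range reported for early-stage
cohorts: single-nigrosome AUCs in the low-to-mid 0.9s, the volume-weighted
combination near 0.99, the whole SNpc clearly lower. Two structural
features of the model, not tuning, produce the combination benefit: the
per-region deficits are drawn independently per subject, so averaging two
regions cancels part of the biological noise; and the weights are the
fixed template volumes, so no per-subject estimation noise enters the
weighting.

What the phantom deliberately does not emulate: MRI physics (no sequence
simulation, no magnetization-transfer or DANTE effects), susceptibility
contrast, partial-volume effects at structure boundaries (structures are
binary in the continuous domain), non-rigid anatomical variability between
subjects, or control-group biological variation in nigral signal
(controls differ only by nuisance effects, so their CR variance is
measurement-driven and smaller than in clinical tables). Passing tests
therefore demonstrate the correctness and calibration of the *pipeline* —
effect recovery, FWE control, localization, the AUC machinery — not
clinical performance on real data.

## Problem sizes and determinism

Everything stochastic is seeded: the cohort is a pure function of
(config, seed), registration has no random element, and the permutation
draws take an explicit seed, so two runs of the pipeline from one config
are byte-identical — asserted end to end in the suite. The validation
suite uses full-size cohorts (n = 50 + 50 at 64×64×48) for effect-structure
checks, 32³ / n = 8 + 8 with 500 permutations and 200 replicates for the
FWE calibration, 50 random perturbations for registration recovery, and a
reduced 48×48×32, n = 3 + 3 cohort for the end-to-end determinism check;
these sizes are the package's validation conditions and are stated here so
they can be reproduced exactly. The acceptance script
(`scripts/acceptance.R`) re-runs the full-scale analysis from scratch; its
cohort is ground-truth aligned, because the per-criterion registration
contract is measured separately (apply-then-recover at full scale) and
registering hundreds of volumes adds runtime without adding information
about the statistical chain.

## Known limitations

* Rigid-only registration: no deformable component, no multi-modal metric;
  the pipeline assumes a midbrain-cropped, single-contrast acquisition.
* The permutation count bounds the smallest achievable corrected p at
  $1/(B+1)$; with the default $B = 1000$ that is ~0.001.
* The LOOCV AUC identity (equal to apparent AUC) means LOOCV here
  validates only the operating point, not the ranking.
* Whole-SNpc CR in the phantom discriminates better than clinical tables
  suggest, because the phantom's remaining-SNpc deficit is drawn from the
  same truncated-normal family as the nigrosome deficits; the qualitative
  ordering (combination first, whole SNpc last) is preserved and is what
  the acceptance checks assert.
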
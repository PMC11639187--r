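---
title: "Methods: evaluating brain-metastasis segmentation with bmseval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating brain-metastasis segmentation with bmseval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bmseval implements the quantitative machinery used to evaluate automated
and human segmentation of brain metastases: overlap and surface metrics,
per-lesion analysis, nonparametric statistics, a randomized-crossover
multi-reader multi-case (MRMC) analysis pipeline, a synthetic phantom that
exercises the full pipeline without patient data, and an exact parameter
calculus for V-Net-style networks and their bottleneck-compressed
variants. This vignette records the mathematical conventions, the phantom
model and its parameters, the numerical choices, and the limitations.

## Masks and geometry

All segmentations are binary voxel masks (`label_volume`) carrying a
`voxel_geometry`: spacing in mm, the axial axis, and an origin. Masks are
binarized on construction (`> 0`), so probability maps must be thresholded
by the caller. NIfTI I/O (`load_mask`, `save_mask`) preserves spacing and
orientation; the axial axis is inferred from the xform column with the
largest world-z component. Metric functions refuse mask pairs whose
geometry disagrees beyond a 1e-4 mm tolerance (`check_geometry`).

## Metrics

* **DSC** `2|P ∩ G| / (|P| + |G|)` on voxel counts. Both masks empty is an
  error (the quantity is undefined); an empty prediction against a
  nonempty ground truth scores 0.
* **RVD** is the *scalar* volume difference
  `2|V_P − V_G| / (V_P + V_G) × 100`, symmetric in its arguments and
  deliberately unclamped: a missed lesion (V_P = 0) scores 200%, which
  keeps missed lesions visible in volume-error summaries.
* **ASD** is directed: the mean, over predicted boundary voxel centers, of
  the minimum Euclidean mm distance to any ground-truth boundary voxel
  center. A boundary voxel is a foreground voxel with at least one
  background 6-neighbour, where the volume border counts as background.
  `symmetric = TRUE` averages the two directed values. An empty mask makes
  the quantity undefined (`NA` with a warning), never silently 0.
* **Voxel confusion** (sensitivity, specificity, MCC) is computed inside
  an evaluation region — by default the union bounding box dilated by 5
  voxels — because whole-volume specificity saturates meaninglessly when
  the background dominates. The region must contain all ground-truth
  foreground.
* **Patient-wise DSC** pools all lesions of a patient into one union mask
  before computing DSC.

## Lesion analysis

Connected components use 26-connectivity by default (18 and 6 are
available). The axial diameter of a lesion is the maximum in-plane
pairwise distance between voxel centers within any single axial slice —
the voxelized analogue of the largest axial diameter used clinically.
Ground-truth-to-prediction matching is GT-centric: every predicted
component that shares voxels with exactly one GT lesion is assigned to it;
predicted components bridging several GT lesions are split by
nearest-GT-voxel assignment (ties to the lower lesion id); predicted
components touching no GT lesion are reported as unmatched false-positive
candidates, never silently dropped.

## Statistics

Summary uncertainty uses the percentile bootstrap (1000 iterations by
default, seed-deterministic, quantile type 7). Paired comparisons use the
Wilcoxon signed-rank test with zero differences dropped, the exact null
for n ≤ 25 without ties and the tie-corrected normal approximation
without continuity correction otherwise; all-zero differences return
p = 1 with a `degenerate` flag rather than an error. Unpaired comparisons
use the Mann-Whitney U test with the analogous exact/approximate switch;
multi-group comparisons use Kruskal-Wallis; correlations are Spearman
rank correlations with a t-approximation p-value; method agreement uses
Bland-Altman bias ± 1.96 SD limits. No multiplicity correction is applied
by default (`adjust_holm` adds one on request).

## The crossover MRMC pipeline

`validate_study` enforces a complete two-mode crossover — every
(reader, patient, lesion) unit must appear exactly once per mode — so
silently partial tables are never analyzed. `compare_modes` reports
per-mode medians with bootstrap CIs, the paired Wilcoxon test over
reader × lesion pairs, and the median paired improvement with its own CI;
for time the paired quantity is the percent time saving
`(t_un − t_as)/t_un × 100`. `compare_groups` contrasts the improvement
distribution between reader strata (experience group or session order)
with a Mann-Whitney test. `patient_level_rollup` pools voxel counts,
volumes and times to patient level. `correlate_quality_time` relates
quality metrics to contouring time and time saving to lesion size.

## The phantom generator

The phantom emulates the statistical structure of a multi-center
brain-metastasis test set at desk scale; the default problem sizes
(64³ voxels at 1 mm isotropic, 10 patients) are the package's own choice,
small enough for test suites while large enough to hold realistic lesion
geometry.

* **Lesion counts**: 1 + Poisson, truncated at 15 per patient (patients
  with more metastases are typically excluded from such studies).
* **Diameters**: log-normal, moment-matched to mean ± SD = 12.8 ± 7.7 mm
  (σ² = log(1 + cv²), μ = log(m) − σ²/2), floored at 3 mm for
  resolvability.
* **Shapes**: spheres whose radius is modulated along each direction by a
  band-limited spherical-harmonic field (nine second- and third-order
  terms in the direction cosines, normalized to unit RMS), scaled by the
  `irregularity` parameter; lesions are placed without overlap.
* **Boundary perturbation** (the error model for both the simulated
  segmentation model and the simulated readers): the mask's signed
  distance to its voxel-face surface is thresholded against a smooth
  angular noise field of RMS `noise_mm`. The signed distance places the
  zero level on the voxel-face surface, so an adjacent voxel pair
  straddling the surface sits at ± half a voxel step, and sub-voxel noise
  scales flip boundary voxels with the expected probability. Only a
  morphological band of width ~3 × `noise_mm` around the surface is
  evaluated; deeper voxels cannot change side.
* **Noise-to-DSC calibration** (12.8 mm sphere, 1 mm isotropic): noise of
  0.3 / 0.6 / 0.8 / 1.0 mm yields DSC of about 0.99 / 0.91 / 0.87 / 0.71.
  The default model noise (0.6 mm) therefore emulates a strong automated
  segmentation (DSC ≈ 0.91); resident and attending unassisted noise
  (0.8 / 0.65 mm) bracket typical human variability.
* **Assistance model**: assisted contours perturb the *model prediction*
  with the reader's residual noise `assist_effect × skill_noise`. Because
  the residual compounds with the model's own noise as
  `sqrt(model² + residual²)`, the default factors (0.10 / 0.15) are small,
  placing assisted accuracy just below the model's own accuracy for both
  groups — so the generating DSC improvement is positive for every
  reader, large for residents and small for attendings.
* **Times**: log-normal with a volume-dependent location
  (`log t = log base + exponent × log V + noise`) and an assisted-mode
  factor `log(1 − s)` with `s = 0.42`, making the *generating median*
  per-pair time saving exactly 42% while the session noise (SD 0.25 on
  the log scale) produces occasional negative savings, as observed in
  real crossover studies.

## Network parameter calculus

`build_vnet` describes a V-Net-style encoder-decoder as a flat table of
convolutions (input conv; encoder stages with strided 2³ down-transitions
that double channels; a mirrored decoder whose first convolution per
stage consumes skip-concatenated features at doubled width; a 1³ output
conv). `count_parameters` is exact: `k³ · in · out + out` per biased
convolution; normalization and activation layers carry no counted
parameters. `to_vbnet` replaces every spatial convolution inside an
encoder or decoder block by a bottleneck
`[1³: C→C/r] [k³: C/r→C'/r] [1³: C'/r→C']`, leaving transitions and the
input/output convolutions untouched; the default architecture drops from
10,037,714 to 1,462,702 parameters at r = 4, an 85.4% reduction. The
substitution is validated for channel continuity and refuses to be
applied twice.

## Numerical choices

Nearest-neighbour surface distances use an exact kd-tree search
(`RANN::nn2` with eps = 0). Bootstrap row medians use
`matrixStats::rowMedians`. Connected components are built as graph
components over half-neighbourhood voxel edges. Axial diameters use the
convex hull before the pairwise scan when a slice has many voxels. All
randomized procedures are deterministic given their seed arguments.

## Limitations

* The phantom generates *masks*, not MR intensities; it cannot probe
  intensity-dependent failure modes (enhancement, artifacts) and contains
  no anatomy.
* RVD is scalar by definition: spatially compensating errors are
  invisible to it (that is what DSC and ASD are for).
* The pair-level bootstrap in `compare_modes` assumes independent pairs.
  In a multi-reader study every assisted contour of a lesion edits the
  same model proposal, which correlates pairs within a lesion and makes
  the pair-level CI anticonservative as reader count grows; a cluster
  (lesion-level) bootstrap would be needed for strict calibration there.
* Percentile bootstrap CIs for medians of small samples (n ≲ 15) can
  undercover; study designs relying on them should keep at least ~20
  units per comparison.
* Simulated reader times share one log-normal family; systematic reader
  speed differences beyond the experience-group factors are not modelled.
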
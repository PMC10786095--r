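---
title: "Methods: synthetic multidimensional biological-motion RSA"
author: "bmRSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic multidimensional biological-motion RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

bmRSA implements a complete multivariate fMRI analysis chain for asking how
three attributes of point-light biological motion — facing direction,
gender and emotional state — are encoded in distributed voxel patterns:

1. parametric point-light walker stimuli on a 2×2×2 attribute crossing;
2. an S1/C1 (HMAX-style) model of early visual cortex, giving a V1
   predictor RDM;
3. a block-design BOLD simulator with planted, controllable multivoxel
   attribute structure;
4. run-wise GLM estimation (condition t-maps for RSA, per-run betas for
   decoding);
5. searchlight multiple-regression RSA with three binary theoretical RDMs
   plus the V1 RDM as predictors, Fisher-transformed group inference, and
   sign-flip Monte Carlo cluster correction;
6. the hierarchy analysis: re-running the RSA with the two non-target
   theoretical RDMs scrambled, averaging z maps over scrambles, and
   quantifying the overlap of corrected maps with the Dice coefficient;
7. leave-one-run-out linear SVM searchlight decoding with cluster-level
   accuracy statistics and the three-level display labels;
8. behavioral rating simulation and behavioral-to-neural RDM linkage.

Everything runs on synthetic data; no scanner data or motion-capture
corpus is required. The point of the package is that every stage of the
analysis is exercised end-to-end against planted ground truth.

# The walker model

Real studies of this kind draw stimuli from a motion-capture morph space.
bmRSA substitutes a documented parametric skeleton: 15 joints whose mean
pose is animated by sinusoids at the 1-s gait frequency (limb swing at
*f*, vertical bounce and lateral sway harmonics), plus two linear morph
axes expressed in "SD units" so that the stimulus set uses ±6 units per
attribute:

* **gender axis** — shoulder/hip width ratio shifts with a stronger
  lateral upper-body sway for male-typical levels;
* **emotion axis** — head/neck elevation and slump, vertical bounce and
  arm-swing amplitude (happy = upright and bouncy, sad = slumped and
  damped).

Morphing is exactly linear in the axis weights, applied in the body frame
before projection; this makes superposition properties testable to
machine precision. Facing is rendered as the two side views at 45°/135°
azimuth; the left-facing walker is the laterally mirrored body rotated to
the opposite azimuth, so the two facings are exact mirror images in the
projected x coordinate — a deliberate, testable convention (the text of
studies using such stimuli typically leaves the relation between the two
views unspecified).

The axis magnitudes were fixed once, when the stimulus generator was
designed, with one additional constraint: the V1-model RDM of the eight
stimuli must not be (nearly) collinear with any single theoretical
predictor, because the four-predictor regression would otherwise be
unable to attribute variance. With the shipped axes the V1 RDM correlates
with the gender, emotion and facing RDMs at roughly 0.49, 0.55 and −0.04,
leaving the theoretical predictors' variance-inflation factors below ≈2.6
(the V1 predictor's own VIF is ≈3.1). Because each
frame's C1 vector is averaged over a full gait cycle, dynamic cues largely
cancel and it is the static component of each axis that controls these
correlations; mirror-symmetric facings are nearly invisible to the model
by construction.

# The V1 model

The S1 stage computes, for each of 8 filter sizes (7–21 px, four two-size
bands) and 4 orientations, the absolute normalized correlation between the
zero-mean unit-norm Gabor filter and the local image patch; responses lie
in [0, 1], are invariant to global intensity scaling, and are zeroed in
the border band where the filter support leaves the image. The C1 stage
takes local maxima over half-overlapping spatial cells (pool sizes
8–14 px per band) and across the two sizes in each band. Per-frame C1
vectors are averaged across the stimulus (processing treated as
instantaneous), and the V1 RDM is 1 − Pearson correlation between the
eight stimulus features. The exact filter constants follow the standard
published C1 recipe; the source studies name only "C1 units", so these
constants are configuration, not fact, and are exposed in `gaborBank()`.

# The BOLD simulator

The acquisition follows the study design exactly: TR 2 s; six runs; per
run 24 stimulus blocks of 12 s (each of the 8 stimuli three times, in
seeded random order) interleaved with 6-s fixations plus one leading
fixation, giving 438 s = 219 volumes per run. The extra fixation slot is
placed at the run start; the run totals are identical either way.

Signal model per voxel: `rest + Σ_s amplitude(v, s) · x_s(t)`, where
`x_s` is the stimulus boxcar convolved with a canonical double-gamma HRF
(peak 6 s, undershoot 16 s, ratio 1/6), peak-normalized so amplitudes are
percent signal change against a rest level of 100. Noise is AR(1)
Gaussian (marginal SD `noise_sd`, lag-1 coefficient 0.3 by default), plus
per-voxel low-frequency drift (linear + half-cosine) and a component
correlated with six synthetic motion regressors. T1-saturation volumes
are not simulated; series are generated at steady state.

**Planted truth.** Three disjoint ball-shaped ROIs (radius 0.165 N on an
N³ grid) carry the three attribute codes. Every ROI voxel responds to its
attribute's category sign through a voxel-specific tuning gain
`1 + tuning_sd·N(0,1)` (default SD 0.5). The gain heterogeneity is what
makes the code *multivoxel*: with identical gains, the category signal
would be a uniform offset inside the searchlight and would vanish under
pattern centering, leaving RSA and decoding blind to interior voxels.
Per-(voxel, stimulus) idiosyncratic jitter (SD 0.3) adds realistic
item-level variability. Cross-attribute couplings come in two forms:
`"target:source"` plants additive source-signed structure into the target
ROI (the target region also encodes the source attribute — the
ingredient of the hierarchy analysis), and `"target*source"` plants a
product-signed modulation (the target contrast depends on the source
category).

**Operating point.** The default `noise_sd = 11` realizes a pattern SNR
of ≈0.5 for a 1% planted effect: the OLS beta estimate of one condition
in the concatenated six-run GLM then has a standard error of ≈2, i.e.
twice the planted amplitude. This is the regime the group-level recovery
analyses are specified for; per-voxel effects are individually weak and
only the pattern statistics recover them.

# GLM

Per run, the design matrix holds the 8 HRF-convolved stimulus regressors,
the 6 motion regressors, an intercept and two drift terms. The condition
t-maps for RSA come from a single concatenated-runs GLM with shared
stimulus regressors and run-wise intercept/nuisance/drift columns — a
convention, since "pooled condition t images" do not dictate one — while
per-run betas for the MVPA are fitted run by run, exactly as the analyses
require. Plain OLS without prewhitening is used throughout; the AR(1)
noise inflates variance mildly (the null-tail test in the suite runs with
AR switched off for exactness, and the cluster-level inference is
calibrated nonparametrically anyway).

# Searchlight multiple-regression RSA

Searchlights are the k nearest in-mask voxels by Euclidean grid distance
(ties broken by ascending linear voxel index; the center always included).
The study-scale default is k = 200; on the desk-scale 16³–20³ grids the
synthetic scenarios use k = 19, keeping the searchlight radius (≈1.6
voxels) proportionate to the planted ROIs — a 200-voxel searchlight on a
20³ grid would have a radius of a fifth of the whole volume and smear the
maps beyond recognition.

In each searchlight, the neural RDM is 1 − Pearson between the 8
condition t-patterns; its 28 lower-triangle entries (fixed row-major pair
order) are regressed on the three theoretical RDM vectors and the V1 RDM
vector, all standardized; the standardized coefficients go to the center
voxel. Group inference Fisher-transforms the coefficients (atanh, inputs
clipped to ±0.999 so the transform stays finite) and runs voxel-wise
one-sample t-tests; voxels with zero between-subject variance are capped
at |t| = 100 and flagged. Searchlights containing a constant pattern are
skipped and recorded.

# Cluster-level inference

Initial threshold: one-sided p < 0.001 on the group t map (the
hypotheses are positive encoding; a two-sided flag exists). Clusters are
connected components under 26-connectivity (configurable). Family-wise
correction builds the null distribution of the maximum supra-threshold
cluster *size* by randomly sign-flipping each subject's map and
recomputing the group t (5000 iterations at study scale, 500 in the test
profile); the corrected p of an observed cluster is
`(1 + #{null max ≥ size}) / (1 + n_iter)`. Using size (not mass) is a
documented choice; size is discrete, which makes the test slightly
conservative — on smooth null fields of searchlight-like correlation
length (Gaussian kernel σ = 4 voxels on a 16³ grid) the measured
family-wise error rate is ≈0.04 at a nominal 0.05.

# Hierarchy analysis (scrambled RDMs + Dice)

For a target attribute, the two other theoretical RDMs are scrambled by a
joint row/column permutation of the condition labels (structure- and
multiset-preserving; entry-level shuffling of the 28-vector is available
as a sensitivity variant). Draws that happen to collide with another
predictor's bipartition — which makes the regression singular — are
rejected and redrawn. Each of the n_perm = 1000 (test profile: 100)
scrambled regressions yields a target-coefficient map that is
z-transformed (Fisher transform, matching the main analysis; per-map
spatial z-scoring is the documented alternative) and the maps are
averaged. Group maps from the standard and scrambled analyses are both
cluster-corrected with the same procedure, thresholded, and compared with
the Dice coefficient `2·N_C/(N_1+N_2)`. Independent planted attributes
give DC near 1; planting an additive cross-encoding (e.g. the gender ROI
also carrying emotion structure) lowers the target attribute's DC, which
is the qualitative signature the analysis is designed to detect.

# MVPA

For each attribute dichotomy, the 48 per-run condition betas are split
4 + 4 stimuli per class (24 samples per class), each searchlight pattern
is demeaned across its voxels (pattern-wise, removing amplitude
differences — per-voxel centering across samples is deliberately not the
default), and a linear SVM (cost 1) is trained on five runs and tested on
the held-out run, cycling all six folds. Cluster-level accuracy is the
mean over the cluster's voxels; in the acceptance-scale analyses it is
estimated on a seeded subsample of up to 40 voxels per cluster — an
unbiased estimate of the same mean at a fraction of the cost. Per
cluster the own attribute's accuracies are tested against chance (0.5,
one-sided) and against each other attribute (paired, one-sided), BH-FDR
corrected per attribute network, yielding the three display levels:
above chance / higher than one other / higher than both.

# Behavioral linkage

The rating simulator emits the 96-trial table (8 stimuli × 3 attributes ×
4 repetitions) as
`clamp(round(4 + slope·sign + N(0, criterion_sd)), 1, 7)`; defaults
slope 1.5, criterion SD 1 give accurate but noisy raters. The behavioral
RDM per attribute is the absolute difference of per-stimulus mean
ratings — the Euclidean distance between scalar means; treating the four
repetitions as a paired 4-vector has no pairing justification and is not
used. Per subject and cluster, the behavioral RDM vector is Pearson-
correlated (Spearman by flag) with the cluster-restricted neural RDM;
correlations are Fisher-transformed, tested against zero across subjects,
and BH-FDR corrected across clusters. Subjects with a zero-variance
behavioral RDM are excluded with a warning, mirroring the "not sure on
most trials" exclusion; `ratingExclusionFlags()` implements the
three-sigma and >50%-unsure screens as a utility.

# Problem sizes and profiles

The `test` profile of `pipelineConfig()` bounds the pipeline at desk
scale: 16³ grid, 6 subjects, k = 19, ≤100 scrambles, ≤500 Monte Carlo
iterations. The acceptance analyses use 20 synthetic subjects on the
default 20³ grid (≈3 500 mask voxels) — the sample size mirroring a
typical analyzed cohort of such a study — with 100 scrambles and 500
Monte Carlo iterations; the `full` profile restores the study-scale 1000
scrambles and 5000 iterations. Null-calibration suites use 100–200
repetitions of 20-subject smooth Gaussian null fields.

# What the synthetic data do and do not show

The generator reproduces the design arithmetic, a plausible hemodynamic
and noise structure, and planted multivoxel codes with controllable
cross-attribute coupling. It does not emulate anatomy, physiological
noise, motion artifacts beyond nuisance-correlated components, retinotopy
(the planted codes are unrelated to the V1 model's actual response to the
stimuli), or inter-subject spatial variability (ROI geometry is shared;
tuning gains are subject-specific). Passing tests therefore demonstrate
that the *analysis machinery* is correct and calibrated — recovery of
planted effects, nominal false-positive control, attribute-specific
decoding where attribute codes were planted — not that any particular
real-data result would replicate.

# Numerical choices and edge cases

* Fisher transform inputs are clipped to ±0.999; group voxels with zero
  between-subject variance get |t| = 100 and a flag.
* Searchlight neighborhoods break distance ties by ascending linear voxel
  index, making maps exactly reproducible.
* RDM regressions reject zero-variance inputs and predictor matrices with
  condition number above 1e10 (reporting it); scrambled draws that become
  singular are redrawn.
* The S1 normalization floors the local patch norm at 1e-6, so empty
  image regions give exact zeros rather than 0/0 noise; border bands are
  zeroed.
* Degenerate (all-identical) SVM training folds score 0.5 with a warning;
  constant accuracy vectors give t = 0, p = 1 instead of an error.
* Dice of two empty maps is defined as 0 and flagged.
* All randomness flows from one global seed through `deriveSeed()`
  (stage label + unit index), so every artifact is bit-reproducible.
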
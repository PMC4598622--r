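---
title: "Subtomogram averaging in tomopipe: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtomogram averaging in tomopipe: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(tomopipe)
```

tomopipe is a desk-scale implementation of the cryo-electron tomography
workflow used to determine membrane-protein complexes in situ: simulate a
vesicle scene and its tilt series, reconstruct a tomogram, find particles by
template matching, average and classify subtomograms under the missing wedge,
measure resolution by Fourier shell correlation (FSC), and interpret the
result by fitting atomic models. This vignette walks through the methods and
records the numerical choices, with emphasis on the places where a naive
implementation goes wrong.

## 1. The missing wedge

A tilt series covers tilt angles about a single axis (y here, beam along z),
so Fourier space is sampled only inside a wedge-shaped region. All
correlation, alignment, and classification in tomopipe is *constrained*: it is
computed only over the Fourier region that both volumes actually sampled.

`make_wedge_mask(n, wedge_spec(tmin, tmax))` marks the sampled region. A
Fourier point with coordinates (kx, kz) lies on the central section of the
tilt at angle `atan2(kz, kx)` folded into (-90, 90]; it is sampled when that
line angle (measured from the kx axis) is within the complement of the wedge.
The solid fraction of a `±t` wedge is `2t/180` of the full *sphere* — a
closed-form check used in the tests. Note the domain matters: over the full
cubic grid the fraction is different (the cube corners overweight directions
near the tilt axis; for ±60 it is analytically `1 - tan(30°) ≈ 0.711`), so
the comparison restricts to the Nyquist ball:

```{r wedge}
wm <- make_wedge_mask(48, wedge_spec(-60, 60))
mean(wm)                                           # cubic grid: ~0.711
ball <- as.vector(tomopipe:::freq_grids(48)$kr) <= 0.5
mean(as.vector(wm)[ball])                          # Nyquist ball: 120/180
```

## 2. Constrained cross-correlation

`constrained_cc(a, b, wedge_a, wedge_b, mask, band)` masks both volumes in
real space, restricts to the intersection of the two wedges and the resolution
band in Fourier space (DC term excluded), and returns the normalized
correlation there. By Parseval's theorem this equals the plain real-space
correlation of the two masked volumes after each has been filtered to the
common Fourier region — the oracle identity checked to 1e-5 in the acceptance
tests. Without the constraint, two subtomograms of *different* particles
correlate strongly through their shared wedge artifacts, and alignment locks
onto the wedge instead of the structure.

## 3. Template matching

`match_template()` runs the 6-dimensional search: a quasi-uniform SO(3) grid
(Fibonacci sphere crossed with in-plane angles, `so3_grid()`), the rotated
template filtered by the tomogram's wedge, and a fast local correlation over
all positions per orientation via FFT. Scores are locally normalized: the
local mean and standard deviation of the tomogram under the (spherical)
template mask are computed by convolution, which makes the score invariant to
the slowly varying background of a crowded tomogram. Two practical details
matter:

* the local standard deviation is floored at 5% of the global standard
  deviation, so featureless regions score near zero instead of 0/0;
* gold fiducial markers are several-fold brighter than any biological
  density and must be erased first (`erase_bright_blobs()`: threshold at half
  the volume maximum, dilate, blank), otherwise they fill the top score peaks.

For membrane-bound particles the template should include a patch of the
membrane itself (`render_membrane_shell()` renders a Gaussian shell of the
vesicle's curvature): matching a particle-only template against a
particle-plus-membrane tomogram drags every peak radially outward by roughly
half the membrane offset, a systematic bias of tens of ångströms.

## 4. Iterative alignment and gold-standard FSC

`refine_iteratively()` alternates aligning each subtomogram against the
current average (rotation grid whose step tracks the current resolution,
`step ≈ atan(resolution / diameter)`, translation from the constrained CC
peak) with rebuilding the average. Averaging is wedge-weighted: each
particle's rotated wedge mask is accumulated and the summed Fourier data
divided by the summed sampling, so well-sampled directions are not
overweighted. Each subtomogram is rotated into the reference frame through a
2x Fourier-oversampled copy rather than by direct trilinear resampling:
trilinear interpolation attenuates exactly the high-frequency shells the
average is supposed to recover, and the resulting reference blur is enough to
trap a visible fraction of particles at wrong orientations.

In `"gold_standard"` mode the data are split into two halves at the start and
each half is aligned only against its own average; the FSC between the two
half-maps is then an unbiased resolution estimate read at the 0.143 threshold
(0.5 for the conventional, correlated-reference mode). The expected FSC of
two half-maps with independent noise is `S/(S+N)` per shell, an identity the
tests verify against seeded noise.

Two numerical choices here were decided by controlled experiments:

* **Peak interpolation is location-only, but the score is evaluated
  exactly off-grid.** `cc_peak3d()` refines the peak *position* with a
  per-axis parabola. A parabola-extrapolated peak *value* is a quadratic form
  of three noisy samples and scrambles orientation rankings; instead the
  rotational score is the exact band-limited value of the cross-correlation
  at the refined fractional shift, computed by a phase-factorized Fourier sum
  (`cc_value_fractional`). Without this, the score as a function of rotation
  has half-voxel plateau jumps — several degrees of artificial landscape
  roughness at coarse voxel sizes — which both traps the optimizer and
  displaces the apparent optimum.
* **Polish updates are accepted, not gated.** The continuous (Nelder-Mead
  over an axis-angle offset) polish starts at the current pose, so its score
  against the current reference never decreases and the refined pose is
  applied directly. Gating the update on a score recorded in an earlier pass
  would compare numbers measured against different references, and in
  practice it freezes exactly the particles that most need the correction.

A constraint to respect when choosing the box: the voxel size must leave the
box Nyquist frequency *below* the resolution the data can actually reach,
otherwise the FSC never crosses the threshold inside the measured range and
the reported "resolution" is just the Nyquist bound.

## 5. Classification

`cpca_features()` implements constrained principal component analysis: each
aligned subtomogram is compared with the global average inside a focused
real-space mask (e.g. around a candidate ligand site) and over its own sampled
Fourier region only, and the leading principal components of these masked,
wedge-compensated difference volumes are the features. k-means on the
features separates occupancy classes; the tests plant a 71/29 two-class
mixture and require the recovered minor-class fraction within ±5 percentage
points and ≥90% label accuracy.

## 6. Model fitting and screw decomposition

The `fitmodel` functions fit atomic models (rigid, domain-wise, helix-axis
scan, elastic) into density and compare conformations.
`screw_decompose()` expresses any rigid transform as a rotation about a line
plus a translation along it (Chasles' theorem); it is the natural language
for describing domain motions such as a lateral-gate opening (a rotation of
one half of a channel about a hinge axis, plus an axial shift):

```{r screw}
tr <- rigid_transform(axis_angle_matrix(c(0, 0, 1), 22),
                      c(0, 0, 13.8))
screw_decompose(tr)
```

Edge cases: for near-zero angles the axis is undefined and flagged
(`axis_defined = FALSE`) — including the numerically delicate case of a
symmetric rotation matrix with trace just below 3, where `acos` rounding
reports a tiny angle but the skew part, from which the axis is read, vanishes
exactly.

## 7. The simulator: realism and limitations

`build_scene()` places particles on the surface of a vesicle (membrane
rendered as a Gaussian shell), with orientations normal to the membrane plus
jitter, together with free particles and gold fiducials.
`project_tilt_series()` projects with a dose-dependent noise model and an
optional CTF per tilt; `phase_flip()` corrects the CTF sign only, which
**preserves the native contrast** — protein is *darker* than solvent, so the
reconstructed tomogram has negative protein density and the matching stage
inverts it before correlating against a positive-density template.
`weighted_backprojection()` applies the standard ramp-like weighting before
smearing each tilt back through the volume.

The phantom is a blob-model ribosome (large body, two feet, optional ligand
sub-densities with set occupancies), not an atomic structure: adequate for
exercising the geometry, statistics, and failure modes of the pipeline, but
the absolute resolutions are only meaningful relative to each other. Other
simplifications: a single global defocus gradient rather than per-particle
defocus, no beam-induced sample deformation beyond rigid frame drift, and
noise that is Gaussian after binning rather than counting-statistics exact.

## 8. End-to-end pipeline

`run_pipeline(pipeline_config(...))` chains everything — scene, tilt series,
reconstruction, matching, subtomogram extraction, two-round averaging with
gold-standard validation, classification, and model fitting — and writes a
JSON report. The `inst/scripts/tomopipe.R` command-line driver
exposes each stage (`simulate`, `reconstruct`, `match`, …, `run-all`) with a
YAML configuration.
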
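---
title: "Methods: simulating the effective laminar resolution of cortical-depth fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the effective laminar resolution of cortical-depth fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarsim)
```

## The problem

Laminar fMRI tries to resolve activity across the depth of the cortical
grey-matter ribbon. Sub-millimetre isotropic voxels (0.7--0.8 mm) are still
large compared to cortical layers, so the standard analysis spatially
upsamples the functional data, assigns interpolated samples to equidistant
depth bins, and averages over an extended region of interest (ROI),
relying on the quasi-random jitter of voxel positions relative to the
cortical layers to recover sub-voxel depth structure. `laminarsim`
quantifies how well this actually works: it injects a known laminar
activation profile into a synthetic cortex, samples it with jittered
isotropic voxel grids, runs the standard reconstruction, and measures the
agreement between induced and reconstructed profiles. Two companion
analyses simulate the partial-volume leakage of a pial-boundary BOLD
signal at two voxel sizes, and the trial-wise PCA used to show that
tangential BOLD variability is reproducible rather than thermal.

## Synthetic cortex

The cortex is a two-dimensional ribbon (depth x tangential distance):
the acquisitions being emulated are single slices, and even a convoluted
cortex is locally flat at this scale. Boundaries are slowly varying
curves placed symmetrically about the mid-surface; thickness is either
constant (`make_flat_patch()`) or a seeded smooth random field rescaled
to span 1.7--3.7 mm (`make_variable_patch()`), the anatomical range of
the visual cortex this emulates. The tangential correlation length of
the thickness variation defaults to 5 mm. The normalized depth
coordinate is *equidistant* (0 at the CSF boundary, 1 at the WM
boundary); on a 2-D ribbon there is no volume-wedge effect, so
equivolume and equidistant layering coincide up to curvature terms that
the ribbon does not model. The convention is recorded in each patch
(`depth_convention`).

Internally the ribbon is rasterized at 0.01 mm pitch, at least ten times
finer than the finest voxel simulated (0.1--0.125 mm), so partial-volume
integration error is negligible relative to the effects studied. Raster
cells store Gauss--Legendre cell averages across depth, which makes
boxcar voxel means quadrature-exact when voxel edges align with cell
edges; tests compare them against closed-form erf integrals at
`1e-6` relative tolerance.

## Activation fields

* **Induced laminar PSF** (`induced_psf()`): a Gaussian in normalized
  depth, constant tangentially, with FWHM a fixed fraction (default 1/5)
  of the *local* cortical depth, centred mid-cortex by default. The
  Gaussian is truncated at the boundaries without renormalization -- it
  is an activation profile, not a probability density, so truncated
  tails are simply lost.
* **Pial rim** (`pial_boundary_field()`): a boxcar band centred on the
  GM--CSF boundary, emulating a strong BOLD response confined to
  pial/CSF-boundary vessels. The width and amplitude are configurable
  (defaults 0.2 mm, 1); the leakage comparison is reported
  qualitatively, as an ordering of depth extents, so the exact rim
  parameters are not critical.
* **Timecourses** (`timecourse_model()`, `simulate_trials()`): a boxcar
  stimulus convolved with a double-gamma impulse response (peak delay
  5 s, undershoot delay 15 s, undershoot ratio 1/6 -- the canonical BOLD
  phenomenology), scaled by a depth gain that increases linearly from 1
  at the WM boundary to 3 at the CSF boundary. Both the positive
  response and the post-stimulus undershoot therefore grow towards the
  pial surface, as observed empirically. A fixed seeded tangential
  modulation (multiplicative, SD 0.3, correlation length 2 mm) is shared
  across trials; a per-trial global gain (`N(1, 0.2)`) models
  trial-to-trial response-amplitude fluctuation. The gain term matters:
  without it every trial carries the same deterministic signal, the
  column-centred trial matrix is pure noise, and no PCA could recover
  the tangential pattern. With it, the shared pattern enters the
  across-trial covariance and loads on the first principal component.

## Voxel sampling

`place_grid()` lays an axis-aligned isotropic lattice over the ribbon
with a uniformly drawn offset in `[0, voxel)^2` -- the spatial jitter of
voxels relative to the layers. `measure()` computes each voxel's
noiseless signal as the mean of the field over the voxel footprint
(boxcar sampling kernel) via a summed-area table, so Monte-Carlo
realizations cost almost nothing beyond grid placement. The boxcar is
the minimal defensible kernel for this geometry; the true EPI
point-spread function of a given sequence is wider, so the boxcar gives
a slightly optimistic bound on the reconstruction quality.

Noise is additive white Gaussian, independent across voxels, with
SD = (peak noiseless signal over the grid) / SNR; this peak-referenced
definition makes SNR = 1 maximally pessimistic, matching the "realistic"
simulation level, with SNR = infinity as the ideal case. Partial-volume
fractions per voxel are obtained by classifying raster cells
(`partial_volume_fractions()`); they sum to one by construction.

## Depth analyses

`upsample_and_bin()` is the standard pipeline: bilinear interpolation of
the measured voxel lattice onto a grid 10x finer (linear interpolation
is the least-assumption choice among the "various techniques" in use;
the factor is configurable), assignment of each interpolated sample
inside grey matter to one of `N` equidistant half-open depth bins
`[k/N, (k+1)/N)` (last bin closed), and averaging per bin over the whole
ROI. Empty bins propagate as `NA`, never as silent zeros, and the
overlap metric refuses profiles with missing bins. All profiles are
ordered from the CSF boundary (index 1) to the WM boundary.
`centroid_sort_profile()` implements the interpolation-free alternative:
whole voxels are assigned to bins by their centroid depth.

A consequence worth knowing: with a field confined to grey matter, bins
adjacent to the boundaries are diluted by voxels that straddle the
boundary -- that is the partial-volume effect itself, not an artefact of
the implementation, and it is exactly the mechanism probed by the
pial-leakage experiment.

`extract_positive_and_undershoot()` averages each depth's timecourse
over a positive window `[onset + lag, offset]` and an undershoot window
`[offset + lag, offset + lag + window]`. With the canonical response
above, the signal crosses zero about 8 s after stimulus offset and
troughs near 11 s, so the defaults are `lag = 8 s`, `window = 12 s`;
with these the undershoot profile of the default generator is strictly
negative at every depth.

Profile normalization offers `peak` and `unit_area` modes; a reference
profile can supply the scale factor so that, e.g., an undershoot profile
can be scaled by its positive-response peak and their ratio stays
interpretable.

## The overlap experiment

`run_overlap_experiment()` reproduces the effective-resolution study.
Per realization: a freshly jittered 0.75 mm grid samples the induced
PSF; a contiguous tangential block of columns containing exactly the
requested number of grey-matter voxels is selected at a random feasible
position (surplus voxels of the last column are trimmed deepest-first);
the profile is reconstructed at 21 (or 3) sampled depths; and the
percent overlap with the induced profile is computed as 100 times the
integral of the pointwise minimum of the two unit-area profiles. This
metric is bounded in [0, 100], symmetric, scale-invariant, and 100 only
for identical shapes. Negative lobes of noisy reconstructions are
clipped to zero before normalization (flagged on the result); a
reconstruction with no positive mass carries no shape information and
scores 0.

The default cortex is sized to host at least 1000 grey-matter voxels
regardless of the ROI sizes requested, so that every ROI size is a
subset of one full-size simulation -- on short ribbons the ROI-24
overlap inherits several percentage points of variance from the
particular thickness realization. Means, SDs and Monte-Carlo standard
errors are reported per ROI size, along with the RMS error between the
unit-area reconstructed and induced profiles (whose across-realization
SD is the reliability measure that shrinks with ROI size at SNR = 1).

Problem sizes used by the shipped tests and the acceptance script: 200
realizations for the ideal-SNR overlap curve, 500 for the SNR = 1
reliability curve, 100 jittered realizations per voxel size for the
pial-leakage comparison, and 100 replicate stacks per noise level for
the PCA noise sweep. At these sizes the Monte-Carlo standard error of
the headline overlap is about 0.5 percentage points.

## The PCA assessment

`build_trial_matrix()` collapses each trial's positive-BOLD window
average over grey-matter depths into one tangential profile (the
depth-resolved alternative is available by operating on the arrays
directly); `pca_explained_variance()` centres the columns and takes the
SVD. Trials are observations and tangential positions variables, so
"variance explained by the first PC" refers to across-trial variability
of spatial profiles. No rotation is applied. PC1's sign is fixed by
non-negative correlation with the mean tangential profile. Explained
variances are checked against an independent eigen-decomposition of the
empirical covariance at `1e-8`.

## What the generator does and does not emulate

The synthetic data reproduce the *statistical structure* the analyses
rely on: jittered sampling of a smooth laminar profile, partial-volume
mixing at tissue boundaries, peak-referenced thermal noise, a
depth-increasing response with undershoot, and reproducible tangential
structure under trial-gain fluctuation. They do not model vascular
drainage (ascending-vein contamination of deep-layer signal),
susceptibility "blooming" from pial vessels, EPI distortions, T2* decay
during readout, slice profiles, or motion. Passing tests therefore
validate the analysis chain and its statistical behaviour, not the
biophysics of real laminar BOLD data; the acquisition-specific sampling
kernel can be substituted for the boxcar when known.

## Numerical choices and degenerate inputs

* Raster pitch 0.01 mm; Gauss--Legendre cell averages (5 nodes) across
  depth; voxel edges snap to the nearest raster cell edge (worst-case
  placement quantization 0.5 cells, i.e. < 1% of a 0.75 mm voxel).
* Depth bins half-open with the last closed, so `d = 1` is always
  binned; bin centres at `(k + 0.5)/N`.
* Resampling between depth grids is linear with constant extension
  beyond the outermost bin centres.
* Zero-variance trial stacks, all-zero profiles under peak
  normalization, ROIs larger than the available grey matter, windows
  outside the sampled time range, and non-positive dimensions are all
  rejected with descriptive errors rather than propagated.
* Every stochastic stage (patch, jitter, noise, ROI position, trial
  gains) derives its seed deterministically from one master seed; equal
  configurations reproduce byte-identical outputs.

## Known limitations

* The boxcar sampling kernel underestimates the blurring of a real EPI
  acquisition; reported overlaps are upper bounds in that respect.
* The 2-D ribbon has no gyral folding, so curvature-driven layering
  effects (and the equivolume/equidistant distinction) are out of reach.
* The pial rim's width and amplitude are not empirically calibrated;
  only orderings across voxel sizes should be interpreted.
* Real-data quantities (subject-level PC1 percentages, F- and t-tests)
  require the original acquisitions and are deliberately not reproduced;
  the package reproduces the procedures and their behaviour on synthetic
  data.
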
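# laminarsim

Synthetic-cortex simulations for laminar fMRI: how much laminar detail
does a sub-millimetre *isotropic* acquisition actually resolve once the
standard upsample-and-bin depth analysis has run?

Laminar fMRI infers cortical-depth profiles from voxels (0.7–0.8 mm)
that are large relative to the layers themselves. The standard analysis
upsamples the functional data, assigns interpolated samples to `N`
equidistant depth bins (`d = 0` at the CSF boundary, `d = 1` at the
white-matter boundary), and averages over an extended region of interest
(ROI), counting on the quasi-random jitter of voxel positions relative
to the cortical layers. `laminarsim` measures what survives this chain:

* a 2-D synthetic cortical ribbon with variable thickness (1.7–3.7 mm);
* an induced laminar point-spread function (PSF): a Gaussian in
  normalized depth with FWHM ≈ 1/5 of the cortical depth;
* jittered isotropic voxel sampling (boxcar kernel, partial-volume
  mixing, additive noise at peak-referenced SNR ∈ {∞, 1});
* reconstruction by 10× upsampling + equidistant binning (or by voxel
  centroid sorting), and the **percent overlap**

  `overlap = 100 · ∫ min(p_induced(d), p_reconstructed(d)) dd`

  between the unit-area induced and reconstructed profiles;
* a partial-volume simulation of pial-boundary BOLD leakage at 0.75 mm
  vs 0.125 mm voxels;
* a trial-wise PCA of tangential positive-BOLD profiles quantifying
  reproducible (non-thermal) tangential variability, with the percent
  variance explained by the first principal component.

Everything runs on synthetic data generated in code; there are no
downloads. See `vignettes/laminar-resolution-methods.Rmd` for the model
and the design decisions.

## Worked example

```r
library(laminarsim)

patch <- make_variable_patch(1.7, 3.7, length_mm = 30, smoothness_mm = 5, seed = 42)
patch
#> <cortex_patch> variable, length 30.0 mm, thickness 1.70-3.70 mm, raster 0.01 mm (equidistant depth)

field  <- induced_psf(center_depth = 0.5, fwhm_fraction = 0.2)
grid   <- place_grid(patch, 0.75, jitter_seed = 1)
grid
#> <voxel_grid> 0.75 mm isotropic, 11 rows x 41 cols, offset (0.199, 0.279) mm

sample <- measure(field, patch, grid, snr = Inf)
roi    <- roi_select(sample, 24, start_col = 10)       # 24 GM voxels
rec    <- upsample_and_bin(sample, patch, n_depths = 21, roi = roi)
overlap_percent(psf_profile(0.5, 0.2), rec)
#> [1] 74.2   (one jitter realization; the Monte-Carlo mean is lower)
```

A single realization can get lucky; the experiment driver averages over
freshly jittered grids (here 50 realizations for speed — the shipped
analyses use 200):

```r
run_overlap_experiment(roi_sizes = c(24, 100), snr = Inf,
                       n_depths_sampled = 21, n_realizations = 50, seed = 1)
#>   roi_size mean_overlap_pct sd_overlap se_mc mean_profile_rmse sd_profile_rmse
#> 1       24            64.69       8.37  1.18              0.96            0.21
#> 2      100            66.67       6.43  0.91              0.92            0.17
```

So a ~24-voxel ROI (4 depth × 8 distance) recovers only about two thirds
of the induced laminar profile even with *noise-free* data, and going to
100 voxels adds ~2 percentage points: the effective laminar resolution
of the isotropic acquisition is limited by the sampling itself, not by
averaging. `run_pial_leakage_experiment()` and
`pca_explained_variance()` drive the other two analyses, and
`run_pipeline()` runs any of them from a YAML configuration (see
`inst/cli/laminarsim.R` for the command-line front end with
`simulate-resolution`, `simulate-pial`, `simulate-trials`,
`analyze-pca` and `depth-profile` subcommands).

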
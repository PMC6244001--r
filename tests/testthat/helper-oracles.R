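# Shared fixtures and independent closed-form oracles.

# Flat reference cortex: 3 mm thick, CSF boundary at +1.5 mm.
flat3 <- function(length_mm = 10, resolution_mm = 0.01)
  make_flat_patch(3, length_mm, resolution_mm = resolution_mm)

# Depth-direction standard deviation (in mm) of the induced Gaussian PSF
# on a cortex of the given thickness.
sigma_y_of <- function(fwhm_fraction, thickness_mm)
  thickness_mm * fwhm_fraction / (2 * sqrt(2 * log(2)))

# Closed-form mean of a Gaussian (centre 0 in y, sd sigma_y, peak 1) over
# the interval [a, b]: the erf oracle for boxcar voxel means.
gauss_interval_mean <- function(a, b, sigma_y) {
  sigma_y * sqrt(2 * pi) / (b - a) * (pnorm(b / sigma_y) - pnorm(a / sigma_y))
}

# Closed-form Gaussian convolved with a boxcar of width v, evaluated at y
# (both centred at 0): the asymptotic voxel-signal profile.
gauss_conv_box <- function(y, sigma_y, v) {
  sigma_y * sqrt(2 * pi) / v *
    (pnorm((y + v / 2) / sigma_y) - pnorm((y - v / 2) / sigma_y))
}
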
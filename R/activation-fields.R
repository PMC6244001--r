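#' Continuous activation fields over a cortical patch
#'
#' An `activation_field` is a continuous scalar signal-amplitude function
#' over a cortical ribbon. Internally it is a function `fn(d, x, t)` of the
#' signed equidistant depth `d` (negative above the CSF boundary, greater
#' than 1 below the WM boundary), the tangential position `x` (mm) and the
#' local cortical thickness `t` (mm), which is enough to express both
#' depth-parameterized laminar profiles and physically-parameterized
#' boundary rims. Amplitude is zero outside the field's support.
#'
#' @name activation_field
#' @keywords internal
NULL

new_activation_field <- function(fn, label, support = "gm", meta = list()) {
  structure(list(fn = fn, label = label, support = support, meta = meta),
            class = "activation_field")
}

#' Evaluate an activation field at physical points
#'
#' @param field An `activation_field`.
#' @param patch The `cortex_patch` the field lives on.
#' @param x,y Point coordinates in mm (vectorized, recycled).
#' @return Signal amplitude at each point (zero outside the support).
#' @export
field_amplitude <- function(field, patch, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  b <- patch_boundaries(patch, x)
  t <- b$csf - b$wm
  field$fn((b$csf - y) / t, x, t)
}

#' @export
print.activation_field <- function(x, ...) {
  cat(sprintf("<activation_field> %s (support: %s)\n", x$label, x$support))
  invisible(x)
}

#' Induced laminar point-spread function
#'
#' Gaussian activation profile in normalized depth, constant along the
#' tangential direction within grey matter: the ground-truth laminar signal
#' injected into the resolution simulations. Its full width at half maximum
#' is a fixed fraction of the local cortical depth (default 1/5), so the
#' physical width scales with thickness on variable-thickness ribbons. The
#' Gaussian is truncated at the cortical boundaries without renormalization
#' (it is an activation profile, not a density).
#'
#' @param center_depth Peak position in normalized depth, in `[0, 1]`.
#' @param fwhm_fraction Full width at half maximum as a fraction of
#'   cortical depth, in `(0, 1)`.
#' @param peak_amplitude Amplitude at the peak (signal units).
#' @return An `activation_field`.
#' @examples
#' f <- induced_psf(0.5, 0.2, 1)
#' p <- make_flat_patch(3, 10)
#' field_amplitude(f, p, 5, 0)     # peak at mid-depth
#' @export
induced_psf <- function(center_depth = 0.5, fwhm_fraction = 0.2,
                        peak_amplitude = 1) {
  if (!is.numeric(fwhm_fraction) || fwhm_fraction <= 0 || fwhm_fraction >= 1)
    stop("fwhm_fraction must lie strictly between 0 and 1")
  if (center_depth < 0 || center_depth > 1)
    stop("center_depth must lie in [0, 1]")
  if (peak_amplitude <= 0) stop("peak_amplitude must be positive")
  sigma <- fwhm_fraction / (2 * sqrt(2 * log(2)))
  fn <- function(d, x, t) {
    a <- peak_amplitude * exp(-(d - center_depth)^2 / (2 * sigma^2))
    a[d < 0 | d > 1] <- 0
    a
  }
  new_activation_field(fn, sprintf("induced PSF (center %.2f, FWHM %.2f)",
                                   center_depth, fwhm_fraction),
                       meta = list(center_depth = center_depth,
                                   fwhm_fraction = fwhm_fraction,
                                   sigma_depth = sigma,
                                   peak_amplitude = peak_amplitude))
}

#' Spatially constant grey-matter field
#'
#' Uniform amplitude inside grey matter, zero elsewhere. Mostly useful as a
#' degenerate reference in validation.
#'
#' @param value Amplitude inside GM.
#' @return An `activation_field`.
#' @export
constant_gm_field <- function(value = 1) {
  fn <- function(d, x, t) ifelse(d >= 0 & d <= 1, value, 0)
  new_activation_field(fn, sprintf("constant GM field (%g)", value))
}

#' Pial-boundary BOLD rim field
#'
#' Boxcar band of signal confined to a thin rim centred on the GM-CSF
#' boundary, emulating a strong BOLD response in pial/CSF-boundary vessels.
#' Half of the rim lies in the CSF margin, half in the most superficial
#' grey matter.
#'
#' @param rim_width_mm Full rim width in mm; must be much smaller than the
#'   thinnest cortex of `patch`.
#' @param peak_amplitude Amplitude inside the rim.
#' @param patch The `cortex_patch` the rim is validated against.
#' @return An `activation_field` with support extending into the CSF rim.
#' @export
pial_boundary_field <- function(rim_width_mm, peak_amplitude = 1, patch) {
  if (rim_width_mm <= 0) stop("rim_width_mm must be positive")
  tmin <- min(patch$csf_y - patch$wm_y)
  if (rim_width_mm >= tmin)
    stop(sprintf("rim width (%g mm) must be smaller than the thinnest cortex (%g mm)",
                 rim_width_mm, tmin))
  fn <- function(d, x, t) {
    # |y - csf_y| = |d| * t
    ifelse(abs(d) * t <= rim_width_mm / 2, peak_amplitude, 0)
  }
  new_activation_field(fn, sprintf("pial rim (width %g mm)", rim_width_mm),
                       support = "gm+csf_rim",
                       meta = list(rim_width_mm = rim_width_mm,
                                   peak_amplitude = peak_amplitude))
}

#' Double-gamma hemodynamic response
#'
#' Canonical BOLD impulse response: difference of two gamma densities with
#' configurable peak delay, undershoot delay and undershoot ratio. With
#' `undershoot_ratio = 0` the response has no post-stimulus undershoot.
#'
#' @param t Time in seconds (vectorized).
#' @param peak_delay_s Mode of the positive lobe (s).
#' @param undershoot_delay_s Mode of the undershoot lobe (s).
#' @param undershoot_ratio Amplitude ratio of undershoot to positive lobe.
#' @return Impulse-response values (arbitrary units).
#' @export
bold_hrf <- function(t, peak_delay_s = 5, undershoot_delay_s = 15,
                     undershoot_ratio = 1 / 6) {
  dgamma(t, shape = peak_delay_s + 1, scale = 1) -
    undershoot_ratio * dgamma(t, shape = undershoot_delay_s + 1, scale = 1)
}

#' Depth- and distance-resolved BOLD timecourse model
#'
#' Deterministic spatio-temporal signal model used by [simulate_trials()]:
#' a boxcar stimulus convolved with a double-gamma hemodynamic response,
#' scaled by a multiplicative depth gain (non-decreasing towards the CSF
#' boundary, reproducing the amplitude increase of both the positive
#' response and the undershoot towards the pial surface) and a fixed seeded
#' tangential modulation shared across trials (the reproducible tangential
#' variability that the PCA analysis is meant to recover).
#'
#' @param stimulus_onset_s,stimulus_duration_s Stimulus window (s).
#' @param total_duration_s Length of the simulated run (s).
#' @param dt_s Sampling interval (s).
#' @param peak_delay_s,undershoot_delay_s,undershoot_ratio Hemodynamic
#'   response parameters, see [bold_hrf()].
#' @param depth_gain Function of normalized depth `d` giving the
#'   multiplicative response amplitude; must be non-increasing in `d`
#'   (largest at the CSF boundary). Default: linear from 3 at the CSFB to
#'   1 at the WMB.
#' @param trial_gain_sd Standard deviation of the per-trial global
#'   response gain about 1. Trial-to-trial amplitude fluctuation is what
#'   makes the shared tangential pattern appear in the across-trial
#'   covariance (and hence in the first principal component); with 0 every
#'   trial carries an identical deterministic signal.
#' @param tangential_modulation_amp Standard deviation of the multiplicative
#'   tangential gain about 1 (0 disables modulation).
#' @param tangential_smoothness_mm Correlation length of the tangential
#'   modulation (mm).
#' @param modulation_seed Seed fixing the shared tangential pattern.
#' @return A `timecourse_model` object.
#' @export
timecourse_model <- function(stimulus_onset_s = 8, stimulus_duration_s = 16,
                             total_duration_s = 60, dt_s = 1,
                             peak_delay_s = 5, undershoot_delay_s = 15,
                             undershoot_ratio = 1 / 6,
                             depth_gain = function(d) 1 + 2 * (1 - d),
                             trial_gain_sd = 0.2,
                             tangential_modulation_amp = 0.3,
                             tangential_smoothness_mm = 2,
                             modulation_seed = 1) {
  stopifnot(stimulus_onset_s >= 0, stimulus_duration_s > 0,
            total_duration_s > stimulus_onset_s + stimulus_duration_s,
            dt_s > 0, undershoot_ratio >= 0, trial_gain_sd >= 0,
            tangential_modulation_amp >= 0)
  dg <- depth_gain(seq(0, 1, length.out = 101))
  if (any(diff(dg) > 1e-9))
    stop("depth_gain must be non-increasing in depth (largest at the CSF boundary)")
  structure(list(
    stimulus_onset_s = stimulus_onset_s,
    stimulus_duration_s = stimulus_duration_s,
    total_duration_s = total_duration_s, dt_s = dt_s,
    peak_delay_s = peak_delay_s, undershoot_delay_s = undershoot_delay_s,
    undershoot_ratio = undershoot_ratio,
    depth_gain = depth_gain,
    trial_gain_sd = trial_gain_sd,
    tangential_modulation_amp = tangential_modulation_amp,
    tangential_smoothness_mm = tangential_smoothness_mm,
    modulation_seed = as.integer(modulation_seed)
  ), class = "timecourse_model")
}

## Stimulus-convolved response timecourse, peak-normalized to 1.
model_response <- function(model) {
  times <- seq(0, model$total_duration_s, by = model$dt_s)
  h <- bold_hrf(seq(0, 40, by = model$dt_s), model$peak_delay_s,
                model$undershoot_delay_s, model$undershoot_ratio)
  box <- as.numeric(times >= model$stimulus_onset_s &
                    times < model$stimulus_onset_s + model$stimulus_duration_s)
  r <- stats::convolve(box, rev(h), type = "open")[seq_along(times)] * model$dt_s
  list(times = times, response = r / max(r))
}

## Shared tangential gain profile at positions x.
model_tangential_modulation <- function(model, x) {
  if (model$tangential_modulation_amp == 0) return(rep(1, length(x)))
  1 + model$tangential_modulation_amp *
    smooth_random_field(x, model$tangential_smoothness_mm, model$modulation_seed)
}

#' Simulate noisy trial-wise BOLD responses on a depth x distance grid
#'
#' Each trial is the deterministic spatio-temporal signal
#' `response(t) * depth_gain(d) * tangential_modulation(x)`, scaled by a
#' per-trial global response gain (`N(1, trial_gain_sd)`), plus
#' independent Gaussian noise. The tangential modulation is a fixed seeded
#' pattern shared across trials; the per-trial gain fluctuation carries it
#' into the across-trial covariance that the PCA analysis decomposes. With
#' `trial_gain_sd = 0` and `noise_sd = 0` all trials are identical.
#'
#' @param model A [timecourse_model()].
#' @param patch A `cortex_patch` (sets the tangential extent).
#' @param n_trials Number of trials (>= 2).
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   units of the peak noiseless response.
#' @param seed Integer seed for the noise.
#' @param n_depths,n_x Size of the evaluation grid.
#' @return A `trial_set`: list with `trials` (list of `n_depths x n_x x
#'   n_times` arrays), `times`, `depths` (bin centres, CSFB first), `x`,
#'   the generating `model`, the realized `tangential_modulation`,
#'   `noise_sd` and `seed`.
#' @export
simulate_trials <- function(model, patch, n_trials, noise_sd, seed,
                            n_depths = 30, n_x = 40) {
  stopifnot(inherits(model, "timecourse_model"))
  if (n_trials < 2) stop("n_trials must be at least 2")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  resp <- model_response(model)
  depths <- depth_bin_centers(n_depths)
  x <- seq(min(patch$x), max(patch$x), length.out = n_x)
  mod <- model_tangential_modulation(model, x)
  spatial <- outer(model$depth_gain(depths), mod)     # n_depths x n_x
  base <- outer(spatial, resp$response)               # n_depths x n_x x n_t
  set.seed(as.integer(seed))
  gains <- if (model$trial_gain_sd > 0)
    rnorm(n_trials, mean = 1, sd = model$trial_gain_sd) else rep(1, n_trials)
  trials <- lapply(seq_len(n_trials), function(i) {
    if (noise_sd == 0) gains[i] * base
    else gains[i] * base + array(rnorm(length(base), sd = noise_sd),
                                 dim = dim(base))
  })
  structure(list(trials = trials, times = resp$times, depths = depths,
                 x = x, model = model, tangential_modulation = mod,
                 trial_gains = gains, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "trial_set")
}
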
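#' Cortical depth profiles
#'
#' A `depth_profile` holds signal amplitude at `n_depths` ordered
#' equidistant normalized depths. Depth bins are half-open intervals
#' `[k/N, (k+1)/N)` with the last bin closed; bin centres are reported at
#' `(k + 0.5)/N`, ordered from the CSF boundary (`d = 0`, first element)
#' to the WM boundary (`d = 1`, last element). Empty bins are kept as
#' missing values, never silently zeroed.
#'
#' @param values Amplitude per depth bin (may contain `NA` for empty bins).
#' @param n_samples Number of samples contributing per bin (optional).
#' @param normalization One of `"none"`, `"peak"`, `"unit_area"`.
#' @param depths Bin centres; default equidistant centres.
#' @return A `depth_profile` object.
#' @export
depth_profile <- function(values, n_samples = NULL, normalization = "none",
                          depths = depth_bin_centers(length(values))) {
  stopifnot(length(depths) == length(values), !is.unsorted(depths),
            all(depths >= 0 & depths <= 1))
  normalization <- match.arg(normalization, c("none", "peak", "unit_area"))
  structure(list(n_depths = length(values), depths = depths,
                 values = as.numeric(values),
                 n_samples = n_samples, normalization = normalization),
            class = "depth_profile")
}

#' Equidistant depth-bin centres
#' @param n Number of depth bins.
#' @return Centres `(k + 0.5)/n`, `k = 0, ..., n-1`, CSF boundary first.
#' @export
depth_bin_centers <- function(n) (seq_len(n) - 0.5) / n

## Bin index for normalized depth d in [0, 1]; half-open bins, last closed.
depth_bin_index <- function(d, n) as.integer(pmin(floor(d * n), n - 1L) + 1L)

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d depths (CSFB first), normalization: %s\n",
              x$n_depths, x$normalization))
  print(data.frame(depth = round(x$depths, 4), value = x$values))
  invisible(x)
}

## Region-of-interest descriptor used by the profile estimators: a
## contiguous block of grid columns, optionally with the deepest GM voxels
## of the last column trimmed so the GM voxel count is exact.
roi_spec <- function(cols, trim_col = NA_integer_, trim_y_below = -Inf,
                     n_gm = NA_integer_) {
  list(cols = cols, trim_col = trim_col, trim_y_below = trim_y_below,
       n_gm = n_gm)
}

#' Standard depth analysis: upsample voxel data and bin by depth
#'
#' The conventional laminar analysis for isotropic acquisitions: measured
#' voxel values are linearly interpolated onto a lattice `upsample_factor`
#' times finer than the voxel grid, every interpolated sample falling
#' inside grey matter is assigned to the equidistant depth bin containing
#' its normalized depth, and the profile value is the mean over all
#' assigned samples across the region of interest.
#'
#' @param sample A [measure()] result covering the full grid.
#' @param patch The `cortex_patch` the sample was drawn on.
#' @param n_depths Number of depth bins (>= 2 unless collapsing to the
#'   overall GM mean with `n_depths = 1`).
#' @param upsample_factor Integer upsampling factor (default 10).
#' @param roi Optional ROI descriptor from [roi_select()]; default uses
#'   the whole grid.
#' @return A `depth_profile`; empty bins carry `NA`.
#' @export
upsample_and_bin <- function(sample, patch, n_depths, upsample_factor = 10,
                             roi = NULL) {
  stopifnot(inherits(sample, "voxel_sample"), n_depths >= 1,
            upsample_factor >= 1)
  if (!any(sample$tissue == "gm"))
    stop("sample contains no grey-matter voxels")
  grid <- attr(sample, "grid")
  v <- grid$voxel_size_mm
  n_row <- grid$n_row; n_col <- grid$n_col
  M <- matrix(sample$signal_measured, n_row, n_col)
  cx <- (grid$x_edges[-1] + grid$x_edges[-(n_col + 1L)]) / 2
  cy <- (grid$y_edges[-1] + grid$y_edges[-(n_row + 1L)]) / 2

  if (is.null(roi)) {
    x_lo <- max(min(cx), min(patch$x)); x_hi <- min(max(cx), max(patch$x))
  } else {
    x_lo <- grid$x_edges[roi$cols[1]]
    x_hi <- grid$x_edges[roi$cols[length(roi$cols)] + 1L]
  }
  step <- v / upsample_factor
  xf <- seq(x_lo + step / 2, x_hi, by = step)
  yf <- seq(min(cy), max(cy), by = step)
  Vf <- bilinear_interp(cx, cy, M, xf, yf)

  b <- patch_boundaries(patch, xf)
  CSF <- matrix(b$csf, length(yf), length(xf), byrow = TRUE)
  TH <- matrix(b$csf - b$wm, length(yf), length(xf), byrow = TRUE)
  D <- (CSF - yf) / TH
  keep <- D >= 0 & D <= 1
  if (!is.null(roi) && !is.na(roi$trim_col)) {
    in_trim <- matrix(xf >= grid$x_edges[roi$trim_col] &
                        xf < grid$x_edges[roi$trim_col + 1L],
                      length(yf), length(xf), byrow = TRUE) &
      (yf < roi$trim_y_below)
    keep <- keep & !in_trim
  }
  bins <- depth_bin_index(D[keep], n_depths)
  vals <- Vf[keep]
  sums <- rowsum(vals, bins)
  counts <- tabulate(bins, nbins = n_depths)
  values <- rep(NA_real_, n_depths)
  values[as.integer(rownames(sums))] <- sums[, 1] / counts[as.integer(rownames(sums))]
  if (any(counts == 0))
    warning(sprintf("%d of %d depth bins received no samples (kept as NA)",
                    sum(counts == 0), n_depths))
  depth_profile(values, n_samples = counts)
}

#' Centroid-sorting depth profile
#'
#' Interpolation-free alternative analysis: each voxel whose centroid lies
#' in grey matter contributes its measured value to the depth bin
#' containing its centroid depth; the profile is the per-bin mean. Voxels
#' with non-GM centroids are excluded.
#'
#' @param sample A [measure()] result.
#' @param n_bins Number of depth bins (>= 2, or 1 for the overall mean).
#' @param roi Optional ROI descriptor from [roi_select()].
#' @return A `depth_profile`; empty bins carry `NA`.
#' @export
centroid_sort_profile <- function(sample, n_bins, roi = NULL) {
  stopifnot(inherits(sample, "voxel_sample"), n_bins >= 1)
  gm <- sample$tissue == "gm"
  if (!is.null(roi)) {
    gm <- gm & sample$col %in% roi$cols &
      !(sample$col == roi$trim_col & sample$cy_mm < roi$trim_y_below)
  }
  if (!any(gm)) stop("no grey-matter-centroid voxels to sort")
  bins <- depth_bin_index(sample$centroid_depth[gm], n_bins)
  sums <- rowsum(sample$signal_measured[gm], bins)
  counts <- tabulate(bins, nbins = n_bins)
  values <- rep(NA_real_, n_bins)
  values[as.integer(rownames(sums))] <- sums[, 1] / counts[as.integer(rownames(sums))]
  depth_profile(values, n_samples = counts)
}

#' Positive-BOLD and post-stimulus-undershoot depth profiles
#'
#' Window averages of per-depth timecourses: the positive response is the
#' mean signal in `[onset + rise_lag, onset + duration]`; the undershoot is
#' the mean in `[offset + rise_lag, offset + rise_lag + undershoot_window]`
#' where `offset = onset + duration`.
#'
#' @param timecourses Matrix of per-depth time series (`n_depths` rows,
#'   CSF boundary first) or a 3-D array (`depth x distance x time`), in
#'   which case the tangential dimension is averaged first.
#' @param times Sample times in seconds (length = time dimension).
#' @param stimulus_onset_s,stimulus_duration_s Stimulus window (s).
#' @param rise_lag_s Hemodynamic lag excluded from the start of each
#'   window (s); the default 8 s skips both the initial rise and the
#'   positive post-stimulus decay, so the undershoot window starts at the
#'   zero crossing of the canonical response.
#' @param undershoot_window_s Length of the undershoot window (s).
#' @return List with `positive` and `undershoot` depth profiles.
#' @export
extract_positive_and_undershoot <- function(timecourses, times,
                                            stimulus_onset_s,
                                            stimulus_duration_s,
                                            rise_lag_s = 8,
                                            undershoot_window_s = 12) {
  if (length(dim(timecourses)) == 3)
    timecourses <- apply(timecourses, c(1, 3), mean)
  stopifnot(is.matrix(timecourses), ncol(timecourses) == length(times))
  onset <- stimulus_onset_s
  offset <- stimulus_onset_s + stimulus_duration_s
  pos_win <- times >= onset + rise_lag_s & times <= offset
  und_win <- times >= offset + rise_lag_s &
    times <= offset + rise_lag_s + undershoot_window_s
  if (!any(pos_win) || offset + rise_lag_s + undershoot_window_s > max(times))
    stop("analysis windows fall outside the sampled time range")
  list(
    positive = depth_profile(rowMeans(timecourses[, pos_win, drop = FALSE])),
    undershoot = depth_profile(rowMeans(timecourses[, und_win, drop = FALSE]))
  )
}

#' Normalize a depth profile
#'
#' `peak` scales so the maximum absolute value is 1; `unit_area` scales so
#' the trapezoidal integral over depth is 1. An optional reference profile
#' supplies the scale factor instead (e.g. to scale an undershoot profile
#' by its positive-response peak, keeping their ratio interpretable).
#'
#' @param profile A `depth_profile` without missing values in the bins
#'   used for scaling.
#' @param mode `"peak"` or `"unit_area"`.
#' @param reference Optional `depth_profile` from which the scale factor
#'   is computed.
#' @return The rescaled `depth_profile` (normalization flag updated).
#' @export
normalize_profile <- function(profile, mode = c("peak", "unit_area"),
                              reference = NULL) {
  mode <- match.arg(mode)
  src <- reference %||% profile
  if (all(is.na(src$values))) stop("profile has no non-missing values")
  scale <- if (mode == "peak") {
    s <- max(abs(src$values), na.rm = TRUE)
    if (s == 0) stop("cannot peak-normalize an all-zero profile")
    s
  } else {
    a <- trapz_int(src$depths, src$values)
    if (a == 0) stop("cannot area-normalize a zero-area profile")
    a
  }
  out <- profile
  out$values <- profile$values / scale
  out$normalization <- mode
  out
}

#' Depth extent above a fraction of the profile maximum
#'
#' Largest bin-centre depth whose value is at least `frac` of the profile
#' maximum; used to quantify how deep a boundary-confined signal leaks
#' into the cortex.
#'
#' @param profile A `depth_profile`.
#' @param frac Threshold fraction of the maximum (default 0.1).
#' @return Normalized depth in `[0, 1]`.
#' @export
profile_extent <- function(profile, frac = 0.1) {
  v <- profile$values
  thr <- frac * max(v, na.rm = TRUE)
  max(profile$depths[!is.na(v) & v >= thr])
}

#' Write / read a depth profile as TSV
#'
#' Columns: `depth_center`, `value`, `n_samples`, `normalization`;
#' round-trips losslessly.
#'
#' @param profile A `depth_profile`.
#' @param path File path.
#' @return `write_depth_profile_tsv` returns `path` invisibly;
#'   `read_depth_profile_tsv` returns a `depth_profile`.
#' @export
write_depth_profile_tsv <- function(profile, path) {
  df <- data.frame(depth_center = profile$depths, value = profile$values,
                   n_samples = profile$n_samples %||% NA_integer_,
                   normalization = profile$normalization)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_depth_profile_tsv
#' @export
read_depth_profile_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  depth_profile(df$value, n_samples = df$n_samples,
                normalization = df$normalization[1], depths = df$depth_center)
}
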
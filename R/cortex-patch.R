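#' Synthetic 2-D cortical-ribbon geometry
#'
#' A `cortex_patch` describes a two-dimensional ribbon of grey matter (GM)
#' between a CSF boundary curve (top) and a white-matter boundary curve
#' (bottom), over a tangential extent in millimetres. The ribbon is stored as
#' boundary heights sampled on a fine tangential raster (default pitch
#' 0.01 mm), which is also the integration grid used downstream for
#' partial-volume and voxel-averaging computations.
#'
#' The normalized depth coordinate is equidistant: `d = 0` on the CSF
#' boundary (CSFB) and `d = 1` on the white-matter boundary (WMB). The
#' convention is recorded in the object (`depth_convention`).
#'
#' @name cortex_patch
#' @keywords internal
NULL

new_cortex_patch <- function(x, csf_y, wm_y, resolution_mm, pad_mm, meta = list()) {
  stopifnot(length(x) == length(csf_y), length(x) == length(wm_y))
  if (any(csf_y - wm_y <= 0))
    stop("invalid patch: cortical thickness must be positive everywhere")
  structure(list(
    x = x,
    csf_y = csf_y,
    wm_y = wm_y,
    length_mm = max(x) - min(x),
    resolution_mm = resolution_mm,
    pad_mm = pad_mm,
    y_range = c(min(wm_y) - pad_mm, max(csf_y) + pad_mm),
    depth_convention = "equidistant",
    meta = meta
  ), class = "cortex_patch")
}

#' Flat cortical patch with constant thickness
#'
#' Degenerate ribbon with parallel straight boundaries, centred on the
#' mid-surface `y = 0` (CSF boundary at `+thickness/2`, WM boundary at
#' `-thickness/2`).
#'
#' @param thickness_mm Cortical thickness in mm (positive).
#' @param length_mm Tangential extent in mm (positive).
#' @param resolution_mm Internal raster pitch in mm (default 0.01, at least
#'   ten times finer than the finest voxel used in the simulations).
#' @param pad_mm Height of the CSF/WM margins kept above and below the
#'   ribbon in the rasterized domain (mm).
#' @return A `cortex_patch` object.
#' @examples
#' p <- make_flat_patch(3, 10)
#' patch_thickness(p, c(1, 5, 9))
#' @export
make_flat_patch <- function(thickness_mm, length_mm, resolution_mm = 0.01,
                            pad_mm = 2) {
  if (!is.numeric(thickness_mm) || thickness_mm <= 0)
    stop("thickness_mm must be a positive number")
  if (!is.numeric(length_mm) || length_mm <= 0)
    stop("length_mm must be a positive number")
  x <- seq(0, length_mm, by = resolution_mm)
  new_cortex_patch(
    x = x,
    csf_y = rep(thickness_mm / 2, length(x)),
    wm_y = rep(-thickness_mm / 2, length(x)),
    resolution_mm = resolution_mm, pad_mm = pad_mm,
    meta = list(kind = "flat", thickness_mm = thickness_mm)
  )
}

#' Cortical patch with smoothly varying thickness
#'
#' Thickness is a seeded smooth random field (Gaussian correlation length
#' `smoothness_mm`) rescaled to attain exactly the range
#' `[thickness_min_mm, thickness_max_mm]`, emulating an anatomically
#' plausible cortex whose thickness varies between about 1.7 and 3.7 mm.
#' Boundaries are placed symmetrically about the mid-surface `y = 0`.
#'
#' @param thickness_min_mm,thickness_max_mm Thickness range in mm;
#'   `0 < min < max`.
#' @param length_mm Tangential extent in mm.
#' @param smoothness_mm Tangential correlation length of the thickness
#'   variation in mm.
#' @param seed Integer seed; identical seeds give bit-identical patches.
#' @inheritParams make_flat_patch
#' @return A `cortex_patch` object.
#' @examples
#' p <- make_variable_patch(1.7, 3.7, 20, 5, seed = 42)
#' range(patch_thickness(p, p$x))
#' @export
make_variable_patch <- function(thickness_min_mm = 1.7, thickness_max_mm = 3.7,
                                length_mm = 20, smoothness_mm = 5, seed = 1,
                                resolution_mm = 0.01, pad_mm = 2) {
  if (!is.numeric(thickness_min_mm) || thickness_min_mm <= 0)
    stop("thickness_min_mm must be positive")
  if (thickness_min_mm >= thickness_max_mm)
    stop("thickness_min_mm must be strictly less than thickness_max_mm")
  if (length_mm <= 0) stop("length_mm must be positive")
  if (smoothness_mm <= 0) stop("smoothness_mm must be positive")
  x <- seq(0, length_mm, by = resolution_mm)
  s <- smooth_random_field(x, smoothness_mm, seed)
  s01 <- (s - min(s)) / (max(s) - min(s))
  t <- thickness_min_mm + (thickness_max_mm - thickness_min_mm) * s01
  new_cortex_patch(
    x = x, csf_y = t / 2, wm_y = -t / 2,
    resolution_mm = resolution_mm, pad_mm = pad_mm,
    meta = list(kind = "variable", thickness_range = c(thickness_min_mm, thickness_max_mm),
                smoothness_mm = smoothness_mm, seed = as.integer(seed))
  )
}

## Boundary heights and thickness, linearly interpolated along the raster.
patch_boundaries <- function(patch, x) {
  list(
    csf = approx(patch$x, patch$csf_y, xout = x, rule = 2)$y,
    wm = approx(patch$x, patch$wm_y, xout = x, rule = 2)$y
  )
}

#' Local cortical thickness
#'
#' @param patch A `cortex_patch`.
#' @param x Tangential positions in mm (vectorized).
#' @return Thickness in mm at each `x`.
#' @export
patch_thickness <- function(patch, x) {
  b <- patch_boundaries(patch, x)
  b$csf - b$wm
}

check_in_bbox <- function(patch, x, y) {
  if (any(x < min(patch$x) - 1e-9 | x > max(patch$x) + 1e-9))
    stop("point outside the patch domain (tangential extent)")
  if (any(y < patch$y_range[1] - 1e-9 | y > patch$y_range[2] + 1e-9))
    stop("point outside the patch domain (height range)")
  invisible(TRUE)
}

#' Normalized cortical depth of a point
#'
#' Equidistant depth coordinate: 0 on the CSF boundary, 1 on the WM
#' boundary. Points above the CSF boundary or below the WM boundary are not
#' grey matter and map to `NA`; use [tissue_class()] for their
#' classification. Points outside the rasterized domain are rejected.
#'
#' @param patch A `cortex_patch`.
#' @param x,y Point coordinates in mm (vectorized, recycled).
#' @return Numeric vector of depths in `[0, 1]`, `NA` outside grey matter.
#' @examples
#' p <- make_flat_patch(3, 10)
#' depth_coordinate(p, 5, 0)       # mid-cortex -> 0.5
#' depth_coordinate(p, 5, 1.5)     # on the CSF boundary -> 0
#' @export
depth_coordinate <- function(patch, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  check_in_bbox(patch, x, y)
  b <- patch_boundaries(patch, x)
  d <- (b$csf - y) / (b$csf - b$wm)
  d[d < 0 | d > 1] <- NA_real_
  d
}

#' Tissue classification of a point
#'
#' @inheritParams depth_coordinate
#' @return Factor with levels `csf`, `gm`, `wm`: points above the CSF
#'   boundary are CSF, below the WM boundary are white matter, and in
#'   between (boundaries included) grey matter.
#' @export
tissue_class <- function(patch, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  check_in_bbox(patch, x, y)
  b <- patch_boundaries(patch, x)
  cls <- ifelse(y > b$csf, "csf", ifelse(y < b$wm, "wm", "gm"))
  factor(cls, levels = c("csf", "gm", "wm"))
}

#' @export
print.cortex_patch <- function(x, ...) {
  t <- x$csf_y - x$wm_y
  cat(sprintf(
    "<cortex_patch> %s, length %.1f mm, thickness %.2f-%.2f mm, raster %.3g mm (%s depth)\n",
    x$meta$kind %||% "custom", x$length_mm, min(t), max(t), x$resolution_mm,
    x$depth_convention))
  invisible(x)
}

#' Write / read a cortical patch as TSV
#'
#' Self-describing tabular form with columns `x_mm`, `csf_y_mm`, `wm_y_mm`
#' (one row per raster column); raster pitch and padding are recovered from
#' the coordinates on read.
#'
#' @param patch A `cortex_patch`.
#' @param path File path.
#' @return `write_patch_tsv` returns `path` invisibly; `read_patch_tsv`
#'   returns a `cortex_patch`.
#' @export
write_patch_tsv <- function(patch, path) {
  df <- data.frame(x_mm = patch$x, csf_y_mm = patch$csf_y, wm_y_mm = patch$wm_y)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patch_tsv
#' @export
read_patch_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("x_mm", "csf_y_mm", "wm_y_mm") %in% names(df)))
  new_cortex_patch(df$x_mm, df$csf_y_mm, df$wm_y_mm,
                   resolution_mm = stats::median(diff(df$x_mm)), pad_mm = 2,
                   meta = list(kind = "from_tsv"))
}

#' Export a patch as a 2-D NIfTI label image
#'
#' Labels: 0 = CSF, 1 = grey matter, 2 = white matter; pixel dimensions are
#' set to the raster pitch. Requires the optional `RNifti` package.
#'
#' @param patch A `cortex_patch`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param pitch_mm Raster pitch of the exported image (defaults to the
#'   patch raster pitch; coarser values downsample the label map).
#' @return `path`, invisibly.
#' @export
patch_to_label_nifti <- function(patch, path, pitch_mm = patch$resolution_mm) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("patch_to_label_nifti requires the 'RNifti' package")
  xs <- seq(min(patch$x), max(patch$x), by = pitch_mm)
  ys <- seq(patch$y_range[1], patch$y_range[2], by = pitch_mm)
  cls <- tissue_class(patch, rep(xs, each = length(ys)), rep(ys, length(xs)))
  lab <- matrix(c(csf = 0L, gm = 1L, wm = 2L)[as.character(cls)],
                length(ys), length(xs))
  img <- RNifti::asNifti(lab, pixdim = c(pitch_mm, pitch_mm))
  RNifti::writeNifti(img, path)
  invisible(path)
}
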
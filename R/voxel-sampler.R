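#' Isotropic voxel grids over a cortical patch
#'
#' A `voxel_grid` is an axis-aligned isotropic lattice whose edges sit at
#' integer multiples of the voxel size minus a two-dimensional offset in
#' `[0, voxel_size)`, so a zero offset aligns the lattice to the patch
#' origin. The jittered offset emulates the quasi-random placement of
#' acquisition voxels relative to the cortical layers.
#'
#' @param patch A `cortex_patch`; the grid covers its full rasterized
#'   domain.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param offset_mm Explicit offset `c(ox, oy)` in `[0, voxel_size)`; if
#'   `NULL`, drawn uniformly from `jitter_seed`.
#' @param jitter_seed Integer seed for the uniform offset draw (ignored
#'   when `offset_mm` is given).
#' @return A `voxel_grid`: voxel size, offset, edge coordinates and lattice
#'   extent.
#' @examples
#' p <- make_flat_patch(3, 10)
#' g <- place_grid(p, 0.75, offset_mm = c(0, 0))
#' g$n_col; g$n_row
#' @export
place_grid <- function(patch, voxel_size_mm, offset_mm = NULL,
                       jitter_seed = NULL) {
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be positive")
  v <- voxel_size_mm
  if (is.null(offset_mm)) {
    if (is.null(jitter_seed)) stop("give either offset_mm or jitter_seed")
    set.seed(as.integer(jitter_seed))
    offset_mm <- stats::runif(2, 0, v)
  }
  if (length(offset_mm) != 2 || any(offset_mm < 0) || any(offset_mm >= v))
    stop("offset_mm must be two values in [0, voxel_size_mm)")
  xlo <- min(patch$x); xhi <- max(patch$x)
  ylo <- patch$y_range[1]; yhi <- patch$y_range[2]
  x0 <- -offset_mm[1] + v * floor((xlo + offset_mm[1]) / v)
  y0 <- -offset_mm[2] + v * floor((ylo + offset_mm[2]) / v)
  n_col <- ceiling((xhi - x0) / v - 1e-9)
  n_row <- ceiling((yhi - y0) / v - 1e-9)
  structure(list(
    voxel_size_mm = v, offset_mm = offset_mm,
    x_edges = x0 + v * (0:n_col), y_edges = y0 + v * (0:n_row),
    n_col = as.integer(n_col), n_row = as.integer(n_row)
  ), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %g mm isotropic, %d rows x %d cols, offset (%.3f, %.3f) mm\n",
              x$voxel_size_mm, x$n_row, x$n_col, x$offset_mm[1], x$offset_mm[2]))
  invisible(x)
}

#' Rasterize an activation field for fast voxel averaging
#'
#' Evaluates the field on the patch's fine raster and stores a summed-area
#' table, so that any boxcar voxel footprint can later be averaged in
#' constant time. Each raster cell holds the field's cell average, computed
#' with Gauss-Legendre quadrature across the depth direction (where the
#' laminar fields vary fast) and the cell-centre value tangentially (where
#' variation is slow relative to the pitch); voxel means over footprints
#' whose edges coincide with cell edges are therefore quadrature-exact.
#'
#' @param field An `activation_field`.
#' @param patch A `cortex_patch`.
#' @param xlim,ylim Extent to rasterize (mm); defaults to the patch domain.
#'   Snapped outward to the pitch lattice (anchored at the origin).
#' @param pitch_mm Raster pitch (default: the patch raster pitch).
#' @param gl_nodes Number of Gauss-Legendre nodes per cell in depth.
#' @return A `field_raster`: origin, pitch, dimensions, the summed-area
#'   table and the peak cell value.
#' @export
field_raster <- function(field, patch, xlim = NULL, ylim = NULL,
                         pitch_mm = patch$resolution_mm, gl_nodes = 5) {
  xlim <- xlim %||% c(min(patch$x), max(patch$x))
  ylim <- ylim %||% patch$y_range
  x0 <- pitch_mm * floor(xlim[1] / pitch_mm + 1e-9)
  y0 <- pitch_mm * floor(ylim[1] / pitch_mm + 1e-9)
  nx <- as.integer(ceiling((xlim[2] - x0) / pitch_mm - 1e-9))
  ny <- as.integer(ceiling((ylim[2] - y0) / pitch_mm - 1e-9))
  gl <- pracma::gaussLegendre(gl_nodes, 0, 1)
  M <- matrix(0, ny, nx)
  chunk <- max(1L, as.integer(4e6 / ny))
  for (j0 in seq(1L, nx, by = chunk)) {
    j1 <- min(j0 + chunk - 1L, nx)
    xc <- x0 + (seq(j0, j1) - 0.5) * pitch_mm
    b <- patch_boundaries(patch, xc)
    t <- b$csf - b$wm
    ncells <- j1 - j0 + 1L
    csf_e <- rep(b$csf, each = ny)
    t_e <- rep(t, each = ny)
    x_e <- rep(xc, each = ny)
    ybase <- y0 + rep.int((seq_len(ny) - 1) * pitch_mm, ncells)
    acc <- numeric(ny * ncells)
    for (k in seq_len(gl_nodes)) {
      yk <- ybase + gl$x[k] * pitch_mm
      acc <- acc + gl$w[k] * field$fn((csf_e - yk) / t_e, x_e, t_e)
    }
    M[, j0:j1] <- acc
  }
  structure(list(x0 = x0, y0 = y0, pitch_mm = pitch_mm, nx = nx, ny = ny,
                 S = integral_image(M), peak_cell = max(abs(M))),
            class = "field_raster")
}

## Map grid edges to raster cell index ranges. Returns inclusive cell
## ranges per voxel row/col; errors if the grid pokes outside the raster.
grid_cell_ranges <- function(grid, raster) {
  p <- raster$pitch_mm
  jx <- round((grid$x_edges - raster$x0) / p)
  iy <- round((grid$y_edges - raster$y0) / p)
  if (min(jx) < 0 || max(jx) > raster$nx || min(iy) < 0 || max(iy) > raster$ny)
    stop("voxel grid extends beyond the field raster; rasterize a larger extent")
  list(jx = as.integer(jx), iy = as.integer(iy))
}

#' Measure an activation field with a voxel grid
#'
#' The noiseless signal of each voxel is the mean of the field over the
#' voxel footprint (boxcar sampling kernel), computed on the fine raster.
#' Measured signal adds independent Gaussian noise whose standard deviation
#' is the peak noiseless signal across the grid divided by `snr`; with
#' `snr = Inf` the measured signal equals the noiseless signal exactly and
#' no random numbers are consumed.
#'
#' @param field An `activation_field`.
#' @param patch The `cortex_patch` both field and grid live on.
#' @param grid A [place_grid()] result.
#' @param snr Signal-to-noise ratio (peak signal / noise SD); positive,
#'   possibly `Inf`.
#' @param seed Integer seed for the noise draw (required for finite `snr`).
#' @param raster Optional precomputed [field_raster()] covering the grid;
#'   built on the fly if missing.
#' @param fractions Logical; also attach per-voxel partial-volume
#'   fractions (GM, WM, CSF). Off by default in tight Monte-Carlo loops.
#' @return A `voxel_sample` data frame, one row per voxel: lattice indices,
#'   centroid position, centroid normalized depth (`NA` outside GM),
#'   centroid tissue class, noiseless and measured signals, and optionally
#'   `f_gm`, `f_wm`, `f_csf`. Grid, SNR and seed are kept as attributes.
#' @export
measure <- function(field, patch, grid, snr = Inf, seed = NULL,
                    raster = NULL, fractions = FALSE) {
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive (possibly Inf)")
  v <- grid$voxel_size_mm
  if (is.null(raster)) {
    raster <- field_raster(field, patch,
                           xlim = range(grid$x_edges), ylim = range(grid$y_edges))
  }
  cr <- grid_cell_ranges(grid, raster)
  n_row <- grid$n_row; n_col <- grid$n_col
  i0 <- rep.int(cr$iy[seq_len(n_row)] + 1L, n_col)
  i1 <- rep.int(cr$iy[seq_len(n_row) + 1L], n_col)
  j0 <- rep(cr$jx[seq_len(n_col)] + 1L, each = n_row)
  j1 <- rep(cr$jx[seq_len(n_col) + 1L], each = n_row)
  sums <- rect_sums(raster$S, i0, i1, j0, j1)
  noiseless <- sums / ((i1 - i0 + 1L) * (j1 - j0 + 1L))

  cx <- (grid$x_edges[-1] + grid$x_edges[-(n_col + 1L)]) / 2
  cy <- (grid$y_edges[-1] + grid$y_edges[-(n_row + 1L)]) / 2
  bx <- patch_boundaries(patch, pmin(pmax(cx, min(patch$x)), max(patch$x)))
  csf_e <- rep(bx$csf, each = n_row)
  wm_e <- rep(bx$wm, each = n_row)
  cy_e <- rep.int(cy, n_col)
  d <- (csf_e - cy_e) / (csf_e - wm_e)
  tissue <- factor(ifelse(cy_e > csf_e, "csf", ifelse(cy_e < wm_e, "wm", "gm")),
                   levels = c("csf", "gm", "wm"))
  d[tissue != "gm"] <- NA_real_

  if (is.finite(snr)) {
    if (is.null(seed)) stop("a seed is required for finite snr")
    set.seed(as.integer(seed))
    measured <- noiseless + rnorm(length(noiseless),
                                  sd = max(abs(noiseless)) / snr)
  } else {
    measured <- noiseless
  }

  out <- data.frame(
    col = rep(seq_len(n_col), each = n_row),
    row = rep.int(seq_len(n_row), n_col),
    cx_mm = rep(cx, each = n_row), cy_mm = cy_e,
    centroid_depth = d, tissue = tissue,
    signal_noiseless = noiseless, signal_measured = measured
  )
  if (fractions) {
    fr <- partial_volume_fractions(patch, grid)
    out$f_gm <- fr$f_gm; out$f_wm <- fr$f_wm; out$f_csf <- fr$f_csf
  }
  structure(out, grid = grid, snr = snr, seed = seed, class = c("voxel_sample", "data.frame"))
}

#' Per-voxel partial-volume tissue fractions
#'
#' Fractions of each voxel footprint occupied by grey matter, white matter
#' and CSF, computed by classifying fine-raster cells (at the patch raster
#' pitch) and counting them per voxel. Fractions sum to one per voxel.
#'
#' @param patch A `cortex_patch`.
#' @param grid A [place_grid()] result.
#' @return Data frame with `col`, `row`, `f_gm`, `f_wm`, `f_csf`.
#' @export
partial_volume_fractions <- function(patch, grid) {
  p <- patch$resolution_mm
  xlim <- range(grid$x_edges); ylim <- range(grid$y_edges)
  x0 <- p * floor(xlim[1] / p + 1e-9)
  y0 <- p * floor(ylim[1] / p + 1e-9)
  nx <- as.integer(ceiling((xlim[2] - x0) / p - 1e-9))
  ny <- as.integer(ceiling((ylim[2] - y0) / p - 1e-9))
  xc <- x0 + (seq_len(nx) - 0.5) * p
  yc <- y0 + (seq_len(ny) - 0.5) * p
  b <- patch_boundaries(patch, pmin(pmax(xc, min(patch$x)), max(patch$x)))
  CSF <- outer(yc, b$csf, `>`) * 1
  WM <- outer(yc, b$wm, `<`) * 1
  Sc <- integral_image(CSF); Sw <- integral_image(WM)
  fake_raster <- list(x0 = x0, y0 = y0, pitch_mm = p, nx = nx, ny = ny)
  cr <- grid_cell_ranges(grid, fake_raster)
  n_row <- grid$n_row; n_col <- grid$n_col
  i0 <- rep.int(cr$iy[seq_len(n_row)] + 1L, n_col)
  i1 <- rep.int(cr$iy[seq_len(n_row) + 1L], n_col)
  j0 <- rep(cr$jx[seq_len(n_col)] + 1L, each = n_row)
  j1 <- rep(cr$jx[seq_len(n_col) + 1L], each = n_row)
  ncell <- (i1 - i0 + 1L) * (j1 - j0 + 1L)
  f_csf <- rect_sums(Sc, i0, i1, j0, j1) / ncell
  f_wm <- rect_sums(Sw, i0, i1, j0, j1) / ncell
  data.frame(col = rep(seq_len(n_col), each = n_row),
             row = rep.int(seq_len(n_row), n_col),
             f_gm = 1 - f_csf - f_wm, f_wm = f_wm, f_csf = f_csf)
}

#' Write a voxel sample as a TSV sidecar
#'
#' One row per voxel with centroid coordinates, depth, tissue fractions (if
#' present) and signals.
#'
#' @param sample A `voxel_sample`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_voxel_sample_tsv <- function(sample, path) {
  write.table(as.data.frame(sample), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
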
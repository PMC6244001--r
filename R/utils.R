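# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats approx rnorm sd cor dgamma
#' @importFrom utils write.table read.table packageVersion
NULL

## Trapezoidal integral; thin wrapper so the dependency is used in one place.
trapz_int <- function(x, y) pracma::trapz(x, y)

## Smooth seeded 1-D random field on grid `x` with Gaussian correlation
## length `smoothness`. Generated on a coarse internal grid (smoothness/5
## pitch) and linearly interpolated, so cost is independent of length(x).
## Returned field is standardized (mean 0, sd 1).
smooth_random_field <- function(x, smoothness, seed) {
  stopifnot(smoothness > 0)
  pitch <- smoothness / 5
  pad <- 4 * smoothness
  xg <- seq(min(x) - pad, max(x) + pad, by = pitch)
  set.seed(as.integer(seed))
  z <- rnorm(length(xg))
  half <- ceiling(4 * smoothness / pitch)
  k <- stats::dnorm(seq(-half, half) * pitch, sd = smoothness)
  k <- k / sum(k)
  s <- stats::filter(c(rep(0, half), z, rep(0, half)), k, sides = 2)
  s <- as.numeric(s[(half + 1):(half + length(xg))])
  s <- (s - mean(s)) / sd(s)
  approx(xg, s, xout = x, rule = 2)$y
}

## Summed-area table with a zero-padded first row/column, so that the sum of
## M[i0:i1, j0:j1] is S[i1+1, j1+1] - S[i0, j1+1] - S[i1+1, j0] + S[i0, j0].
integral_image <- function(M) {
  ny <- nrow(M); nx <- ncol(M)
  S <- matrix(0, ny + 1L, nx + 1L)
  S[-1L, -1L] <- M
  for (i in 2:(ny + 1L)) S[i, ] <- S[i, ] + S[i - 1L, ]
  for (j in 2:(nx + 1L)) S[, j] <- S[, j] + S[, j - 1L]
  S
}

## Vectorized rectangle sums over an integral image. i0/i1, j0/j1 are
## inclusive cell index ranges (recycled against each other).
rect_sums <- function(S, i0, i1, j0, j1) {
  nS <- nrow(S)
  idx <- function(i, j) (j - 1L) * nS + i
  S[idx(i1 + 1L, j1 + 1L)] - S[idx(i0, j1 + 1L)] -
    S[idx(i1 + 1L, j0)] + S[idx(i0, j0)]
}

## Bilinear interpolation of Z (length(yg) x length(xg)) at the tensor grid
## yf (rows) x xf (cols). Queries outside the knot range are clamped to the
## border (no extrapolation).
bilinear_interp <- function(xg, yg, Z, xf, yf) {
  nx <- length(xg); ny <- length(yg)
  jx <- pmin(pmax(findInterval(xf, xg), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(yf, yg), 1L), ny - 1L)
  wx <- (xf - xg[jx]) / (xg[jx + 1L] - xg[jx])
  wy <- (yf - yg[iy]) / (yg[iy + 1L] - yg[iy])
  wx <- pmin(pmax(wx, 0), 1)
  wy <- pmin(pmax(wy, 0), 1)
  idx <- function(i, j) outer(i, (j - 1L) * ny, `+`)
  WY <- matrix(wy, length(yf), length(xf))
  WX <- matrix(wx, length(yf), length(xf), byrow = TRUE)
  Z[idx(iy, jx)] * (1 - WY) * (1 - WX) +
    Z[idx(iy + 1L, jx)] * WY * (1 - WX) +
    Z[idx(iy, jx + 1L)] * (1 - WY) * WX +
    Z[idx(iy + 1L, jx + 1L)] * WY * WX
}

## Derive a bounded child seed from a master seed and a stage label, keeping
## results below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
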
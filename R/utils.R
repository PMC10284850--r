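#' @useDynLib t1phase, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd cor fft coef
#' @importFrom utils write.csv modifyList
NULL

## Periodic-geometry helpers. All coordinates live on the torus [0, L)^2.

#' Wrap an angle to (-pi, pi]
#' @param x angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

## minimal-image displacement a - b on a torus of period L
torus_diff <- function(a, b, L) {
  d <- (a - b) %% L
  d - L * (d > L / 2)
}

#' Distance between points on the periodic domain
#'
#' @param a,b numeric vectors or 2-column matrices of coordinates.
#' @param L domain period.
#' @return Euclidean minimal-image distance(s).
#' @export
torus_dist <- function(a, b, L) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 2)
    b <- matrix(b, ncol = 2)
    sqrt(torus_diff(a[, 1], b[, 1], L)^2 + torus_diff(a[, 2], b[, 2], L)^2)
  } else {
    sqrt(sum(torus_diff(a, b, L)^2))
  }
}

## weighted periodic centroid via the circular mean of each coordinate
torus_centroid <- function(w, L) {
  n <- nrow(w)
  dx <- L / n
  xs <- (seq_len(n) - 1) * dx
  ang <- 2 * pi * xs / L
  wx <- rowSums(w)
  wy <- colSums(w)
  cx <- Arg(sum(wx * exp(1i * ang))) / (2 * pi) * L
  cy <- Arg(sum(wy * exp(1i * ang))) / (2 * pi) * L
  c(cx %% L, cy %% L)
}

## angular wavenumbers of the length-n DFT on period L, FFT ordering
fft_wavenumbers <- function(n, L) {
  2 * pi / L * c(0:(n %/% 2), -(n - n %/% 2 - 1):-1)[seq_len(n)]
}

## spectral partial derivatives of a periodic field (rows = x1, cols = x2)
spectral_gradient <- function(phi, L) {
  n <- nrow(phi)
  k <- fft_wavenumbers(n, L)
  F <- fft(phi)
  gx <- Re(fft(F * (1i * k), inverse = TRUE)) / n^2
  gy <- Re(fft(t(t(F) * (1i * k)), inverse = TRUE)) / n^2
  list(gx = gx, gy = gy)
}

## spectral Laplacian
spectral_laplacian <- function(phi, L) {
  n <- nrow(phi)
  k2 <- outer(fft_wavenumbers(n, L)^2, fft_wavenumbers(n, L)^2, `+`)
  Re(fft(fft(phi) * (-k2), inverse = TRUE)) / n^2
}

## periodic bilinear interpolation of field f (grid over [0,L)) at points
## given as a 2-column matrix
interp_periodic <- function(f, pts, L) {
  n <- nrow(f)
  dx <- L / n
  pts <- matrix(pts, ncol = 2)
  u <- (pts[, 1] %% L) / dx
  v <- (pts[, 2] %% L) / dx
  i0 <- floor(u)
  j0 <- floor(v)
  fu <- u - i0
  fv <- v - j0
  i0 <- i0 %% n
  j0 <- j0 %% n
  i1 <- (i0 + 1) %% n
  j1 <- (j0 + 1) %% n
  idx <- function(i, j) f[cbind(i + 1, j + 1)]
  idx(i0, j0) * (1 - fu) * (1 - fv) + idx(i1, j0) * fu * (1 - fv) +
    idx(i0, j1) * (1 - fu) * fv + idx(i1, j1) * fu * fv
}

## canonical string key of an unordered pair
pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

key_to_pair <- function(k) as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
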
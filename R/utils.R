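# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Centered 2-D FFT pair (DC at the array center, 1-based index n/2 + 1).
fftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq(d[1] %/% 2 + 1, d[1]), seq_len(d[1] %/% 2))
  j <- c(seq(d[2] %/% 2 + 1, d[2]), seq_len(d[2] %/% 2))
  x[i, j, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq(d[1] - d[1] %/% 2 + 1, d[1]), seq_len(d[1] - d[1] %/% 2))
  j <- c(seq(d[2] - d[2] %/% 2 + 1, d[2]), seq_len(d[2] - d[2] %/% 2))
  x[i, j, drop = FALSE]
}

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

# Degrees to radians.
deg2rad <- function(x) x * pi / 180

# Angle of (x, y) in degrees, counterclockwise, in [0, 360).
angle_deg <- function(x, y) (atan2(y, x) * 180 / pi) %% 360

# 2x2 in-plane block average over the first two dims, values replicated back
# to the original grid (piecewise-constant at the coarse resolution).
block_average_2x2 <- function(img) {
  d <- dim(img)
  ny <- d[1]; nx <- d[2]
  stopifnot(ny %% 2 == 0, nx %% 2 == 0)
  rest <- if (length(d) > 2) prod(d[-(1:2)]) else 1L
  a <- array(img, c(ny, nx, rest))
  out <- a
  for (k in seq_len(rest)) {
    m <- a[, , k]
    mb <- (m[seq(1, ny, 2), , drop = FALSE] + m[seq(2, ny, 2), , drop = FALSE]) / 2
    mb <- (mb[, seq(1, nx, 2), drop = FALSE] + mb[, seq(2, nx, 2), drop = FALSE]) / 2
    out[, , k] <- mb[rep(seq_len(ny / 2), each = 2), rep(seq_len(nx / 2), each = 2)]
  }
  array(out, d)
}

# Separable Gaussian smoothing of a 2-D matrix (replicate-free: renormalized
# at the edges), used for sensitivity-map regularization.
gauss_smooth2 <- function(m, fwhm) {
  if (fwhm <= 0) return(m)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    wts <- numeric(n)
    for (j in -r:r) {
      idx <- seq_len(n) + j
      ok <- idx >= 1 & idx <= n
      out[ok] <- out[ok] + k[j + r + 1] * v[idx[ok]]
      wts[ok] <- wts[ok] + k[j + r + 1]
    }
    out / wts
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}
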
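#' Model spiral k-space trajectory
#'
#' Single-shot Archimedean spiral reaching the Nyquist radius
#' `k_max = N / (2 FOV)` with `N/2` turns (unit radial Nyquist spacing).
#' Two radius-versus-time laws are available: `"arc"` (constant speed along
#' the trajectory arc, the gradient-amplitude-limited regime, radius
#' proportional to sqrt(t)) and `"linear"` (radius proportional to t).
#' Density-compensation weights are the analytic k-space area per sample,
#' scaled so that a fully sampled Cartesian acquisition would have unit
#' weight per grid cell divided by `N^2` (making density-compensated
#' conjugate-phase reconstruction approximately unit-gain).
#'
#' @param matrix_size nominal reconstruction matrix N.
#' @param fov_cm field of view (cm).
#' @param n_samples number of readout samples (default about 2.5x the
#'   Nyquist cell count, scaled with `fov_oversample`).
#' @param readout_ms readout duration (ms).
#' @param radius_law `"arc"` or `"linear"`.
#' @param fov_oversample alias-free-FOV margin: the turn spacing supports a
#'   field of view this factor larger than `fov_cm`, keeping the first
#'   radial alias ring outside the imaged region (standard spiral design
#'   margin).
#' @return Object of class `"hp_traj"`: list with `kx`, `ky` (cycles/cm),
#'   `t_ms` (time since excitation), `dcf`, `fov`, `matrix_size`.
#' @export
make_spiral_trajectory <- function(matrix_size, fov_cm,
                                   n_samples = NULL, readout_ms = 22,
                                   radius_law = c("arc", "linear"),
                                   fov_oversample = 1.25) {
  radius_law <- match.arg(radius_law)
  N <- matrix_size
  if (is.null(n_samples)) {
    n_samples <- ceiling(8 * N^2 / pi * fov_oversample)
  }
  kmax <- N / (2 * fov_cm)
  u <- (seq_len(n_samples) - 0.5) / n_samples
  if (radius_law == "arc") {
    k <- kmax * sqrt(u)
    area <- rep(pi * kmax^2 / n_samples, n_samples)
  } else {
    k <- kmax * u
    area <- 2 * pi * k * kmax / n_samples
    area <- area * pi * kmax^2 / sum(area)
  }
  theta <- 2 * pi * (N / 2) * fov_oversample * (k / kmax)
  structure(list(kx = k * cos(theta), ky = k * sin(theta),
                 t_ms = u * readout_ms,
                 dcf = area * fov_cm^2 / N^2,
                 fov = fov_cm, matrix_size = N),
            class = "hp_traj")
}

#' Sample k-space of an image on an arbitrary trajectory (forward DFT)
#'
#' Brute-force discrete Fourier transform of a Cartesian image at arbitrary
#' k-space locations: `s_i = sum_x img(x) exp(-2 pi i k_i . x)`, with voxel
#' coordinates centered on `(N/2 + 1)`. Used to synthesize k-space data from
#' digital phantoms and as the exact counterpart of gridding reconstruction
#' in round-trip checks.
#'
#' @param image complex or real matrix.
#' @param traj an [make_spiral_trajectory()] trajectory (or compatible list).
#' @return Complex vector of samples.
#' @export
dft_sample <- function(image, traj) {
  d <- dim(image)
  dx <- traj$fov / d[2]
  dy <- traj$fov / d[1]
  xc <- (seq_len(d[2]) - (d[2] %/% 2 + 1)) * dx
  yc <- (seq_len(d[1]) - (d[1] %/% 2 + 1)) * dy
  idx <- which(image != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(complex(length(traj$kx)))
  vals <- image[idx]
  ph <- outer(traj$kx, xc[idx[, 2]]) + outer(traj$ky, yc[idx[, 1]])
  as.vector(exp(-2i * pi * ph) %*% vals)
}

# Kaiser-Bessel kernel on |d| <= width/2, with the standard optimal beta
# for the given width and oversampling factor.
kb_beta <- function(width, osf) {
  pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
}

kb_kernel <- function(d, width, beta) {
  out <- numeric(length(d))
  inside <- abs(d) <= width / 2
  z <- sqrt(1 - (2 * d[inside] / width)^2)
  out[inside] <- besselI(beta * z, 0) / besselI(beta, 0)
  out
}

#' Gridding reconstruction with a Kaiser-Bessel kernel
#'
#' Density-compensated convolution gridding of non-Cartesian samples onto a
#' 1.4x oversampled Cartesian grid with a Kaiser-Bessel kernel of width 4.5,
#' inverse FFT, deapodization, and central crop to the requested size.
#' Deapodization divides by the transform of the *sampled* kernel placed at
#' the grid center, which makes a single DC sample reconstruct to an exactly
#' constant image and matches the scale of direct conjugate-phase DFT
#' reconstruction.
#'
#' @param samples complex vector (one channel) or matrix
#'   `n_samples x n_channels`.
#' @param traj trajectory as from [make_spiral_trajectory()]; `kx`/`ky` in
#'   cycles/cm with `|k| <= N / (2 FOV)`.
#' @param size output matrix size N.
#' @param osf oversampling factor.
#' @param width kernel width in (oversampled) grid cells.
#' @param dcf optional density-compensation override.
#' @return Complex matrix `size x size`, or array `size x size x n_channels`.
#' @export
grid_reconstruct <- function(samples, traj, size, osf = 1.4, width = 4.5,
                             dcf = NULL) {
  one <- is.null(dim(samples))
  smat <- if (one) matrix(samples, ncol = 1) else samples
  if (nrow(smat) != length(traj$kx)) {
    stop("trajectory and samples disagree in length", call. = FALSE)
  }
  if (nrow(smat) == 0) {
    warning("no k-space samples: returning a zero image")
    out <- array(0i, c(size, size, ncol(smat)))
    return(if (one) out[, , 1] else out)
  }
  if (is.null(dcf)) dcf <- traj$dcf
  G <- 2L * as.integer(ceiling(size * osf / 2))
  osf_eff <- G / size
  beta <- kb_beta(width, osf)
  cu <- G / 2 + 1
  u <- traj$kx * traj$fov * osf_eff + cu   # column coordinate
  v <- traj$ky * traj$fov * osf_eff + cu   # row coordinate
  hw <- ceiling(width / 2)
  offs <- seq(-hw + 1, hw)   # support of kb(j - u) for j integer, u in [0,1)
  nc <- ncol(smat)
  grids <- vector("list", nc)
  for (ch in seq_len(nc)) grids[[ch]] <- matrix(0i, G, G)
  wsamp <- dcf
  for (ou in offs) {
    ju <- floor(u) + ou
    kx_w <- kb_kernel(ju - u, width, beta)
    for (ov in offs) {
      jv <- floor(v) + ov
      kv_w <- kb_kernel(jv - v, width, beta)
      w <- kx_w * kv_w * wsamp
      ok <- w > 0 & ju >= 1 & ju <= G & jv >= 1 & jv <= G
      if (!any(ok)) next
      lin <- jv[ok] + (ju[ok] - 1L) * G
      for (ch in seq_len(nc)) {
        contrib <- w[ok] * smat[ok, ch]
        re <- rowsum(Re(contrib), lin)
        im <- rowsum(Im(contrib), lin)
        at <- as.integer(rownames(re))
        grids[[ch]][at] <- grids[[ch]][at] + complex(real = re, imaginary = im)
      }
    }
  }
  # deapodization: transform of the sampled kernel at the grid center
  kg <- matrix(0, G, G)
  k1d <- kb_kernel(offs, width, beta)
  kg[cu + offs, cu + offs] <- outer(k1d, k1d)
  crop <- (G / 2 + 1 - size %/% 2):(G / 2 + size - size %/% 2)
  deapod <- Re(fftshift2(ifft2(ifftshift2(kg))))[crop, crop]
  out <- array(0i, c(size, size, nc))
  for (ch in seq_len(nc)) {
    img <- fftshift2(ifft2(ifftshift2(grids[[ch]])))[crop, crop]
    out[, , ch] <- img / deapod
  }
  if (one) out[, , 1] else out
}

#' Estimate coil sensitivity maps from pyruvate channel images
#'
#' Sensitivities are estimated from the high-SNR pyruvate data: each
#' channel's AUC image is divided by the root-sum-of-squares across
#' channels, masked where the RSS falls below the noise floor, and smoothed
#' with a Gaussian low-pass (coil profiles are spatially smooth).
#'
#' @param channel_auc complex array `(ny, nx, n_channels)` or
#'   `(ny, nx, n_slices, n_channels)` of per-channel pyruvate AUC images.
#' @param smooth_fwhm Gaussian FWHM in voxels (0 disables smoothing).
#' @param noise_floor RSS magnitude below which the maps are set to zero.
#' @return Complex array of the same shape: per-channel sensitivity maps.
#' @export
estimate_sensitivities <- function(channel_auc, smooth_fwhm = 2,
                                   noise_floor = 0) {
  d <- dim(channel_auc)
  nc <- d[length(d)]
  a <- array(channel_auc, c(prod(d[-length(d)]), nc))
  rss <- sqrt(rowSums(abs(a)^2))
  if (all(rss == 0)) {
    stop("all-zero channel images: cannot normalize sensitivities",
         call. = FALSE)
  }
  maps <- a
  ok <- rss > noise_floor
  maps[ok, ] <- a[ok, ] / rss[ok]
  maps[!ok, ] <- 0i
  maps <- array(maps, d)
  if (smooth_fwhm > 0) {
    nplane <- if (length(d) == 3) nc else d[3] * nc
    m <- array(maps, c(d[1], d[2], nplane))
    for (p in seq_len(nplane)) {
      m[, , p] <- complex(real = gauss_smooth2(Re(m[, , p]), smooth_fwhm),
                          imaginary = gauss_smooth2(Im(m[, , p]), smooth_fwhm))
    }
    maps <- array(m, d)
  }
  # renormalize to unit RSS so that Roemer combination has spatially
  # uniform unit noise scaling (the combined image keeps the RSS-weighted
  # coil shading, which downstream ratio/coil-correction steps address)
  mm <- array(maps, c(prod(d[-length(d)]), nc))
  rssm <- sqrt(rowSums(abs(mm)^2))
  ok <- rssm > 0
  mm[ok, ] <- mm[ok, ] / rssm[ok]
  array(mm, d)
}

#' Roemer coil combination
#'
#' Sensitivity-weighted combination of multi-channel complex images:
#' `combined = sum_c conj(s_c) x_c / sum_c |s_c|^2`. Voxels where the
#' sensitivity RSS is zero are set to zero. With correct maps this is the
#' algebraic inverse of the coil modulation and is SNR-optimal for
#' uncorrelated channel noise.
#'
#' @param images complex array with channels as the last dimension.
#' @param maps sensitivity maps of identical shape.
#' @return Complex array with the channel dimension dropped.
#' @export
roemer_combine <- function(images, maps) {
  d <- dim(images)
  if (!all(d == dim(maps))) {
    stop("images and sensitivity maps must have identical shape",
         call. = FALSE)
  }
  nc <- d[length(d)]
  x <- array(images, c(prod(d[-length(d)]), nc))
  s <- array(maps, c(prod(d[-length(d)]), nc))
  num <- rowSums(Conj(s) * x)
  den <- rowSums(abs(s)^2)
  out <- ifelse(den > 0, num / den, 0i)
  if (length(d) > 2) array(out, d[-length(d)]) else out
}

#' Sinc upsampling by a factor of two with a Fermi window
#'
#' Zero-pads k-space to twice the in-plane matrix (splitting the Nyquist
#' row/column so that, with the window disabled, original voxel centers are
#' reproduced exactly) and applies a radial Fermi window to suppress
#' ringing. Operates plane-by-plane on arrays with trailing dimensions.
#'
#' @param img real or complex matrix (even dimensions) or array
#'   `(ny, nx, ...)`.
#' @param fermi apply the Fermi window?
#' @param radius,width Fermi cutoff radius and transition width as fractions
#'   of the padded Nyquist radius.
#' @return Upsampled array `(2 ny, 2 nx, ...)`; real input returns the real
#'   part.
#' @export
upsample2x <- function(img, fermi = TRUE, radius = 0.45, width = 0.05) {
  was_real <- is.numeric(img)
  d <- if (is.null(dim(img))) stop("need a matrix or array") else dim(img)
  ny <- d[1]; nx <- d[2]
  if (ny %% 2 || nx %% 2) stop("in-plane dimensions must be even")
  rest <- if (length(d) > 2) prod(d[-(1:2)]) else 1L
  a <- array(img, c(ny, nx, rest))
  out <- array(0i, c(2 * ny, 2 * nx, rest))
  rows <- (ny / 2 + 1):(3 * ny / 2)
  cols <- (nx / 2 + 1):(3 * nx / 2)
  if (fermi) {
    fr <- ((seq_len(2 * ny) - (ny + 1)) / ny)
    fc <- ((seq_len(2 * nx) - (nx + 1)) / nx)
    rho <- sqrt(outer(fr^2, fc^2, `+`))
    win <- 1 / (1 + exp((rho - radius) / width))
  }
  for (p in seq_len(rest)) {
    F <- fftshift2(fft2(a[, , p]))
    P <- matrix(0i, 2 * ny, 2 * nx)
    P[rows, cols] <- F
    # split the Nyquist row/column for exact interpolation
    P[3 * ny / 2 + 1, cols] <- P[ny / 2 + 1, cols] / 2
    P[ny / 2 + 1, cols] <- P[ny / 2 + 1, cols] / 2
    P[, 3 * nx / 2 + 1] <- P[, nx / 2 + 1] / 2
    P[, nx / 2 + 1] <- P[, nx / 2 + 1] / 2
    if (fermi) P <- P * win
    out[, , p] <- ifft2(ifftshift2(P)) * 4
  }
  out <- array(out, c(2 * ny, 2 * nx, if (length(d) > 2) d[-(1:2)] else NULL))
  if (was_real) Re(out) else out
}

#' Constant-phase correction of a dynamic complex series
#'
#' Each voxel's dynamic series is assumed to carry a single constant phase
#' offset. The maximizer of the real-channel energy
#' `sum_t Re(s_t exp(-i phi))^2` has the closed form
#' `phi = Arg(sum_t s_t^2) / 2`; the remaining pi-ambiguity is resolved
#' towards a nonnegative temporal sum of the real channel, but only where
#' that sum is decisive (|sum| beyond `flip_nsd` temporal standard
#' deviations): a sign flip driven by noise alone would rectify signal-free
#' voxels and destroy the zero-mean noise property that signed real-valued
#' analysis exists to preserve. Signal-bearing voxels (whose temporal sum
#' dwarfs its standard error) always come out positive; pure-noise voxels
#' keep the symmetric `phi` in `(-pi/2, pi/2]` and stay zero-mean.
#'
#' @param x complex vector (one series) or array whose last dimension is
#'   time.
#' @param flip_nsd decisiveness threshold (temporal standard deviations of
#'   the real channel) for the sign flip; 0 reproduces an unconditional
#'   nonnegative-sum convention.
#' @return List with `phase` (per-voxel phase in `(-pi, pi]`; 0 for an
#'   all-zero series) and `real` (rotated real-valued dynamics, same shape
#'   as `x`).
#' @export
phase_correct <- function(x, flip_nsd = 3) {
  vec <- is.null(dim(x))
  d <- if (vec) c(1L, length(x)) else dim(x)
  nt <- d[length(d)]
  m <- matrix(x, ncol = nt)
  s2 <- rowSums(m^2)
  phi <- ifelse(s2 == 0, 0, Arg(s2) / 2)   # in (-pi/2, pi/2]
  re <- Re(m * exp(-1i * phi))
  tsum <- rowSums(re)
  sdv <- if (nt > 1) {
    sqrt(pmax(0, (rowSums(re^2) - tsum^2 / nt) / (nt - 1)))
  } else {
    numeric(nrow(m))
  }
  flip <- tsum < -flip_nsd * sdv * sqrt(nt)
  phi[flip] <- phi[flip] + pi
  re[flip, ] <- -re[flip, ]
  phi <- ((phi + pi) %% (2 * pi)) - pi
  phi[phi == -pi] <- pi
  all_zero <- rowSums(abs(m)) == 0
  phi[all_zero] <- 0
  if (vec) {
    list(phase = phi[1], real = as.vector(re))
  } else {
    list(phase = array(phi, d[-length(d)]), real = array(re, d))
  }
}
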
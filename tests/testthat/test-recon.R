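# Direct conjugate-phase DFT reconstruction: the brute-force oracle for
# gridding, sharing only the trajectory definition.
conjugate_phase_dft <- function(samples, traj, size) {
  dx <- traj$fov / size
  xc <- (seq_len(size) - (size %/% 2 + 1)) * dx
  out <- matrix(0i, size, size)
  for (r in seq_len(size)) {
    ph <- exp(2i * pi * (outer(traj$ky * xc[r], rep(1, size)) +
                           outer(traj$kx, xc)))
    out[r, ] <- colSums(traj$dcf * samples * ph)
  }
  out
}

test_that("a single DC sample reconstructs to a uniform image", {
  traj <- list(kx = 0, ky = 0, fov = 10, dcf = 1)
  img <- grid_reconstruct(1 + 0i, traj, 16)
  expect_lt(max(abs(img - mean(img))) / abs(mean(img)), 1e-6)
})

test_that("gridding is linear to machine precision", {
  traj <- make_spiral_trajectory(16, 10)
  set.seed(2)
  a <- complex(real = rnorm(length(traj$kx)), imaginary = rnorm(length(traj$kx)))
  b <- complex(real = rnorm(length(traj$kx)), imaginary = rnorm(length(traj$kx)))
  r1 <- grid_reconstruct(2 * a - 3i * b, traj, 16)
  r2 <- 2 * grid_reconstruct(a, traj, 16) - 3i * grid_reconstruct(b, traj, 16)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("gridding matches direct conjugate-phase DFT within 2% RMS on 16x16 spirals", {
  traj <- make_spiral_trajectory(16, 10)
  img0 <- blob_image(16, seed = 3)
  samp <- dft_sample(img0, traj)
  rec <- grid_reconstruct(samp, traj, 16)
  direct <- conjugate_phase_dft(samp, traj, 16)
  expect_lt(sqrt(mean(abs(rec - direct)^2)) / sqrt(mean(abs(direct)^2)), 0.02)
})

test_that("a known phantom survives the forward-DFT / gridding round trip", {
  n <- 32
  traj <- make_spiral_trajectory(n, 12)
  img0 <- blob_image(n, seed = 8)
  rec <- grid_reconstruct(dft_sample(img0, traj), traj, n)
  nrmse <- sqrt(mean(abs(rec - img0)^2)) / sqrt(mean(img0^2))
  expect_lt(nrmse, 0.05)
  # empty input warns and returns zeros
  expect_warning(z <- grid_reconstruct(complex(0), list(kx = numeric(0),
                                                        ky = numeric(0),
                                                        fov = 10,
                                                        dcf = numeric(0)), 8),
                 "no k-space")
  expect_true(all(z == 0))
})

test_that("sensitivity estimation handles the degenerate and symmetric cases", {
  img <- blob_image(16) + 0.2
  one <- estimate_sensitivities(array(img + 0i, c(16, 16, 1)), smooth_fwhm = 0)
  expect_equal(Re(one[, , 1]), matrix(1, 16, 16), tolerance = 1e-12)
  two <- estimate_sensitivities(array(rep(img, 2) + 0i, c(16, 16, 2)),
                                smooth_fwhm = 0)
  expect_equal(Mod(two[, , 1]), matrix(1 / sqrt(2), 16, 16), tolerance = 1e-12)
  expect_error(estimate_sensitivities(array(0i, c(4, 4, 2))), "all-zero")
})

test_that("estimated sensitivities correlate with the simulated coil profiles", {
  # phase offsets disabled: the estimates absorb the voxel phase field into
  # the maps (harmless for combination, but it confounds the magnitude
  # comparison against the generating profiles)
  st <- small_study(noise = TRUE, seed = 6, phase_offsets = FALSE)
  d <- dim(st$images$pyruvate)
  pyr_auc <- array(0i, c(d[1:3], d[5]))
  for (ch in seq_len(d[5])) {
    pyr_auc[, , , ch] <- apply(st$images$pyruvate[, , , , ch, drop = FALSE],
                               1:3, sum)
  }
  # unsmoothed: on a phantom this small the low-pass mixes body-edge voxels
  # with noise-dominated background, which is smoothing behavior rather
  # than the estimator's fidelity
  est <- estimate_sensitivities(pyr_auc, smooth_fwhm = 0)
  truth <- st$truth$sensitivities
  body <- st$truth$labels > 0
  for (ch in seq_len(dim(truth)[4])) {
    # compare normalized magnitudes inside the signal-bearing region
    tr <- Mod(truth[, , , ch]) /
      sqrt(apply(Mod(truth)^2, 1:3, sum))
    expect_gt(cor(Mod(est[, , , ch])[body], tr[body]), 0.95)
  }
})

test_that("Roemer combination inverts known maps and is the identity for one channel", {
  img <- blob_image(16)
  one <- roemer_combine(array(img + 0i, c(16, 16, 1)),
                        array(1 + 0i, c(16, 16, 1)))
  expect_equal(one, img + 0i, tolerance = 1e-12)
  set.seed(3)
  maps <- array(complex(real = rnorm(16 * 16 * 4, 1),
                        imaginary = rnorm(16 * 16 * 4, 0, 0.3)),
                c(16, 16, 4))
  chans <- array(0i, c(16, 16, 4))
  for (ch in 1:4) chans[, , ch] <- img * maps[, , ch]
  expect_equal(roemer_combine(chans, maps), img + 0i, tolerance = 1e-10)
})

test_that("Roemer combined noise variance follows sigma^2 / (n |s|^2)", {
  set.seed(9)
  nvox <- 40000; nc <- 4; smag <- 0.7; sigma <- 1.3
  maps <- array(smag * exp(2i * pi * runif(nvox * nc)), c(200, 200, nc))
  noise <- array(complex(real = rnorm(nvox * nc, sd = sigma),
                         imaginary = rnorm(nvox * nc, sd = sigma)),
                 c(200, 200, nc))
  comb <- roemer_combine(noise, maps)
  expect_equal(var(as.vector(Re(comb))), sigma^2 / (nc * smag^2),
               tolerance = 0.05)
  expect_lt(abs(mean(Re(comb))), 3 * sd(Re(comb)) / sqrt(nvox))
})

test_that("upsample2x preserves constants, symmetry, and original samples", {
  const <- matrix(5.5, 16, 16)
  up <- upsample2x(const, fermi = FALSE)
  expect_equal(up, matrix(5.5, 32, 32), tolerance = 1e-12)
  # impulse -> symmetric windowed-sinc kernel about the source voxel
  imp <- matrix(0, 16, 16); imp[9, 9] <- 1
  upw <- upsample2x(imp)
  expect_equal(dim(upw), c(32L, 32L))
  for (dlt in 1:6) {
    expect_equal(upw[17 + dlt, 17], upw[17 - dlt, 17], tolerance = 1e-10)
    expect_equal(upw[17, 17 + dlt], upw[17, 17 - dlt], tolerance = 1e-10)
  }
  # with the window disabled, original voxel centers are reproduced exactly
  set.seed(4)
  img <- matrix(rnorm(16 * 16), 16, 16)
  up2 <- upsample2x(img, fermi = FALSE)
  expect_lt(max(abs(up2[seq(1, 31, 2), seq(1, 31, 2)] - img)), 1e-9)
})

test_that("closed-form phasing inverts a constant offset and never loses to a grid search", {
  set.seed(12)
  r <- abs(rnorm(20))
  phi0 <- 1.23
  out <- phase_correct(r * exp(1i * phi0))
  expect_equal(out$phase, phi0, tolerance = 1e-12)
  expect_equal(out$real, r, tolerance = 1e-12)
  expect_equal(phase_correct(complex(10))$phase, 0)

  n_series <- 1000
  s <- matrix(complex(real = rnorm(n_series * 10),
                      imaginary = rnorm(n_series * 10)), n_series, 10)
  out <- phase_correct(array(s, c(n_series, 1, 10)))
  e_opt <- rowSums(out$real[, 1, ]^2)
  # energy at every angle of a 3600-point grid via the quadratic form
  a <- rowSums(Re(s)^2); b <- rowSums(Im(s)^2); cc <- rowSums(Re(s) * Im(s))
  phi <- seq(0, pi, length.out = 3600)
  e_grid <- outer(a, cos(phi)^2) + outer(b, sin(phi)^2) +
    2 * outer(cc, sin(phi) * cos(phi))
  expect_true(all(e_opt >= apply(e_grid, 1, max) - 1e-9))
})

test_that("phasing of pure noise keeps the real channel zero-mean", {
  set.seed(30)
  nt <- 30; nvox <- 2000
  s <- array(complex(real = rnorm(nvox * nt), imaginary = rnorm(nvox * nt)),
             c(nvox, 1, nt))
  out <- phase_correct(s)
  m <- mean(out$real)
  se <- sd(out$real) / sqrt(length(out$real))
  expect_lt(abs(m), 3 * se)
})

test_that("the phantom is recovered end-to-end through DFT sampling, gridding, combination and phasing", {
  geom <- build_geometry(ny = 32, nx = 32, n_slices = 1, lv_radius = 5,
                         wall_thickness = 3, rv_radius = 3,
                         slice_levels = "mid")
  proto <- acquisition_protocol(n_frames = 30, n_slices = 1)
  st <- render_dynamic_study(geom, coils = coil_array(n_channels = 2),
                             protocol = proto, noise = FALSE, seed = 2)
  traj <- make_spiral_trajectory(32, 32 * 0.3)
  # the acquisition samples the k-space disk |k| <= kmax, so the sharp-edged
  # label phantom is compared at the resolution the readout can represent:
  # the reference is the disk-bandlimited phantom through the same
  # combination and phasing chain
  disk_filter <- function(plane) {
    n <- nrow(plane)
    F <- fft(plane)
    F <- F[c((n / 2 + 1):n, 1:(n / 2)), c((n / 2 + 1):n, 1:(n / 2))]
    fr <- (1:n) - (n / 2 + 1)
    F[sqrt(outer(fr^2, fr^2, `+`)) > n / 2] <- 0
    F <- F[c((n / 2 + 1):n, 1:(n / 2)), c((n / 2 + 1):n, 1:(n / 2))]
    fft(F, inverse = TRUE) / n^2
  }
  d <- dim(st$images$pyruvate)
  rec <- ref <- list()
  for (m in names(st$images)) {
    arr <- array(0i, d)
    flt <- array(0i, d)
    for (f in seq_len(d[4])) {
      for (ch in seq_len(d[5])) {
        plane <- st$images[[m]][, , 1, f, ch]
        arr[, , 1, f, ch] <- grid_reconstruct(dft_sample(plane, traj),
                                              traj, 32)
        flt[, , 1, f, ch] <- disk_filter(plane)
      }
    }
    rec[[m]] <- arr
    ref[[m]] <- flt
  }
  rec_st <- st; rec_st$images <- rec
  ref_st <- st; ref_st$images <- ref
  out <- combine_study(rec_st)
  want <- combine_study(ref_st)
  for (m in names(out$images)) {
    denom <- sqrt(mean(want$images[[m]]^2))
    nrmse <- sqrt(mean((out$images[[m]] - want$images[[m]])^2)) / denom
    expect_lt(nrmse, 0.05)
  }
})
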
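# Desk-scale phantom fixtures shared across test files. All fixtures are
# generated in code; nothing is read from disk.

small_geometry <- function(ny = 32, nx = 32) {
  build_geometry(ny = ny, nx = nx, n_slices = 3,
                 lv_radius = 5, wall_thickness = 3, rv_radius = 3,
                 slice_levels = c("basal", "mid", "apical"))
}

small_protocol <- function(n_frames = 30, seed = 1L) {
  acquisition_protocol(n_frames = n_frames, n_slices = 3, seed = seed)
}

small_coils <- function(n_channels = 4, sigma = 0.001) {
  coil_array(n_channels = n_channels, sigma = sigma)
}

small_study <- function(state = "fasted", noise = TRUE, seed = 3L,
                        kinetics = tissue_kinetics(), ...) {
  render_dynamic_study(small_geometry(), kinetics = kinetics,
                       coils = small_coils(), protocol = small_protocol(),
                       state = state, noise = noise, seed = seed, ...)
}

# 2x2-in-plane block dilation of a logical mask: TRUE wherever the mask
# touches the voxel's 2x2 block (the lactate/bicarbonate rendering cell).
block_dilate <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (s in seq_len(d[3])) {
    m <- mask[, , s]
    ri <- rep(seq(1, d[1], 2), each = 2)
    ci <- rep(seq(1, d[2], 2), each = 2)
    blk <- (m[seq(1, d[1], 2), seq(1, d[2], 2)] |
              m[seq(2, d[1], 2), seq(1, d[2], 2)] |
              m[seq(1, d[1], 2), seq(2, d[2], 2)] |
              m[seq(2, d[1], 2), seq(2, d[2], 2)])
    out[, , s] <- blk[rep(seq_len(d[1] / 2), each = 2),
                      rep(seq_len(d[2] / 2), each = 2)]
  }
  out
}

# Smooth test image: a few Gaussian blobs on an N x N grid, compactly
# supported away from the FOV edge (as a heart within the torso FOV is).
blob_image <- function(n, seed = 1) {
  set.seed(seed)
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  img <- matrix(0, n, n)
  for (b in 1:3) {
    cy <- runif(1, 3 * n / 8, 5 * n / 8)
    cx <- runif(1, 3 * n / 8, 5 * n / 8)
    w <- runif(1, n / 14, n / 9)
    img <- img + runif(1, 0.5, 1) * exp(-((r - cy)^2 + (c - cx)^2) / (2 * w^2))
  }
  img
}

deg2rad_test <- function(x) x * pi / 180
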
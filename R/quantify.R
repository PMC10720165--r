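#' Metabolite-specific AUC frame windows
#'
#' Only frames with observable signal are summed, so that the AUC does not
#' accumulate extra noise: pyruvate uses the first 25 time-points, lactate
#' all 30, bicarbonate the 5th to 20th. Frame ranges are 1-based and
#' inclusive, as in the configuration convention "5th to 20th time-points".
#'
#' @param pyruvate,lactate,bicarbonate integer frame ranges `c(first, last)`.
#' @return Named list of class `"hp_auc_window"`.
#' @export
auc_window <- function(pyruvate = c(1, 25), lactate = c(1, 30),
                       bicarbonate = c(5, 20)) {
  w <- list(pyruvate = pyruvate, lactate = lactate, bicarbonate = bicarbonate)
  for (m in names(w)) {
    if (w[[m]][1] < 1 || w[[m]][2] < w[[m]][1]) {
      stop("invalid frame range for ", m, call. = FALSE)
    }
  }
  structure(w, class = "hp_auc_window")
}

#' Area-under-curve maps from phased real dynamics
#'
#' Plain per-voxel sum of the real-valued signal over the metabolite's
#' frame window (no frame-interval weighting: the SNR normalization by
#' sqrt(n) assumes an unweighted sum).
#'
#' @param images named list of real arrays `(ny, nx, n_slices, n_frames)`
#'   (metabolite names), or a single array (then `metabolite` selects the
#'   window).
#' @param window an [auc_window()].
#' @param metabolite window name when `images` is a single array.
#' @return Named list of AUC arrays `(ny, nx, n_slices)` (or one array).
#' @export
auc_maps <- function(images, window = auc_window(), metabolite = NULL) {
  one_map <- function(arr, rng) {
    nt <- dim(arr)[4]
    if (rng[2] > nt) {
      stop("AUC window [", rng[1], ", ", rng[2],
           "] exceeds the ", nt, " available frames", call. = FALSE)
    }
    apply(arr[, , , rng[1]:rng[2], drop = FALSE], 1:3, sum)
  }
  if (is.list(images)) {
    out <- lapply(names(images), function(m) one_map(images[[m]], window[[m]]))
    names(out) <- names(images)
    out
  } else {
    if (is.null(metabolite)) stop("metabolite needed for a single array")
    one_map(images, window[[metabolite]])
  }
}

#' Estimate the noise level from a signal-free time-point
#'
#' The standard deviation of the real component of a single frame acquired
#' after the hyperpolarized signal has completely decayed, over a
#' background region (by default everything outside the body mask). The
#' mean is subtracted (it is a standard deviation), so a constant offset
#' does not bias the estimate.
#'
#' @param images real dynamic array `(ny, nx, n_slices, n_frames)`.
#' @param frame frame index or `"last"`.
#' @param background logical array `(ny, nx, n_slices)` of noise-only
#'   voxels; default all voxels.
#' @return Object of class `"hp_noise"`: `sigma`, `frame`, `n_voxels`.
#' @export
estimate_noise <- function(images, frame = "last", background = NULL) {
  nt <- dim(images)[4]
  if (identical(frame, "last")) frame <- nt
  if (frame < 1 || frame > nt) stop("noise frame out of range", call. = FALSE)
  plane <- images[, , , frame]
  if (!is.null(background)) plane <- plane[background]
  sigma <- sd(as.vector(plane))
  if (sigma == 0) {
    warning("noise frame is constant: sigma = 0 will break SNR computation")
  }
  structure(list(sigma = sigma, frame = frame, n_voxels = length(plane)),
            class = "hp_noise")
}

#' AUC-SNR map
#'
#' `SNR = |AUC| / (sigma * sqrt(n_frames))`: the AUC magnitude divided by
#' the noise level scaled for the noise averaging of the `n_frames`-point
#' sum.
#'
#' @param auc AUC array.
#' @param noise an [estimate_noise()] result (or a positive number).
#' @param n_frames number of frames summed in the AUC window.
#' @return SNR array (dimensionless).
#' @export
auc_snr_map <- function(auc, noise, n_frames) {
  sigma <- if (inherits(noise, "hp_noise")) noise$sigma else noise
  if (!is.finite(sigma) || sigma <= 0) {
    stop("noise sigma must be positive for SNR computation", call. = FALSE)
  }
  abs(auc) / (sigma * sqrt(n_frames))
}

#' Pyruvate AUC-SNR mask
#'
#' Quantification (ratios, kinetic rates) is restricted to voxels with
#' sufficient pyruvate signal. The default threshold of 200 is a per-study
#' configurable value ("approximately 200, adjusted for each subject").
#'
#' @param snr pyruvate AUC-SNR array.
#' @param threshold minimum pyruvate AUC-SNR.
#' @return Logical array.
#' @export
pyruvate_mask <- function(snr, threshold = 200) snr >= threshold

#' Signed metabolite AUC ratio maps
#'
#' Voxelwise lactate/pyruvate, bicarbonate/pyruvate and bicarbonate/lactate
#' ratios of the signed real-valued AUC maps, computed only inside the
#' pyruvate SNR mask (`NA` outside). Signs are preserved: no magnitude
#' rectification, avoiding the low-SNR bias of magnitude images.
#'
#' @param auc_l,auc_b,auc_p lactate, bicarbonate and pyruvate AUC arrays.
#' @param mask logical array from [pyruvate_mask()].
#' @return List of arrays `lactate_pyruvate`, `bicarbonate_pyruvate`,
#'   `bicarbonate_lactate`.
#' @export
ratio_maps <- function(auc_l, auc_b, auc_p, mask) {
  blank <- array(NA_real_, dim(auc_p))
  lp <- bp <- bl <- blank
  lp[mask] <- auc_l[mask] / auc_p[mask]
  bp[mask] <- auc_b[mask] / auc_p[mask]
  bl[mask] <- auc_b[mask] / auc_l[mask]
  list(lactate_pyruvate = lp, bicarbonate_pyruvate = bp,
       bicarbonate_lactate = bl)
}

#' Coil-profile correction
#'
#' Divides an image by a measured receive sensitivity magnitude field
#' inside the mask; masked (NA) elsewhere. The field must be strictly
#' positive where the correction is applied.
#'
#' @param image numeric array.
#' @param field sensitivity magnitude field, same shape.
#' @param mask logical array; default everywhere.
#' @return Corrected array, `NA` outside the mask.
#' @export
coil_correct <- function(image, field, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  if (any(field[mask] <= 0)) {
    stop("sensitivity field must be strictly positive inside the mask",
         call. = FALSE)
  }
  out <- array(NA_real_, dim(image))
  out[mask] <- image[mask] / field[mask]
  out
}
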
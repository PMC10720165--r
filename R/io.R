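#' Write a synthetic study to disk
#'
#' One NIfTI volume per metabolite per channel with the dynamic frames as
#' the 4th dimension; complex data are stored as paired `_real` / `_imag`
#' volumes. A JSON sidecar records the acquisition protocol, state, seed,
#' noise sigma and ground-truth region rates; the label map is written as
#' an integer NIfTI.
#'
#' @param study an [render_dynamic_study()] study.
#' @param dir output directory (created if needed).
#' @param vox_mm voxel dimensions for the NIfTI headers.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, vox_mm = c(3, 3, 21)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(study$images$pyruvate)
  nc <- d[5]
  for (m in names(study$images)) {
    for (ch in seq_len(nc)) {
      arr <- array(study$images[[m]][, , , , ch], d[1:4])
      base <- file.path(dir, sprintf("%s_ch%02d", m, ch))
      RNifti::writeNifti(RNifti::asNifti(Re(arr), pixdim = vox_mm),
                         paste0(base, "_real.nii"))
      RNifti::writeNifti(RNifti::asNifti(Im(arr), pixdim = vox_mm),
                         paste0(base, "_imag.nii"))
    }
  }
  RNifti::writeNifti(
    RNifti::asNifti(study$truth$labels + 0L, pixdim = vox_mm),
    file.path(dir, "labels.nii"))
  sidecar <- list(
    protocol = unclass(study$protocol), state = study$state,
    seed = study$seed, sigma = study$truth$sigma,
    n_channels = nc,
    truth = list(k_pl_myocardium = unique(study$truth$k_pl[study$truth$labels >= 3]),
                 k_pb_myocardium = unique(study$truth$k_pb[study$truth$labels >= 3])))
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir study directory.
#' @return List with `images` (complex arrays `(ny, nx, ns, nt, nc)`),
#'   `labels`, and the JSON `sidecar`.
#' @export
read_study <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "study.json"),
                                 simplifyVector = TRUE)
  nc <- sidecar$n_channels
  images <- list()
  for (m in c("pyruvate", "lactate", "bicarbonate")) {
    chans <- lapply(seq_len(nc), function(ch) {
      base <- file.path(dir, sprintf("%s_ch%02d", m, ch))
      re <- as.array(RNifti::readNifti(paste0(base, "_real.nii")))
      im <- as.array(RNifti::readNifti(paste0(base, "_imag.nii")))
      complex(real = re, imaginary = im)
    })
    d4 <- dim(as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_ch01_real.nii", m)))))
    images[[m]] <- array(unlist(chans), c(d4, nc))
  }
  labels <- as.array(RNifti::readNifti(file.path(dir, "labels.nii")))
  list(images = images, labels = labels, sidecar = sidecar)
}

#' Write a parameter map as NIfTI
#'
#' @param map numeric array (e.g. a kPL map in s^-1); `NA` sentinels are
#'   preserved as NaN.
#' @param file output path (`.nii`).
#' @param vox_mm voxel dimensions.
#' @export
write_map <- function(map, file, vox_mm = c(3, 3, 21)) {
  RNifti::writeNifti(RNifti::asNifti(map, pixdim = vox_mm[seq_len(min(3, length(dim(map))))]),
                     file)
  invisible(file)
}

#' Write the cohort manifest as CSV
#'
#' @param cohort an [generate_paired_cohort()] cohort.
#' @param file output path.
#' @export
write_cohort_manifest <- function(cohort, file) {
  write.csv(cohort$manifest, file, row.names = FALSE)
  invisible(file)
}

#' Write per-segment summary tables as CSV
#'
#' @param tables named list of [segment_means()] data frames (one per
#'   metric); the metric name is added as a column.
#' @param file output path.
#' @export
write_segment_table <- function(tables, file) {
  rows <- lapply(names(tables), function(m) cbind(metric = m, tables[[m]]))
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
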
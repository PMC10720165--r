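#' Build the synthetic cardiac phantom geometry
#'
#' Constructs a short-axis label map standing in for a manual CINE-based
#' segmentation: LV blood pool, a closed myocardial annulus divided into AHA
#' 16 segments, and an RV blood pool exterior to the ring. Labels partition
#' the grid: 0 background, 1 RV blood, 2 LV blood, 3-18 myocardium (AHA
#' segment = label - 2). Radii taper towards the apex.
#'
#' @param ny,nx in-plane matrix size (default 64 x 64).
#' @param n_slices number of short-axis slices (default 5).
#' @param vox_mm voxel size in mm `(dy, dx, dz)`; default `c(3, 3, 21)`
#'   (simulation scale).
#' @param lv_center LV center `(row, col)`, recycled per slice; default the
#'   grid center.
#' @param lv_radius LV blood-pool radius in voxels on basal slices.
#' @param wall_thickness myocardial wall thickness in voxels.
#' @param rv_radius RV blood-pool radius in voxels.
#' @param rv_angle RV-insertion reference angle in degrees (counterclockwise,
#'   0 = image "east").
#' @param slice_levels slice level per slice (`"basal"`, `"mid"`, `"apical"`).
#' @param taper multiplicative radius scaling per level.
#' @return An object of class `"hp_geometry"`: list with `labels` (integer
#'   array `(ny, nx, n_slices)`), `dims`, `vox_mm`, `lv_center`, `rv_angle`,
#'   `slice_levels`, and `segments` (the [assign_aha16()] label array over
#'   the myocardium).
#' @examples
#' geom <- build_geometry()
#' table(geom$labels)
#' @export
build_geometry <- function(ny = 64, nx = 64, n_slices = 5,
                           vox_mm = c(3, 3, 21),
                           lv_center = NULL,
                           lv_radius = 8, wall_thickness = 4,
                           rv_radius = 6, rv_angle = 120,
                           slice_levels = c("basal", "basal", "mid", "mid", "apical"),
                           taper = c(basal = 1, mid = 0.85, apical = 0.65)) {
  if (length(slice_levels) != n_slices) {
    stop("need one slice level per slice", call. = FALSE)
  }
  slice_levels <- match.arg(slice_levels, c("basal", "mid", "apical"),
                            several.ok = TRUE)
  if (is.null(lv_center)) lv_center <- c((ny + 1) / 2, (nx + 1) / 2)
  if (is.vector(lv_center) && length(lv_center) == 2) {
    lv_center <- matrix(lv_center, n_slices, 2, byrow = TRUE)
  }
  outer_r <- (lv_radius + wall_thickness) * max(taper[slice_levels])
  margin <- min(lv_center[, 1] - 1, ny - lv_center[, 1],
                lv_center[, 2] - 1, nx - lv_center[, 2])
  if (outer_r + 2 * rv_radius + 1 > margin) {
    stop("annulus and RV pool exceed the grid; enlarge the grid or shrink radii",
         call. = FALSE)
  }

  labels <- array(0L, c(ny, nx, n_slices))
  myo <- array(FALSE, c(ny, nx, n_slices))
  row <- matrix(seq_len(ny), ny, nx)
  col <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (s in seq_len(n_slices)) {
    sc <- taper[slice_levels[s]]
    r1 <- lv_radius * sc
    r2 <- (lv_radius + wall_thickness) * sc
    x <- col - lv_center[s, 2]
    y <- lv_center[s, 1] - row
    rr <- sqrt(x^2 + y^2)
    sl <- matrix(0L, ny, nx)
    sl[rr <= r1] <- 2L
    ring <- rr > r1 & rr <= r2
    myo[, , s] <- ring
    # RV blood pool: disk tangent to the ring, centered near the insertion
    rv_dir <- deg2rad(rv_angle - 30)
    cx <- (r2 + 0.9 * rv_radius * sc) * cos(rv_dir)
    cy <- (r2 + 0.9 * rv_radius * sc) * sin(rv_dir)
    rv <- sqrt((x - cx)^2 + (y - cy)^2) <= rv_radius * sc & !ring & sl == 0L
    sl[rv] <- 1L
    labels[, , s] <- sl
  }
  segments <- assign_aha16(myo, lv_center, rv_angle, slice_levels)
  labels[myo] <- segments[myo] + 2L
  structure(
    list(labels = labels, segments = segments,
         dims = c(ny = ny, nx = nx, n_slices = n_slices),
         vox_mm = vox_mm, lv_center = lv_center, rv_angle = rv_angle,
         slice_levels = slice_levels),
    class = "hp_geometry"
  )
}

#' @export
print.hp_geometry <- function(x, ...) {
  cat("Cardiac phantom geometry:",
      paste(x$dims, collapse = " x "), "voxels,",
      paste(x$vox_mm, collapse = " x "), "mm\n")
  cat("  slice levels:", paste(x$slice_levels, collapse = ", "), "\n")
  cat("  myocardial voxels:", sum(x$labels >= 3L),
      "| LV blood:", sum(x$labels == 2L),
      "| RV blood:", sum(x$labels == 1L), "\n")
  invisible(x)
}

# Logical myocardial mask of a geometry.
myocardium_mask <- function(geometry) geometry$labels >= 3L
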
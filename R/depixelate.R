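#' One-time interpolation calibration for de-pixelated reconstruction
#'
#' Builds the Delaunay triangulation over the detected core positions and
#' precomputes, for every pixel of the square reconstruction grid, the
#' enclosing triangle and its barycentric coordinates. Also records each
#' core's intensity in the blank calibration image, used for background
#' subtraction and flat-fielding. After this calibration, reconstructing a
#' frame is a single sparse weighted sum (no triangulation at frame time).
#'
#' The grid spans the bounding square of the bundle (side twice the maximal
#' core distance from the bundle centre).
#'
#' @param core_positions n x 2 matrix of core centres (`x`, `y`, 0-based
#'   camera pixels), e.g. from [find_cores()].
#' @param blank blank calibration frame (matrix, no sample in view).
#' @param grid_size reconstruction grid side in pixels (>= 16; default 512).
#' @param cam_pitch physical size of one camera pixel at the bundle plane,
#'   micrometres (default 3.7/6).
#' @return object of class `interp_calibration`.
#' @export
calibrate_single <- function(core_positions, blank, grid_size = 512,
                             cam_pitch = 3.7 / 6) {
  core_positions <- as.matrix(core_positions)
  if (ncol(core_positions) != 2L) stop("'core_positions' must be n x 2")
  if (nrow(core_positions) < 3L) stop("need at least 3 cores")
  if (grid_size < 16) stop("'grid_size' must be at least 16")
  grid_size <- as.integer(grid_size)

  geom <- grid_geometry(core_positions, grid_size)
  tri <- triangulate_points(core_positions)
  tables <- grid_bary_tables(core_positions, tri,
                             geom$x0, geom$dx, grid_size,
                             geom$y0, geom$dx, grid_size)
  b <- extract_core_values(blank, core_positions)
  check_background(b)

  structure(list(core_positions = core_positions, background = b,
                 grid_size = grid_size,
                 pixel_pitch = geom$dx * cam_pitch, cam_pitch = cam_pitch,
                 x0 = geom$x0, y0 = geom$y0, dx = geom$dx,
                 center_grid = geom$center_grid, radius_grid = geom$radius_grid,
                 tri = tri, tables = tables, version = 1L),
            class = "interp_calibration")
}

# grid frame spanning the bundle bounding square, shared by single and
# enhanced calibrations so their reconstructions align pixel-for-pixel
grid_geometry <- function(core_positions, grid_size) {
  cx <- (min(core_positions[, 1]) + max(core_positions[, 1])) / 2
  cy <- (min(core_positions[, 2]) + max(core_positions[, 2])) / 2
  R <- max(sqrt((core_positions[, 1] - cx)^2 + (core_positions[, 2] - cy)^2))
  if (R <= 0) stop("degenerate core positions")
  dx <- 2 * R / grid_size
  list(x0 = cx - R + dx / 2, y0 = cy - R + dx / 2, dx = dx,
       center_grid = c((cx - (cx - R + dx / 2)) / dx,
                       (cy - (cy - R + dx / 2)) / dx),
       radius_grid = R / dx)
}

check_background <- function(b) {
  bad <- which(!is.finite(b) | b <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive blank intensity at core(s) %s",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(b)
}

#' @export
print.interp_calibration <- function(x, ...) {
  cat(sprintf(
    "<interp_calibration> %d cores, grid %d px (%.3g um/px), %d triangles\n",
    nrow(x$core_positions), x$grid_size, x$pixel_pitch, nrow(x$tri)))
  cat(sprintf("  interior fraction %.1f%%\n",
              100 * mean(x$tables$tri_id > 0)))
  invisible(x)
}

#' Extract per-core intensities from a raw frame
#'
#' Takes the pixel value at the nearest integer pixel to each (sub-pixel)
#' core position.
#'
#' @param image raw frame (matrix).
#' @param core_positions n x 2 matrix (`x`, `y`, 0-based pixels).
#' @param bilinear sample with bilinear interpolation instead of the
#'   nearest pixel (default `FALSE`, the nearest-pixel convention).
#' @return numeric vector of per-core intensities.
#' @export
extract_core_values <- function(image, core_positions, bilinear = FALSE) {
  core_positions <- as.matrix(core_positions)
  x <- core_positions[, 1]; y <- core_positions[, 2]
  if (any(x < -0.5 | y < -0.5 | x > ncol(image) - 0.5 | y > nrow(image) - 0.5)) {
    stop("core position outside the image")
  }
  if (bilinear) return(bilinear_sample(image, x, y))
  ix <- round_half_up(x); iy <- round_half_up(y)
  ix <- pmin(pmax(ix, 0), ncol(image) - 1)
  iy <- pmin(pmax(iy, 0), nrow(image) - 1)
  image[cbind(iy + 1, ix + 1)]
}

#' Contrast-normalize core intensities against the blank calibration
#'
#' `c' = (b - c) / b`: background subtraction and flat-fielding in one step.
#' A core seeing blank illumination maps to 0; a fully absorbing object maps
#' to 1, so the contrast is inverted (absorbing features become bright).
#'
#' @param c per-core raw intensities.
#' @param b per-core blank intensities (all > 0).
#' @return per-core contrast values.
#' @export
contrast_normalize <- function(c, b) {
  if (length(c) != length(b)) stop("'c' and 'b' lengths differ")
  check_background(b)
  (b - c) / b
}

#' Reconstruct a de-pixelated hologram from a raw frame
#'
#' Per-frame half of the interpolation pipeline: extract core intensities,
#' optionally contrast-normalize them against the stored blank, and
#' evaluate the precomputed barycentric weighted sum at every grid pixel.
#' Pixels outside the convex hull of the cores are set to 0.
#'
#' @param raw raw camera frame (matrix).
#' @param calib an [calibrate_single()] calibration.
#' @param normalize apply the blank contrast normalization (default `TRUE`).
#' @param background optional per-core background overriding the stored one
#'   (used for per-source backgrounds in multi-source work).
#' @return [hologram_grid()] with the de-pixelated (contrast) hologram.
#' @export
reconstruct <- function(raw, calib, normalize = TRUE, background = NULL) {
  if (!inherits(calib, "interp_calibration")) {
    stop("'calib' must be an interp_calibration")
  }
  cv <- extract_core_values(raw, calib$core_positions)
  b <- background %||% calib$background
  if (normalize) cv <- contrast_normalize(cv, b)
  interp_values(cv, calib)
}

# evaluate the barycentric tables for a vector of per-core values
interp_values <- function(core_values, calib) {
  t <- calib$tables
  p <- numeric(length(t$tri_id))
  idx <- t$tri_id > 0L
  p[idx] <- t$bary[idx, 1] * core_values[t$verts[idx, 1]] +
            t$bary[idx, 2] * core_values[t$verts[idx, 2]] +
            t$bary[idx, 3] * core_values[t$verts[idx, 3]]
  hologram_grid(matrix(p, nrow = calib$grid_size),
                pixel_pitch = calib$pixel_pitch,
                center = calib$center_grid, radius = calib$radius_grid)
}
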
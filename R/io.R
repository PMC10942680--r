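#' Read a grayscale frame or multi-page stack from TIFF
#'
#' @param path TIFF file.
#' @param all read all pages (returns a list of matrices) or only the
#'   first (returns a matrix).
#' @return matrix, or list of matrices when `all = TRUE`.
#' @export
read_frames_tiff <- function(path, all = TRUE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  img <- tryCatch(tiff::readTIFF(path, all = all, as.is = FALSE),
                  error = function(e) stop(sprintf(
                    "failed to read TIFF '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  side <- paste0(path, ".json")
  restore <- if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    function(m) m * meta$scale + meta$offset
  } else identity
  to_gray <- function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]   # drop extra channels
    restore(m)
  }
  if (all) lapply(if (is.list(img)) img else list(img), to_gray)
  else to_gray(if (is.list(img)) img[[1]] else img)
}

#' Write frames as a 16-bit grayscale (multi-page) TIFF
#'
#' Values are scaled by `1 / white_level` and clipped to `[0, 1]` before
#' quantization; `white_level` should exceed the brightest expected pixel
#' (simulated intensities are of order 1).
#'
#' @param frames matrix or list of matrices (page order = source order).
#' @param path output file.
#' @param white_level full-scale value (default 4).
#' @export
write_stack_tiff <- function(frames, path, white_level = 4) {
  if (is.matrix(frames)) frames <- list(frames)
  scaled <- lapply(frames, function(m) pmin(pmax(m / white_level, 0), 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a hologram or amplitude image as 32-bit TIFF
#'
#' Values are stored as 32-bit samples after an affine map into `[0, 1]`;
#' the offset and scale are recorded in a small JSON sidecar
#' (`<path>.json`) which [read_frames_tiff()] uses to restore the original
#' values exactly (to about 1 part in 4e9). This keeps negative-valued
#' contrast holograms lossless within the sample formats the TIFF layer
#' supports.
#'
#' @param image `hologram_grid` or numeric matrix; complex values are
#'   written as their amplitude.
#' @param path output file.
#' @export
write_float_tiff <- function(image, path) {
  v <- if (inherits(image, "hologram_grid")) image$values else image
  if (is.complex(v)) v <- Mod(v)
  rng <- range(v)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((v - rng[1]) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(list(offset = rng[1], scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Persist a calibration container
#'
#' Calibrations (single, enhanced, depth-shift model, LUT) are stored in a
#' single versioned serialized container.
#'
#' @param object calibration object.
#' @param path output file (conventionally `.rds`).
#' @export
save_calibration <- function(object, path) {
  ok <- inherits(object, c("interp_calibration", "enh_calibration",
                           "depth_shift_model", "calibration_lut"))
  if (!ok) stop("not a calibration object")
  saveRDS(list(format = "fibreholo-calibration", format_version = 1L,
               class = class(object), object = object), path)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stop(sprintf("no calibration at '%s'", path))
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "fibreholo-calibration")) {
    stop(sprintf("'%s' is not a calibration container", path))
  }
  x$object
}

#' Write / read core positions as a two-column CSV
#'
#' @param positions n x 2 matrix (`x`, `y` in pixels).
#' @param path CSV file.
#' @export
write_cores_csv <- function(positions, path) {
  utils::write.csv(data.frame(x = positions[, 1], y = positions[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cores_csv
#' @export
read_cores_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x", "y")])
}
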
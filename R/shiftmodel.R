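#' Geometric hologram shift between two illumination fibers
#'
#' For an illumination fiber offset laterally by `s` from the reference
#' fiber, at distance `h` from the object, the hologram of an object at
#' depth `d` from the bundle translates by `s' = s * d / (d + h)`. The
#' shift is zero at zero depth, monotonically increasing in `d`, and
#' bounded above by `s`.
#'
#' @param s fiber separation (um); may be a vector or n x 2 matrix of
#'   offset vectors.
#' @param d object-to-bundle depth (um, >= 0).
#' @param h illuminator-to-object distance (um, > 0).
#' @return shift(s) `s'` in micrometres, same shape as `s`.
#' @examples
#' predict_shift(550, 300, 30000)   # 5.45 um
#' @export
predict_shift <- function(s, d, h) {
  stop_if_not_scalar_pos(h, "h")
  stop_if_not_scalar_pos(d, "d", allow_zero = TRUE)
  if (d + h == 0) stop("d + h must be non-zero")
  s * d / (d + h)
}

#' Fit the per-source depth-to-shift calibration model
#'
#' Shift magnitudes are fitted against depth by least squares through the
#' origin (the shift is known to be exactly zero at zero depth); shift
#' directions are averaged circularly (resultant-vector mean) across
#' depths, since the direction does not change with depth. The fitted model
#' predicts each source's 2D hologram shift at any depth.
#'
#' @param depths vector of object depths (um) at which shifts were measured.
#' @param shifts list with one n_sources x 2 shift matrix (um) per depth,
#'   reference source first (zero shift).
#' @return object of class `depth_shift_model` with per-source `slope`
#'   (shift magnitude per unit depth) and `angle` (radians; `NA` for a
#'   source whose shift never leaves the origin).
#' @export
fit_depth_model <- function(depths, shifts) {
  if (!is.list(shifts)) shifts <- list(shifts)
  if (length(depths) != length(shifts)) {
    stop("'depths' and 'shifts' lengths differ")
  }
  if (!length(depths)) stop("need at least one depth")
  ns <- nrow(as.matrix(shifts[[1]]))
  mags <- matrix(NA_real_, length(depths), ns)
  ux <- matrix(0, length(depths), ns); uy <- matrix(0, length(depths), ns)
  for (i in seq_along(depths)) {
    m <- as.matrix(shifts[[i]])
    if (nrow(m) != ns || ncol(m) != 2) {
      stop(sprintf("shift matrix at depth %g has wrong shape", depths[i]))
    }
    r <- sqrt(rowSums(m^2))
    mags[i, ] <- r
    nz <- r > 0
    ux[i, nz] <- m[nz, 1] / r[nz]
    uy[i, nz] <- m[nz, 2] / r[nz]
  }
  d <- as.numeric(depths)
  slope <- colSums(d * mags) / sum(d^2)       # through-origin least squares
  sx <- colSums(ux); sy <- colSums(uy)
  angle <- ifelse(sx^2 + sy^2 > 0, atan2(sy, sx), NA_real_)
  structure(list(slope = slope, angle = angle, n_sources = ns,
                 depths = d), class = "depth_shift_model")
}

#' @export
print.depth_shift_model <- function(x, ...) {
  cat(sprintf("<depth_shift_model> %d sources, fitted at %d depth(s)\n",
              x$n_sources, length(x$depths)))
  print(coef(x), digits = 4)
  invisible(x)
}

#' @export
coef.depth_shift_model <- function(object, ...) {
  data.frame(source = seq_len(object$n_sources),
             slope = object$slope, angle_rad = object$angle)
}

#' @export
predict.depth_shift_model <- function(object, depth, ...) {
  shifts_at_depth(object, depth)
}

#' Predicted per-source shifts at a given depth
#'
#' @param model a [fit_depth_model()] model.
#' @param d depth (um, >= 0).
#' @return n_sources x 2 matrix of shifts (um).
#' @export
shifts_at_depth <- function(model, d) {
  if (!inherits(model, "depth_shift_model")) {
    stop("'model' must be a depth_shift_model")
  }
  stop_if_not_scalar_pos(d, "d", allow_zero = TRUE)
  ang <- ifelse(is.na(model$angle), 0, model$angle)
  cbind(model$slope * d * cos(ang), model$slope * d * sin(ang))
}

#' Pre-generate a depth-indexed look-up table of enhancement calibrations
#'
#' For every depth on a uniform grid, predicts the per-source shifts from
#' the depth-shift model and builds an enhancement calibration with them
#' (no per-depth registration needed). At imaging time the calibration
#' closest to the requested refocus depth is used.
#'
#' @param core_positions n x 2 core centres (camera pixels).
#' @param blanks list of per-source blank frames.
#' @param model a [fit_depth_model()] model (shifts in um at the bundle
#'   plane).
#' @param depth_min,depth_max,step depth grid (um); e.g. 100 to 500 in
#'   steps of 20 gives 21 calibrations and a worst-case depth error of
#'   10 um.
#' @param ... passed to [calibrate_enhancement()] (`grid_size`,
#'   `cam_pitch`, ...).
#' @return object of class `calibration_lut`.
#' @export
build_lut <- function(core_positions, blanks, model, depth_min, depth_max,
                      step, cam_pitch = 3.7 / 6, ...) {
  if (depth_min >= depth_max && !isTRUE(all.equal(depth_min, depth_max))) {
    if (depth_min > depth_max) stop("'depth_min' must be <= 'depth_max'")
  }
  stop_if_not_scalar_pos(step, "step")
  depths <- seq(depth_min, depth_max, by = step)
  if (!length(depths)) stop("empty depth grid")
  calibs <- lapply(depths, function(d) {
    shifts_px <- shifts_at_depth(model, d) / cam_pitch
    calibrate_enhancement(core_positions, blanks, shifts = shifts_px,
                          depth = d, cam_pitch = cam_pitch, ...)
  })
  structure(list(depths = depths, calibrations = calibs, step = step),
            class = "calibration_lut")
}

#' @export
print.calibration_lut <- function(x, ...) {
  cat(sprintf("<calibration_lut> %d calibrations, depths %g..%g um (step %g)\n",
              length(x$depths), min(x$depths), max(x$depths), x$step))
  invisible(x)
}

#' Fetch the calibration closest to a requested refocus depth
#'
#' Nearest-depth lookup with ties broken toward the smaller depth. The
#' depth error (calibration depth minus requested depth) is attached as
#' attribute `depth_error`.
#'
#' @param lut a [build_lut()] table.
#' @param depth requested refocus depth (um).
#' @return the selected `enh_calibration` (attribute `depth_error` in um).
#' @export
lut_lookup <- function(lut, depth) {
  if (!inherits(lut, "calibration_lut")) stop("'lut' must be a calibration_lut")
  i <- which.min(abs(lut$depths - depth))     # first minimum = smaller depth
  cal <- lut$calibrations[[i]]
  attr(cal, "depth_error") <- lut$depths[i] - depth
  cal
}
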
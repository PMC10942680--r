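#' Estimate the translation between two reconstructed holograms
#'
#' Normalized cross-correlation registration: a central square template one
#' quarter of the bundle diameter is cut from the target and matched against
#' a central square search region one half of the bundle diameter cut from
#' the reference, so the bundle rim is visible in neither. The integer-pixel
#' NCC peak is refined to sub-pixel precision by a separable quadratic fit
#' unless `subpixel = FALSE`.
#'
#' Registration is performed on the contrast holograms (not the raw
#' reconstructions): residual background structure would otherwise bias the
#' correlation peak. Both images are Gaussian smoothed before correlation
#' (default sigma one core spacing): content near and above the Nyquist
#' limit of the single-frame mesh does not translate faithfully under
#' resampling, and correlating it biases the peak towards integer lattice
#' offsets.
#'
#' @param reference,target [hologram_grid()] objects on the same grid.
#' @param subpixel refine the peak by a separable quadratic fit (default).
#' @param smooth_sigma pre-smoothing sigma in grid pixels; 0 disables.
#' @return shift `c(dx, dy)` in grid pixels such that
#'   `target(x) ~ reference(x - shift)`; attribute `peak` holds the NCC
#'   value at the maximum.
#' @export
estimate_shift <- function(reference, target, subpixel = TRUE,
                           smooth_sigma = 0) {
  if (!inherits(reference, "hologram_grid") || !inherits(target, "hologram_grid")) {
    stop("'reference' and 'target' must be hologram_grid objects")
  }
  if (!all(dim(reference$values) == dim(target$values))) {
    stop("reference and target grids differ in size")
  }
  rv <- Re(reference$values); tv <- Re(target$values)
  if (smooth_sigma > 0) {
    rv <- as.matrix(EBImage::gblur(rv, sigma = smooth_sigma))
    tv <- as.matrix(EBImage::gblur(tv, sigma = smooth_sigma))
  }
  D <- 2 * reference$radius
  tside <- max(8L, as.integer(round(D / 4)))
  sside <- max(tside + 4L, as.integer(round(D / 2)))
  n <- nrow(reference$values)
  sside <- min(sside, n)

  crop_center <- function(m, side, cx, cy) {
    x1 <- as.integer(round(cx - side / 2)) + 1L
    y1 <- as.integer(round(cy - side / 2)) + 1L
    x1 <- min(max(x1, 1L), ncol(m) - side + 1L)
    y1 <- min(max(y1, 1L), nrow(m) - side + 1L)
    list(m = m[y1:(y1 + side - 1L), x1:(x1 + side - 1L)],
         x1 = x1 - 1L, y1 = y1 - 1L)       # 0-based crop origin
  }
  cx <- reference$center[1]; cy <- reference$center[2]
  tm <- crop_center(tv, tside, cx, cy)
  sm <- crop_center(rv, sside, cx, cy)
  if (stats::sd(tm$m) == 0) stop("flat template: cannot estimate shift")

  ncc <- cpp_ncc(sm$m, tm$m)
  pk <- arrayInd(which.max(ncc), dim(ncc))
  pr <- pk[1, 1]; pc <- pk[1, 2]              # 1-based row/col of peak
  if (pr == 1L || pc == 1L || pr == nrow(ncc) || pc == ncol(ncc)) {
    warning("NCC peak on the search border; shift may exceed the search range")
  }
  sub <- c(0, 0)
  if (subpixel) {
    para <- function(l, c0, r) {
      den <- l - 2 * c0 + r
      if (den >= 0) 0 else 0.5 * (l - r) / den
    }
    if (pc > 1L && pc < ncol(ncc)) {
      sub[1] <- para(ncc[pr, pc - 1], ncc[pr, pc], ncc[pr, pc + 1])
    }
    if (pr > 1L && pr < nrow(ncc)) {
      sub[2] <- para(ncc[pr - 1, pc], ncc[pr, pc], ncc[pr + 1, pc])
    }
  }
  # template top-left sits at reference coords (sm$x1 + pc - 1, sm$y1 + pr - 1);
  # for target(x) = reference(x - shift) the match lands at (template origin
  # in target coords) - shift
  shift <- c(tm$x1 - (sm$x1 + pc - 1 + sub[1]),
             tm$y1 - (sm$y1 + pr - 1 + sub[2]))
  structure(shift, peak = max(ncc))
}

#' Build a multi-source resolution-enhancement calibration
#'
#' Reconstructs each source's contrast hologram with its own blank
#' calibration, estimates each source's translation relative to the
#' reference source by NCC (or accepts precomputed shifts), translates each
#' source's core coordinates by minus its shift so that every core sits at
#' the position it truly samples on the reference hologram, merges the core
#' sets, removes near-coincident points, and precomputes Delaunay
#' barycentric tables over the merged, denser mesh.
#'
#' @param core_positions n x 2 core centres (camera pixels).
#' @param blanks list of per-source blank frames (reference source first).
#' @param raws list of per-source raw frames of a calibration object;
#'   only needed when `shifts` is `NULL`.
#' @param grid_size reconstruction grid side (default 512).
#' @param cam_pitch camera pixel size at the bundle plane (um).
#' @param depth object depth (um) this calibration is valid for (recorded).
#' @param shifts optional n x 2 matrix of per-source shifts in camera
#'   pixels (reference row zero); when given, NCC estimation is skipped
#'   (used when shifts are predicted from a depth-shift model).
#' @param dedupe_frac merge tolerance as a fraction of the median core
#'   spacing (default 0.05).
#' @return object of class `enh_calibration`.
#' @export
calibrate_enhancement <- function(core_positions, blanks, raws = NULL,
                                  grid_size = 512, cam_pitch = 3.7 / 6,
                                  depth = NA_real_, shifts = NULL,
                                  dedupe_frac = 0.05) {
  core_positions <- as.matrix(core_positions)
  ns <- length(blanks)
  if (ns < 1) stop("need at least one source")
  grid_size <- as.integer(grid_size)

  if (is.null(shifts)) {
    if (is.null(raws) || length(raws) != ns) {
      stop("'raws' must supply one frame per source when shifts are estimated")
    }
    base <- calibrate_single(core_positions, blanks[[1]], grid_size, cam_pitch)
    recon_ref <- reconstruct(raws[[1]], base)
    sigma_grid <- median_nn_spacing(core_positions) / base$dx
    shifts <- matrix(0, ns, 2)
    for (s in seq_len(ns)[-1]) {
      b_s <- extract_core_values(blanks[[s]], core_positions)
      rec <- reconstruct(raws[[s]], base, background = b_s)
      sh <- tryCatch(estimate_shift(recon_ref, rec, smooth_sigma = sigma_grid),
                     error = function(e) stop(sprintf(
                       "shift estimation failed for source %d: %s",
                       s, conditionMessage(e)), call. = FALSE))
      shifts[s, ] <- as.numeric(sh) * base$dx     # grid px -> camera px
    }
  } else {
    shifts <- as.matrix(shifts)
    if (nrow(shifts) != ns) stop("'shifts' must have one row per source")
  }

  # merged mesh: shift every source's cores back to the reference frame
  nc <- nrow(core_positions)
  merged <- do.call(rbind, lapply(seq_len(ns), function(s) {
    sweep(core_positions, 2, shifts[s, ])
  }))
  source_of_core <- rep(seq_len(ns), each = nc)
  core_index <- rep(seq_len(nc), ns)

  spacing <- median_nn_spacing(core_positions)
  keep <- dedupe_points(merged, dedupe_frac * spacing)
  merged <- merged[keep, , drop = FALSE]
  source_of_core <- source_of_core[keep]
  core_index <- core_index[keep]
  if (nrow(merged) < 3) stop("fewer than 3 merged cores")

  geom <- grid_geometry(core_positions, grid_size)
  tri <- triangulate_points(merged)
  tables <- grid_bary_tables(merged, tri, geom$x0, geom$dx, grid_size,
                             geom$y0, geom$dx, grid_size)
  backgrounds <- lapply(blanks, extract_core_values,
                        core_positions = core_positions)
  for (b in backgrounds) check_background(b)

  structure(list(core_positions = merged,
                 orig_positions = core_positions,
                 source_of_core = source_of_core, core_index = core_index,
                 n_sources = ns, shifts_px = shifts,
                 backgrounds = backgrounds,
                 norm_means = vapply(backgrounds, mean, numeric(1)),
                 depth = depth, grid_size = grid_size,
                 pixel_pitch = geom$dx * cam_pitch, cam_pitch = cam_pitch,
                 x0 = geom$x0, y0 = geom$y0, dx = geom$dx,
                 center_grid = geom$center_grid,
                 radius_grid = geom$radius_grid,
                 tri = tri, tables = tables, version = 1L),
            class = "enh_calibration")
}

#' @export
print.enh_calibration <- function(x, ...) {
  cat(sprintf(
    "<enh_calibration> %d sources, %d merged cores, grid %d px (%.3g um/px)\n",
    x$n_sources, nrow(x$core_positions), x$grid_size, x$pixel_pitch))
  if (is.finite(x$depth)) cat(sprintf("  calibrated for depth %.4g um\n", x$depth))
  invisible(x)
}

# median nearest-neighbour distance via cell hashing (avoids O(n^2))
median_nn_spacing <- function(p) {
  n <- nrow(p)
  if (n < 2) return(1)
  cell <- max(1e-9, sqrt(diff(range(p[, 1])) * diff(range(p[, 2])) / n))
  ix <- floor(p[, 1] / cell); iy <- floor(p[, 2] / cell)
  key <- paste(ix, iy)
  buckets <- split(seq_len(n), key)
  sub <- if (n > 4000) sort(sample.int(n, 2000)) else seq_len(n)
  nn <- vapply(sub, function(i) {
    best <- Inf
    for (ddx in -1:1) for (ddy in -1:1) {
      k <- paste(ix[i] + ddx, iy[i] + ddy)
      js <- buckets[[k]]
      if (is.null(js)) next
      js <- js[js != i]
      if (length(js)) {
        d2 <- (p[js, 1] - p[i, 1])^2 + (p[js, 2] - p[i, 2])^2
        best <- min(best, min(d2))
      }
    }
    sqrt(best)
  }, numeric(1))
  stats::median(nn[is.finite(nn)])
}

# indices of points to keep, removing points within tol of an earlier point
dedupe_points <- function(p, tol) {
  n <- nrow(p)
  if (tol <= 0 || n < 2) return(rep(TRUE, n))
  ix <- floor(p[, 1] / tol); iy <- floor(p[, 2] / tol)
  keep <- rep(TRUE, n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    hit <- FALSE
    for (ddx in -1:1) {
      for (ddy in -1:1) {
        k <- paste(ix[i] + ddx, iy[i] + ddy)
        js <- seen[[k]]
        if (!is.null(js)) {
          d2 <- (p[js, 1] - p[i, 1])^2 + (p[js, 2] - p[i, 2])^2
          if (any(d2 < tol^2)) { hit <- TRUE; break }
        }
      }
      if (hit) break
    }
    if (hit) { keep[i] <- FALSE; next }
    k <- paste(ix[i], iy[i])
    seen[[k]] <- c(seen[[k]], i)
  }
  keep
}

#' Reconstruct a resolution-enhanced hologram from a source stack
#'
#' Extracts core intensities from every source's raw frame, optionally
#' rescales each source's values so their mean matches that source's blank
#' mean (cancelling per-source illumination power differences), applies the
#' per-source contrast normalization, and interpolates over the merged
#' shift-corrected mesh.
#'
#' @param raws list of raw frames, one per source, in calibration order.
#' @param calib an [calibrate_enhancement()] calibration.
#' @param mean_normalize rescale each source's raw core intensities to its
#'   blank's mean before contrast normalization (default `TRUE`).
#' @return [hologram_grid()] resolution-enhanced contrast hologram.
#' @export
reconstruct_enhanced <- function(raws, calib, mean_normalize = TRUE) {
  if (!inherits(calib, "enh_calibration")) {
    stop("'calib' must be an enh_calibration")
  }
  if (length(raws) != calib$n_sources) {
    stop(sprintf("stack has %d frames but calibration expects %d sources",
                 length(raws), calib$n_sources))
  }
  cprime <- vector("list", calib$n_sources)
  for (s in seq_len(calib$n_sources)) {
    cv <- extract_core_values(raws[[s]], calib$orig_positions)
    if (mean_normalize) {
      m <- mean(cv)
      if (m <= 0) stop(sprintf("source %d frame has non-positive mean", s))
      cv <- cv * calib$norm_means[s] / m
    }
    cprime[[s]] <- contrast_normalize(cv, calib$backgrounds[[s]])
  }
  merged_vals <- numeric(nrow(calib$core_positions))
  for (s in seq_len(calib$n_sources)) {
    sel <- calib$source_of_core == s
    merged_vals[sel] <- cprime[[s]][calib$core_index[sel]]
  }
  interp_values(merged_vals, calib)
}
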
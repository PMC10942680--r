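# run expr with a private RNG stream so simulation never disturbs the
# caller's random state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Quasi-hexagonal fiber bundle core layout
#'
#' Generates core positions on a hexagonal lattice (one lattice vector along
#' +x) clipped to a circular aperture, with each node perturbed uniformly
#' within a disc of radius `jitter * spacing` and a per-core transmission
#' factor drawn from a Gamma distribution with unit mean and coefficient of
#' variation `transmission_cv`. This emulates the quasi-hexagonal mosaic of
#' a high-density imaging bundle (~3 um core spacing inside a 600 um active
#' area).
#'
#' @param spacing mean core-to-core spacing, micrometres (default 3).
#' @param diameter active area diameter, micrometres (default 600).
#' @param jitter node perturbation as a fraction of `spacing`, in
#'   `[0, 0.5)`; values up to 0.25 preserve a minimum pairwise separation of
#'   half the spacing (default 0.15).
#' @param transmission_cv coefficient of variation of per-core transmission
#'   (default 0.1).
#' @param seed integer seed; generation is deterministic for a fixed seed.
#' @return object of class `core_layout`: `positions` (n x 2 matrix, um,
#'   bundle axis at the origin), `center`, `radius`, `mean_spacing`,
#'   `transmission`.
#' @export
make_bundle_layout <- function(spacing = 3, diameter = 600, jitter = 0.15,
                               transmission_cv = 0.1, seed = 1) {
  stop_if_not_scalar_pos(spacing, "spacing")
  stop_if_not_scalar_pos(diameter, "diameter")
  if (!is.numeric(jitter) || jitter < 0 || jitter >= 0.5) {
    stop("'jitter' must be in [0, 0.5)")
  }
  if (!is.numeric(transmission_cv) || transmission_cv < 0) {
    stop("'transmission_cv' must be >= 0")
  }
  radius <- diameter / 2
  if (diameter < spacing) {
    pos <- matrix(0, 1, 2)
  } else {
    dy <- spacing * sqrt(3) / 2
    nrow_half <- ceiling(radius / dy) + 1
    ncol_half <- ceiling(radius / spacing) + 1
    rows <- (-nrow_half):nrow_half
    pos <- do.call(rbind, lapply(rows, function(r) {
      xs <- ((-ncol_half):ncol_half) * spacing + (r %% 2) * spacing / 2
      cbind(xs, r * dy)
    }))
    keep <- sqrt(rowSums(pos^2)) <= radius - spacing / 2
    pos <- pos[keep, , drop = FALSE]
    if (nrow(pos) == 0L) pos <- matrix(0, 1, 2)
  }
  n <- nrow(pos)
  with_seed(seed, {
    if (jitter > 0 && n > 1L) {
      th <- runif(n, 0, 2 * pi)
      rr <- jitter * spacing * sqrt(runif(n))
      pos <- pos + cbind(rr * cos(th), rr * sin(th))
    }
    transmission <- if (transmission_cv > 0) {
      shape <- 1 / transmission_cv^2
      stats::rgamma(n, shape = shape, rate = shape)
    } else rep(1, n)
  })
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, center = c(0, 0), radius = radius,
                 mean_spacing = spacing, transmission = transmission),
            class = "core_layout")
}

#' @export
print.core_layout <- function(x, ...) {
  cat(sprintf(
    "<core_layout> %d cores, spacing %.3g um, diameter %.4g um\n",
    nrow(x$positions), x$mean_spacing, 2 * x$radius))
  invisible(x)
}

#' @export
plot.core_layout <- function(x, ...) {
  graphics::plot(x$positions, pch = ".", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}

#' Multi-fiber illuminator geometry
#'
#' Lateral offsets of the illumination fibers relative to the reference
#' fiber, the illuminator-to-object distance, and the source wavelength. The
#' default emulates a seven-fiber illuminator: one reference fiber on axis
#' and six fibers on a hexagonal ring, all within an approximately 550 um
#' circle, mounted 30 mm from the sample.
#'
#' @param offsets n x 2 matrix of fiber offsets (um); the first row must be
#'   `c(0, 0)` (reference source). `NULL` builds the default 7-fiber set.
#' @param n_sources number of sources for the default arrangement.
#' @param ring_radius ring radius of the default arrangement (um).
#' @param h illuminator-to-object distance (um), default 30 mm.
#' @param wavelength central wavelength (um); default 0.45 ("royal blue"
#'   LED, configurable).
#' @return object of class `source_geometry`.
#' @export
make_source_geometry <- function(offsets = NULL, n_sources = 7,
                                 ring_radius = 225, h = 30000,
                                 wavelength = 0.45) {
  stop_if_not_scalar_pos(h, "h")
  stop_if_not_scalar_pos(wavelength, "wavelength")
  if (is.null(offsets)) {
    if (n_sources < 1) stop("'n_sources' must be >= 1")
    k <- n_sources - 1
    ang <- if (k > 0) 2 * pi * (0:(k - 1)) / max(k, 1) + pi / 7 else numeric(0)
    offsets <- rbind(c(0, 0),
                     cbind(ring_radius * cos(ang), ring_radius * sin(ang)))
  }
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 2L) stop("'offsets' must have two columns")
  if (any(abs(offsets[1, ]) > 1e-12)) {
    stop("the first (reference) source must have offset (0, 0)")
  }
  structure(list(offsets = offsets, h = h, wavelength = wavelength),
            class = "source_geometry")
}

#' @export
print.source_geometry <- function(x, ...) {
  cat(sprintf(
    "<source_geometry> %d sources, h = %.4g um, lambda = %.3g um\n",
    nrow(x$offsets), x$h, x$wavelength))
  invisible(x)
}

# translate a field by (sx, sy) micrometres using the Fourier shift theorem
fourier_shift <- function(values, pixel_pitch, sx, sy) {
  if (sx == 0 && sy == 0) return(values)
  n <- nrow(values)
  f <- fft_freq(n, pixel_pitch)
  ramp <- exp(-2i * pi * (outer(f * sy, f * sx, "+")))
  out <- stats::fft(stats::fft(values) * ramp, inverse = TRUE) / length(values)
  if (is.complex(values)) out else Re(out)
}

#' Simulate an inline hologram at the bundle plane
#'
#' Propagates an amplitude object over the object-to-bundle distance `d`
#' using the angular spectrum method and records the intensity at the
#' bundle plane. For source `k` the hologram is a pure lateral translation
#' of the reference hologram by `s' = s_k * d / (d + h)` (geometric-shift
#' approximation, valid because the illuminator-to-object distance is much
#' greater than `d`, so the illumination angle change is well under a
#' degree).
#'
#' @param object an [make_usaf_target()] / [make_uniform_object()]
#'   amplitude object.
#' @param geom a [make_source_geometry()].
#' @param source_index which source fired (1 = reference).
#' @param d object-to-bundle distance, micrometres (>= 0).
#' @return list with `intensity` (real matrix, same grid as the object),
#'   `pixel_pitch`, and `shift_um`, the applied translation `c(sx, sy)`.
#' @export
simulate_hologram <- function(object, geom, source_index = 1, d) {
  if (!inherits(object, "amplitude_object")) stop("'object' must be an amplitude_object")
  if (!inherits(geom, "source_geometry")) stop("'geom' must be a source_geometry")
  stop_if_not_scalar_pos(d, "d", allow_zero = TRUE)
  ns <- nrow(geom$offsets)
  if (source_index < 1 || source_index > ns) {
    stop(sprintf("source_index %d out of range 1..%d", source_index, ns))
  }
  if (object$pixel_pitch < geom$wavelength / 2) {
    warning("pixel pitch finer than lambda/2: evanescent components present")
  }
  U <- propagate_forward(object$amplitude, object$pixel_pitch,
                         geom$wavelength, d)
  intensity <- Re(U * Conj(U))
  s <- geom$offsets[source_index, ]
  shift <- s * d / (d + geom$h)
  intensity <- fourier_shift(intensity, object$pixel_pitch,
                             shift[1], shift[2])
  list(intensity = intensity, pixel_pitch = object$pixel_pitch,
       shift_um = shift)
}

# vectorised bilinear sampling of a matrix at 0-based pixel coords
bilinear_sample <- function(img, x, y) {
  nx <- ncol(img); ny <- nrow(img)
  x <- pmin(pmax(x, 0), nx - 1 - 1e-9)
  y <- pmin(pmax(y, 0), ny - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

#' Sample a bundle-plane field through the fiber core mosaic
#'
#' Each core integrates the local field intensity with a Gaussian collection
#' profile, is attenuated by its transmission factor, and receives additive
#' Gaussian noise. The raw camera frame is rendered by painting each core as
#' a Gaussian spot at the camera pixel scale of the proximal-end imaging
#' optics.
#'
#' @param field real intensity matrix from [simulate_hologram()] (or any
#'   field covering the bundle aperture, canvas centred on the bundle axis).
#' @param pixel_pitch field pixel pitch, micrometres.
#' @param layout a [make_bundle_layout()].
#' @param collection_sigma Gaussian collection radius, micrometres; default
#'   one sixth of the core spacing, the second-moment Gaussian equivalent
#'   of a top-hat core aperture of diameter two thirds the spacing (a ~2 um
#'   core in a 3 um-pitch bundle). Values below a tenth of the field pitch
#'   fall back to point (bilinear) sampling.
#' @param noise_sigma additive Gaussian noise SD on core intensities
#'   (intensities are of order 1 for unit illumination); default 0.01.
#' @param seed integer seed for the noise.
#' @param cam_pitch camera pixel size referred to the bundle plane,
#'   micrometres per pixel (default 3.7/6, the pixel size of a 3.7 um camera
#'   behind ~6x relay optics).
#' @param gain global illumination gain applied to this frame.
#' @param render if `FALSE`, skip frame rendering and return core values
#'   only.
#' @return list with `frame` (camera image matrix), `core_values`
#'   (ground-truth per-core intensities), `positions_px` (core positions in
#'   0-based camera pixels), `cam_pitch`, `offset_um` (micrometres from the
#'   bundle axis to the frame's top-left pixel centre, for mapping between
#'   physical and camera coordinates).
#' @export
sample_through_bundle <- function(field, pixel_pitch, layout,
                                  collection_sigma = NULL,
                                  noise_sigma = 0.01, seed = 1,
                                  cam_pitch = 3.7 / 6, gain = 1,
                                  render = TRUE) {
  if (!inherits(layout, "core_layout")) stop("'layout' must be a core_layout")
  n <- nrow(field)
  if (n * pixel_pitch < 2 * layout$radius) {
    stop("field does not cover the bundle aperture")
  }
  collection_sigma <- collection_sigma %||% (layout$mean_spacing / 6)
  fx <- layout$positions[, 1] / pixel_pitch + (n - 1) / 2
  fy <- layout$positions[, 2] / pixel_pitch + (n - 1) / 2
  f <- field
  if (collection_sigma > 0.1 * pixel_pitch) {
    f <- as.matrix(EBImage::gblur(field, sigma = collection_sigma / pixel_pitch))
  }
  vals <- bilinear_sample(f, fx, fy) * layout$transmission * gain
  vals <- with_seed(seed, vals + stats::rnorm(length(vals), 0, noise_sigma))

  side <- 2 * layout$radius + 8 * layout$mean_spacing
  px <- (layout$positions[, 1] + side / 2) / cam_pitch
  py <- (layout$positions[, 2] + side / 2) / cam_pitch
  frame <- NULL
  if (render) {
    npx <- as.integer(ceiling(side / cam_pitch))
    sigma_px <- (layout$mean_spacing / 5) / cam_pitch
    frame <- cpp_render_spots(px, py, vals, sigma_px, npx, npx)
  }
  list(frame = frame, core_values = vals,
       positions_px = cbind(x = px, y = py),
       cam_pitch = cam_pitch, offset_um = side / 2)
}

#' Simulate a multi-source acquisition (raw stack plus blank stack)
#'
#' Fires each illumination source in turn against the object, then repeats
#' with an empty field of view to obtain the per-source blank calibration
#' frames. Per-source LED gains emulate the power spread across illuminator
#' fibers; the same gain applies to a source's raw and blank frame.
#'
#' @param object amplitude object (the scene).
#' @param geom a [make_source_geometry()].
#' @param layout a [make_bundle_layout()].
#' @param d object-to-bundle distance (um).
#' @param seed integer seed (noise and gains).
#' @param noise_sigma additive core-intensity noise SD.
#' @param gain_cv coefficient of variation of per-source LED gain
#'   (default 0.15, matching a roughly +/- 20% power spread).
#' @param shifts_um optional n x 2 matrix of hologram translations (um)
#'   overriding the source-geometry shifts; used to emulate acquisition with
#'   a laterally stepped sample instead of the multi-fiber illuminator.
#' @param ... passed to [sample_through_bundle()].
#' @return list with `raws` and `blanks` (lists of camera frames),
#'   `core_truth` (matrix, cores x sources), `positions_px`, `cam_pitch`,
#'   `offset_um`, `shifts_um` (true per-source hologram translations) and
#'   `gains`.
#' @export
simulate_source_stack <- function(object, geom, layout, d, seed = 1,
                                  noise_sigma = 0.01, gain_cv = 0.15,
                                  shifts_um = NULL, ...) {
  if (is.null(shifts_um)) {
    shifts_um <- geom$offsets * d / (d + geom$h)
  }
  shifts_um <- as.matrix(shifts_um)
  ns <- nrow(shifts_um)
  gains <- with_seed(seed + 7919, {
    if (gain_cv > 0) stats::rgamma(ns, 1 / gain_cv^2, 1 / gain_cv^2) else rep(1, ns)
  })
  U <- propagate_forward(object$amplitude, object$pixel_pitch,
                         geom$wavelength, d)
  base <- Re(U * Conj(U))
  blank_field <- matrix(1, nrow(base), ncol(base))
  raws <- vector("list", ns); blanks <- vector("list", ns)
  truth <- matrix(NA_real_, nrow(layout$positions), ns)
  pos_px <- NULL; cam_pitch <- NULL; offset_um <- NULL
  for (s in seq_len(ns)) {
    ints <- fourier_shift(base, object$pixel_pitch,
                          shifts_um[s, 1], shifts_um[s, 2])
    r <- sample_through_bundle(ints, object$pixel_pitch, layout,
                               noise_sigma = noise_sigma,
                               seed = seed + 2 * s, gain = gains[s], ...)
    b <- sample_through_bundle(blank_field, object$pixel_pitch, layout,
                               noise_sigma = noise_sigma,
                               seed = seed + 2 * s + 1, gain = gains[s], ...)
    raws[[s]] <- r$frame; blanks[[s]] <- b$frame
    truth[, s] <- r$core_values
    pos_px <- r$positions_px; cam_pitch <- r$cam_pitch
    offset_um <- r$offset_um
  }
  list(raws = raws, blanks = blanks, core_truth = truth,
       positions_px = pos_px, cam_pitch = cam_pitch, offset_um = offset_um,
       shifts_um = shifts_um, gains = gains)
}

#' Lateral shift sequence emulating a manually stepped sample
#'
#' A 4 x 4 grid of sample positions (roughly 6 um steps with sub-core
#' jitter) visited in a spread-out order, so that any prefix of the
#' sequence already covers the step cell well. Used to emulate acquiring a
#' stack of holograms while translating the sample, the acquisition mode
#' used to study how many shifted images the enhancement needs. Returned
#' shifts are relative to the first position (the reference frame).
#'
#' @param step grid step in micrometres (default 6.2).
#' @param jitter_um uniform jitter added to each position (default 0.8);
#'   avoids shifts that are exact multiples of the core spacing.
#' @param seed integer seed for the jitter.
#' @return 16 x 2 matrix of shifts (um), first row `c(0, 0)`.
#' @export
sample_shift_sequence <- function(step = 6.2, jitter_um = 0.8, seed = 1) {
  ord <- matrix(c(0,0, 2,2, 0,2, 2,0, 1,1, 3,3, 1,3, 3,1,
                  0,1, 2,3, 1,0, 3,2, 0,3, 2,1, 3,0, 1,2),
                ncol = 2, byrow = TRUE)
  pos <- ord * step
  pos <- with_seed(seed, pos + matrix(runif(32, -jitter_um, jitter_um), 16, 2))
  sweep(pos, 2, pos[1, ])
}
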
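#' Hologram on a regular reconstruction grid
#'
#' Light container for a de-pixelated (contrast) hologram: a square matrix of
#' real or complex values together with its physical pixel pitch and the
#' bundle disc geometry in grid pixels.
#'
#' @param values square numeric or complex matrix, indexed `[y + 1, x + 1]`.
#' @param pixel_pitch physical size of one grid pixel (micrometres).
#' @param center bundle centre `c(x, y)` in 0-based grid pixels; defaults to
#'   the grid centre.
#' @param radius bundle radius in grid pixels; defaults to half the grid.
#' @return object of class `hologram_grid`.
#' @export
hologram_grid <- function(values, pixel_pitch, center = NULL, radius = NULL) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (nrow(values) != ncol(values)) stop("hologram grid must be square")
  stop_if_not_scalar_pos(pixel_pitch, "pixel_pitch")
  n <- nrow(values)
  structure(list(values = values,
                 pixel_pitch = pixel_pitch,
                 center = center %||% c((n - 1) / 2, (n - 1) / 2),
                 radius = radius %||% (n / 2)),
            class = "hologram_grid")
}

#' @export
print.hologram_grid <- function(x, ...) {
  cat(sprintf("<hologram_grid> %d x %d px, pitch %.4g um (%s)\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch,
              if (is.complex(x$values)) "complex" else "real"))
  cat(sprintf("  bundle centre (%.1f, %.1f) px, radius %.1f px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' @export
plot.hologram_grid <- function(x, ...) {
  v <- if (is.complex(x$values)) Mod(x$values) else x$values
  # transpose + row flip so that x runs right and y runs down on screen
  graphics::image(t(v)[, nrow(v):1],
                  col = grDevices::gray(seq(0, 1, length.out = 256)),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

# DFT frequency axis (cycles per micrometre) in standard FFT layout
fft_freq <- function(n, pitch) {
  c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L)) / (n * pitch)
}

#' Angular spectrum propagation kernel
#'
#' Phase accrued by each plane-wave component over a propagation distance
#' `z`: `(2*pi*z/lambda) * sqrt(1 - (lambda*u)^2 - (lambda*v)^2)` on the
#' discrete Fourier frequency grid. Evanescent components
#' (`(lambda*u)^2 + (lambda*v)^2 > 1`) are masked to zero amplitude.
#'
#' @param n grid size in pixels (square grid).
#' @param pixel_pitch grid pixel pitch (micrometres).
#' @param wavelength central wavelength (micrometres).
#' @param z refocus distance (micrometres); positive `z` back-propagates a
#'   bundle-plane hologram to the object plane.
#' @return object of class `refocus_kernel` with elements `phase` (radians),
#'   `mask` (logical, propagating components), `wavelength`, `z`,
#'   `pixel_pitch`, `n`.
#' @export
make_kernel <- function(n, pixel_pitch, wavelength, z) {
  stop_if_not_scalar_pos(wavelength, "wavelength")
  stop_if_not_scalar_pos(pixel_pitch, "pixel_pitch")
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z)) {
    stop("'z' must be a single finite number")
  }
  n <- as.integer(n)
  u <- fft_freq(n, pixel_pitch)
  lu2 <- (wavelength * u)^2
  arg <- 1 - outer(lu2, lu2, "+")      # 1 - (lambda u)^2 - (lambda v)^2
  mask <- arg >= 0
  phase <- (2 * pi * z / wavelength) * sqrt(pmax(arg, 0))
  structure(list(phase = phase, mask = mask, wavelength = wavelength,
                 z = z, pixel_pitch = pixel_pitch, n = n),
            class = "refocus_kernel")
}

#' @export
print.refocus_kernel <- function(x, ...) {
  cat(sprintf(
    "<refocus_kernel> %d px, z = %.4g um, lambda = %.4g um, pitch %.4g um\n",
    x$n, x$z, x$wavelength, x$pixel_pitch))
  invisible(x)
}

#' Numerically refocus a hologram
#'
#' Applies the angular spectrum propagator: the hologram is Fourier
#' transformed, each plane-wave component is multiplied by
#' `exp(i * phase)` from the kernel (evanescent components dropped), and the
#' result inverse transformed. The refocused field is complex; the image of
#' record is its amplitude `Mod()`.
#'
#' @param hologram a [hologram_grid()] (or bare square matrix).
#' @param kernel a [make_kernel()] kernel, or `NULL` to build one from
#'   `z` and `wavelength`.
#' @param z,wavelength used when `kernel` is `NULL`.
#' @return `hologram_grid` with complex values at the refocused plane.
#' @export
refocus <- function(hologram, kernel = NULL, z = NULL, wavelength = NULL) {
  hg <- as_hologram(hologram)
  if (is.null(kernel)) {
    if (is.null(z) || is.null(wavelength)) {
      stop("supply either 'kernel' or both 'z' and 'wavelength'")
    }
    kernel <- make_kernel(nrow(hg$values), hg$pixel_pitch, wavelength, z)
  }
  if (!inherits(kernel, "refocus_kernel")) stop("'kernel' is not a refocus_kernel")
  if (kernel$n != nrow(hg$values)) {
    stop(sprintf("kernel size %d does not match hologram size %d",
                 kernel$n, nrow(hg$values)))
  }
  if (abs(kernel$pixel_pitch - hg$pixel_pitch) > 1e-9 * hg$pixel_pitch) {
    stop("kernel pixel pitch does not match hologram pixel pitch")
  }
  if (kernel$z == 0) {          # identity by contract, evanescent content kept
    out <- hg
    out$values <- hg$values + 0i
    return(out)
  }
  H <- stats::fft(hg$values)
  H <- H * exp(1i * kernel$phase)
  H[!kernel$mask] <- 0
  out <- hg
  out$values <- stats::fft(H, inverse = TRUE) / length(H)
  out
}

# forward propagation used by the simulator: the conjugate of the refocus
# propagator, so that refocus(z = d) brings a hologram formed at distance d
# back into focus
propagate_forward <- function(values, pixel_pitch, wavelength, d) {
  if (d == 0) return(values + 0i)
  k <- make_kernel(nrow(values), pixel_pitch, wavelength, d)
  H <- stats::fft(values) * exp(-1i * k$phase)
  H[!k$mask] <- 0
  stats::fft(H, inverse = TRUE) / length(H)
}

as_hologram <- function(x) {
  if (inherits(x, "hologram_grid")) return(x)
  if (is.matrix(x)) stop("bare matrix lacks a pixel pitch; use hologram_grid()")
  stop("cannot interpret input as a hologram grid")
}

#' Circular cosine edge window
#'
#' Apodization mask that is 1 inside radius `R`, 0 beyond `R + w`, and falls
#' as `cos((pi / (2 w)) * (r - R))^2` across the transition band. Applied to
#' contrast holograms before refocusing to suppress ringing from the
#' intensity step at the bundle rim.
#'
#' @param n grid size (pixels).
#' @param center disc centre `c(x, y)`, 0-based grid pixels.
#' @param R inner radius (pixels) of the flat region.
#' @param w taper width in pixels (default 5).
#' @return `n` x `n` numeric mask.
#' @export
cosine_window <- function(n, center, R, w = 5) {
  stop_if_not_scalar_pos(R, "R")
  stop_if_not_scalar_pos(w, "w")
  n <- as.integer(n)
  if (R + w > n / 2) {
    warning("window extends beyond the grid half-size; rim will be clipped")
  }
  xs <- (0:(n - 1)) - center[1]
  ys <- (0:(n - 1)) - center[2]
  r <- sqrt(outer(ys^2, xs^2, "+"))     # [y + 1, x + 1]
  m <- cos((pi / (2 * w)) * (r - R))^2
  m[r < R] <- 1
  m[r > R + w] <- 0
  m
}

#' Apply a window mask to a hologram
#'
#' @param hologram a [hologram_grid()].
#' @param mask numeric matrix from [cosine_window()] (same size).
#' @return windowed `hologram_grid`.
#' @export
apply_window <- function(hologram, mask) {
  hg <- as_hologram(hologram)
  if (!all(dim(mask) == dim(hg$values))) stop("mask size mismatch")
  hg$values <- hg$values * mask
  hg
}

#' Image sharpness metric for focus search
#'
#' Normalized variance of the amplitude, `var(A) / mean(A)^2`, over the
#' interior of the bundle disc (or a supplied mask). Invariant to global
#' intensity scaling; zero for a constant image. Higher values indicate a
#' sharper (better focused) image. The variance is taken on the amplitude
#' rather than the squared intensity: on refocused inline holograms of
#' sparse absorbing objects the intensity variance keeps growing with the
#' defocused twin's fringe energy, whereas the amplitude variance peaks at
#' the object plane.
#'
#' @param image amplitude image: `hologram_grid` or numeric matrix.
#' @param mask optional logical matrix selecting the pixels to use; defaults
#'   to the bundle interior when `image` is a `hologram_grid`, else all
#'   pixels.
#' @return single numeric sharpness value.
#' @export
focus_metric <- function(image, mask = NULL) {
  if (inherits(image, "hologram_grid")) {
    v <- image$values
    if (is.null(mask)) {
      n <- nrow(v)
      xs <- (0:(n - 1)) - image$center[1]
      ys <- (0:(n - 1)) - image$center[2]
      mask <- sqrt(outer(ys^2, xs^2, "+")) < 0.9 * image$radius
    }
  } else {
    v <- image
    if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  }
  if (!any(mask)) stop("focus metric mask selects no pixels")
  a <- if (is.complex(v)) Mod(v) else v
  a <- a[mask]
  m <- mean(a)
  if (m == 0) return(0)
  stats::var(a) / m^2
}
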
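#' Spatial frequency of a USAF 1951 element
#'
#' The 1951 USAF chart assigns element `e` of group `g` the spatial frequency
#' `2^(g + (e - 1)/6)` line pairs per millimetre.
#'
#' @param group group number (integer, may be negative).
#' @param element element number, 1 to 6.
#' @return spatial frequency in lp/mm.
#' @examples
#' lp_per_mm(7, 4)   # 181.02
#' lp_per_mm(8, 4)   # 362.04
#' @export
lp_per_mm <- function(group, element) {
  if (any(element < 1 | element > 6 | element != round(element))) {
    stop("'element' must be an integer between 1 and 6")
  }
  2^(group + (element - 1) / 6)
}

#' Line-pair period corresponding to a spatial frequency
#'
#' Resolution is quoted here as the full line-pair period, `1000 / (lp/mm)`
#' micrometres, the same convention used when quoting a chart element as
#' "resolved".
#'
#' @param lp spatial frequency in lp/mm.
#' @return period in micrometres.
#' @examples
#' resolution_um(lp_per_mm(7, 4))  # 5.52 um
#' @export
resolution_um <- function(lp) {
  if (any(!is.finite(lp)) || any(lp <= 0)) stop("'lp' must be positive")
  1000 / lp
}

#' Synthetic USAF 1951 three-bar resolution target
#'
#' Renders opaque (amplitude 0) three-bar patterns on a unit-amplitude
#' background. Each element is drawn in both orientations side by side:
#' vertical bars (modulating along x) on the left, horizontal bars
#' (modulating along y) on the right. Bar width is half the line-pair
#' period; bar length is five times the width; bars are separated by
#' one-bar-width gaps. Elements are stacked top to bottom in the order
#' given.
#'
#' @param groups list of `c(group, element)` pairs; an empty list gives a
#'   uniform unit-amplitude canvas.
#' @param pixel_pitch canvas pixel pitch in micrometres; must render at
#'   least 4 pixels per bar of the finest element.
#' @param canvas_um physical canvas side length in micrometres; enlarged
#'   automatically if the layout does not fit.
#' @param gap_um vertical spacing between consecutive elements
#'   (micrometres); default twice the coarser element's bar width. Generous
#'   gaps keep the defocused twin image of one element from spilling onto
#'   its neighbours.
#' @return object of class `amplitude_object`: a list with `amplitude`
#'   (matrix in `[0, 1]`, indexed `[y + 1, x + 1]`, canvas centred on the
#'   optical axis), `pixel_pitch`, and `elements`, a data frame with one row
#'   per rendered bar pattern (`group`, `element`, `lp_mm`, `period_um`,
#'   `bar_w`, `orientation`, `cx`, `cy` in micrometres relative to the
#'   canvas centre).
#' @export
make_usaf_target <- function(groups, pixel_pitch, canvas_um = 200,
                             gap_um = NULL) {
  stop_if_not_scalar_pos(pixel_pitch, "pixel_pitch")
  stop_if_not_scalar_pos(canvas_um, "canvas_um")
  rows <- lapply(groups, function(ge) {
    lp <- lp_per_mm(ge[1], ge[2])
    p <- resolution_um(lp)
    data.frame(group = ge[1], element = ge[2], lp_mm = lp,
               period_um = p, bar_w = p / 2)
  })
  info <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = numeric(0), element = numeric(0), lp_mm = numeric(0),
               period_um = numeric(0), bar_w = numeric(0))

  if (nrow(info)) {
    finest <- min(info$bar_w)
    if (finest / pixel_pitch < 4) {
      i <- which.min(info$bar_w)
      stop(sprintf(
        "element G%dE%d is under-sampled: bar width %.3g um needs pixel pitch <= %.3g um",
        info$group[i], info$element[i], finest, finest / 4))
    }
  }

  # vertical block spans 5w wide, horizontal block 5w; 3w gap between them;
  # consecutive elements are separated by twice the coarser element's bar
  block_w <- 13 * info$bar_w
  block_h <- 5 * info$bar_w
  gap_y <- if (nrow(info) > 1) {
    if (is.null(gap_um)) 2 * info$bar_w[-nrow(info)]
    else rep(gap_um, nrow(info) - 1)
  } else numeric(0)
  total_h <- sum(block_h) + sum(gap_y)
  need <- max(c(canvas_um, block_w + 4, total_h + 4))
  n <- as.integer(ceiling(need / pixel_pitch))
  if (n %% 2L == 1L) n <- n + 1L

  amp <- matrix(1, n, n)
  xs <- ((0:(n - 1)) - (n - 1) / 2) * pixel_pitch   # um, column coords
  ys <- xs                                          # row coords

  draw_bars <- function(amp, cx, cy, w, orientation) {
    centers <- c(-2 * w, 0, 2 * w)
    half_len <- 2.5 * w
    for (cc in centers) {
      if (orientation == "v") {
        sel_x <- xs >= cx + cc - w / 2 & xs < cx + cc + w / 2
        sel_y <- ys >= cy - half_len & ys < cy + half_len
      } else {
        sel_y <- ys >= cy + cc - w / 2 & ys < cy + cc + w / 2
        sel_x <- xs >= cx - half_len & xs < cx + half_len
      }
      amp[sel_y, sel_x] <- 0
    }
    amp
  }

  out <- vector("list", 2L * nrow(info))
  y_top <- -total_h / 2
  for (i in seq_len(nrow(info))) {
    w <- info$bar_w[i]
    cy <- y_top + 2.5 * w
    cx_v <- -4 * w
    cx_h <- +4 * w
    amp <- draw_bars(amp, cx_v, cy, w, "v")
    amp <- draw_bars(amp, cx_h, cy, w, "h")
    out[[2 * i - 1]] <- cbind(info[i, ], orientation = "v", cx = cx_v, cy = cy)
    out[[2 * i]] <- cbind(info[i, ], orientation = "h", cx = cx_h, cy = cy)
    y_top <- y_top + 5 * w + if (i < nrow(info)) gap_y[i] else 0
  }
  elements <- if (length(out)) do.call(rbind, out) else
    cbind(info, orientation = character(0), cx = numeric(0), cy = numeric(0))
  rownames(elements) <- NULL

  structure(list(amplitude = amp, pixel_pitch = pixel_pitch,
                 elements = elements, depth = NA_real_),
            class = "amplitude_object")
}

#' Uniform amplitude object (blank scene)
#'
#' @param canvas_um canvas side in micrometres.
#' @param pixel_pitch pixel pitch in micrometres.
#' @param value constant amplitude in `[0, 1]`.
#' @return `amplitude_object` with no elements.
#' @export
make_uniform_object <- function(canvas_um, pixel_pitch, value = 1) {
  if (value < 0 || value > 1) stop("'value' must be in [0, 1]")
  n <- as.integer(ceiling(canvas_um / pixel_pitch))
  if (n %% 2L == 1L) n <- n + 1L
  structure(list(amplitude = matrix(value, n, n), pixel_pitch = pixel_pitch,
                 elements = NULL, depth = NA_real_),
            class = "amplitude_object")
}

#' @export
print.amplitude_object <- function(x, ...) {
  cat(sprintf("<amplitude_object> %d x %d px, pitch %.4g um (%.4g um canvas)\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pixel_pitch,
              nrow(x$amplitude) * x$pixel_pitch))
  if (!is.null(x$elements) && nrow(x$elements)) {
    els <- unique(x$elements[, c("group", "element")])
    cat("  USAF elements:",
        paste(sprintf("G%dE%d", els$group, els$element), collapse = ", "),
        "\n")
  }
  invisible(x)
}
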
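#' Locate fiber-core centres in a bundle calibration image
#'
#' Seven-step morphological procedure: (1) Gaussian smooth with sigma equal
#' to one fifth of the estimated core spacing, to suppress modal structure
#' within cores; (2) grayscale dilation with a 3 px circular structuring
#' element; (3) subtract the dilated image from the original, so local
#' maxima sit at exactly zero (dilation does not change the value of a local
#' maximum); (4) threshold, keeping only the (near-)maxima; (5) dilate the
#' resulting mask with a circular element one third of the core spacing in
#' diameter, merging maxima split by residual multimode structure; (6) take
#' the unweighted centroid of every connected region; (7) discard centroids
#' farther than the bundle radius from the bundle centre.
#'
#' @param image single-channel numeric matrix (calibration frame, no
#'   sample in the field of view).
#' @param est_spacing estimated core-to-core spacing in pixels (>= 2).
#' @param bundle_center bundle centre `c(x, y)` in 0-based pixels; estimated
#'   with [estimate_bundle_geometry()] when `NULL`.
#' @param bundle_radius bundle radius in pixels.
#' @param eps_frac step-4 tolerance: pixels with `original - dilated >=
#'   -eps_frac * dynamic range` are kept as maxima. Zero keeps exact maxima
#'   only (appropriate for noiseless input); the default 0.02 tolerates
#'   mild noise. Structuring-element diameters round to the nearest odd
#'   pixel count.
#' @param threshold intensity level for step 4: candidate maxima must also
#'   reach this level in the smoothed image. `NULL` (default) sets it by
#'   Otsu's method over the smoothed pixels inside the bundle disc, which
#'   separates core peaks from the darker inter-core gaps and makes the
#'   detected count insensitive to sensor noise.
#' @return n x 2 matrix of sub-pixel core centres (`x`, `y`, 0-based
#'   pixels).
#' @export
find_cores <- function(image, est_spacing, bundle_center = NULL,
                       bundle_radius = NULL, eps_frac = 0.02,
                       threshold = NULL) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (est_spacing < 2) stop("'est_spacing' must be at least 2 pixels")
  if (is.null(bundle_center) || is.null(bundle_radius)) {
    g <- estimate_bundle_geometry(image)
    bundle_center <- bundle_center %||% g$center
    # the equivalent-area radius of the thresholded face sits slightly
    # inside the outermost cores; pad so genuine edge cores survive step 7
    bundle_radius <- bundle_radius %||% (g$radius + est_spacing)
  }

  sm <- as.matrix(EBImage::gblur(image, sigma = est_spacing / 5))
  dil <- as.matrix(EBImage::dilate(sm, EBImage::makeBrush(3L, "disc")))
  diffimg <- sm - dil                       # <= 0, maxima at 0

  # restrict to the bundle disc before labelling so that flat regions
  # outside the aperture cannot form spurious regions (step-7 constraint
  # applied at pixel level as well as to the centroids)
  nx <- ncol(image); ny <- nrow(image)
  xs <- (0:(nx - 1)) - bundle_center[1]
  ys <- (0:(ny - 1)) - bundle_center[2]
  inside <- sqrt(outer(ys^2, xs^2, "+")) <= bundle_radius

  rng <- range(sm[inside])
  if (diff(rng) <= 1e-3 * diff(range(sm))) {
    warning("no signal inside the bundle radius; no cores found")
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  }
  if (is.null(threshold)) {
    norm <- pmin(pmax((sm - rng[1]) / diff(rng), 0), 1)
    th <- EBImage::otsu(EBImage::Image(norm * inside), range = c(0, 1))
    threshold <- rng[1] + th * diff(rng)
  }
  keep <- diffimg >= -eps_frac * diff(rng) & sm >= threshold & inside

  # discrete disc diameter nearest to est_spacing/3 (odd); below 3 px the
  # dilation is the identity and is skipped -- at ~5 px core spacing a 3 px
  # merge element would fuse the maxima of adjacent cores
  merge_d <- 2L * as.integer(round((est_spacing / 3 - 1) / 2)) + 1L
  mask <- if (merge_d >= 3L) {
    as.matrix(EBImage::dilate(keep * 1, EBImage::makeBrush(merge_d, "disc"))) > 0
  } else keep
  lab <- EBImage::bwlabel(mask)
  labv <- as.integer(lab)
  sel <- which(labv > 0L)
  if (!length(sel)) {
    warning("no core maxima found")
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  }
  # unweighted region centroids, 0-based pixel coords
  row0 <- (sel - 1) %% ny          # y
  col0 <- (sel - 1) %/% ny         # x
  grp <- labv[sel]
  cx <- tapply(col0, grp, mean)
  cy <- tapply(row0, grp, mean)
  cen <- cbind(x = as.numeric(cx), y = as.numeric(cy))

  d <- sqrt((cen[, 1] - bundle_center[1])^2 + (cen[, 2] - bundle_center[2])^2)
  cen <- cen[d <= bundle_radius, , drop = FALSE]
  if (!nrow(cen)) warning("all detected cores fell outside the bundle radius")
  cen
}

#' Estimate the bundle disc from a calibration image
#'
#' Thresholds the illuminated bundle face (Otsu), takes the largest
#' connected foreground component, and fits an equivalent-area circle.
#' Accuracy degrades (radius within ~5%) when the disc touches the frame
#' edge.
#'
#' @param image single-channel numeric matrix with the bundle face brighter
#'   than the background.
#' @return list with `center` (`c(x, y)`, 0-based pixels) and `radius`
#'   (pixels).
#' @export
estimate_bundle_geometry <- function(image) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  rng <- range(image)
  if (diff(rng) == 0) stop("blank image: cannot estimate bundle geometry")
  norm <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > th
  # close the gaps between core spots so the face forms one component
  bw <- as.matrix(EBImage::closing(bw * 1, EBImage::makeBrush(9L, "disc"))) > 0
  lab <- EBImage::bwlabel(bw)
  labv <- as.integer(lab)
  if (!any(labv > 0)) stop("no foreground found: cannot estimate bundle geometry")
  counts <- tabulate(labv[labv > 0L])
  big <- which.max(counts)
  sel <- which(labv == big)
  ny <- nrow(image)
  row0 <- (sel - 1) %% ny
  col0 <- (sel - 1) %/% ny
  list(center = c(mean(col0), mean(row0)),
       radius = sqrt(length(sel) / pi))
}
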
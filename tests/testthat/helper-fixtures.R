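# shared simulated fixtures, built once per test run
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small bundle (~1.3k cores) and a 7-source USAF stack at d = 180 um
fx_layout <- function() fx("layout", function() {
  make_bundle_layout(spacing = 3, diameter = 120, jitter = 0.15,
                     transmission_cv = 0.1, seed = 7)
})

fx_geom <- function() make_source_geometry()

fx_scene <- function() fx("scene", function() {
  make_usaf_target(list(c(7, 2), c(8, 2)), pixel_pitch = 0.25,
                   canvas_um = 140, gap_um = 12)
})

fx_stack <- function() fx("stack", function() {
  simulate_source_stack(fx_scene(), fx_geom(), fx_layout(), d = 180,
                        seed = 19, noise_sigma = 0.01)
})

fx_cores <- function() fx("cores", function() {
  find_cores(fx_stack()$blanks[[1]], est_spacing = 3 / fx_stack()$cam_pitch)
})

fx_calib <- function() fx("calib", function() {
  calibrate_single(fx_cores(), fx_stack()$blanks[[1]], grid_size = 256,
                   cam_pitch = fx_stack()$cam_pitch)
})

# brute-force circumcircle check: TRUE if no point lies strictly inside any
# triangle's circumcircle (the Delaunay property)
delaunay_property_holds <- function(p, tri, tol = 1e-9) {
  x <- p[, 1]; y <- p[, 2]
  for (t in seq_len(nrow(tri))) {
    a <- tri[t, 1]; b <- tri[t, 2]; cc <- tri[t, 3]
    ax <- x[a]; ay <- y[a]; bx <- x[b]; by <- y[b]; cx <- x[cc]; cy <- y[cc]
    D <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / D
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / D
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (x - ux)^2 + (y - uy)^2
    inside <- setdiff(which(d2 < r2 - tol * r2), c(a, b, cc))
    if (length(inside)) return(FALSE)
  }
  TRUE
}

# match detected points against truth; returns recall, spurious rate and
# RMS position error of the matched detections
match_detections <- function(detected, truth, tol = 1) {
  nn_t <- apply(truth, 1, function(p) {
    min(sqrt((detected[, 1] - p[1])^2 + (detected[, 2] - p[2])^2))
  })
  nn_d <- apply(detected, 1, function(p) {
    min(sqrt((truth[, 1] - p[1])^2 + (truth[, 2] - p[2])^2))
  })
  list(recall = mean(nn_t < tol),
       spurious = mean(nn_d >= tol),
       rms = sqrt(mean(nn_t[nn_t < tol]^2)))
}

with_seed_rnorm <- function(seed, n, sd) {
  set.seed(seed)
  rnorm(n, 0, sd)
}
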
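test_that("bundle layout matches hexagonal packing density", {
  lay <- make_bundle_layout(spacing = 3, diameter = 600, jitter = 0,
                            transmission_cv = 0, seed = 1)
  expected <- pi * 300^2 / (sqrt(3) / 2 * 3^2)      # ~36,000
  expect_lt(abs(nrow(lay$positions) - expected) / expected, 0.1)
  lay33 <- make_bundle_layout(spacing = 3.3, diameter = 600, jitter = 0,
                              transmission_cv = 0, seed = 1)
  expect_lt(abs(nrow(lay33$positions) - 30000) / 30000, 0.1)
})

test_that("layout honours aperture, jitter and determinism contracts", {
  expect_equal(nrow(make_bundle_layout(10, 5, seed = 1)$positions), 1)
  a <- make_bundle_layout(3, 90, jitter = 0.2, seed = 42)
  b <- make_bundle_layout(3, 90, jitter = 0.2, seed = 42)
  expect_identical(a, b)
  expect_true(all(sqrt(rowSums(a$positions^2)) <= a$radius))
  expect_true(all(a$transmission > 0))
  d <- dist(a$positions)
  expect_gte(min(d), 0.5 * a$mean_spacing)
  expect_error(make_bundle_layout(-3, 600), "positive")
  expect_error(make_bundle_layout(3, 600, jitter = 0.7), "jitter")
})

test_that("USAF chart arithmetic reproduces the standard frequencies", {
  expect_equal(lp_per_mm(0, 1), 1)
  expect_equal(lp_per_mm(7, 4), 181.02, tolerance = 1e-4)
  expect_equal(lp_per_mm(8, 4), 362.04, tolerance = 1e-4)
  expect_equal(resolution_um(1000), 1)
  expect_equal(round(resolution_um(lp_per_mm(7, 4)), 1), 5.5)
  expect_equal(round(resolution_um(lp_per_mm(8, 4)), 1), 2.8)
  expect_error(lp_per_mm(7, 7), "element")
  expect_error(resolution_um(0), "positive")
})

test_that("USAF target renders 5:1 bars at the element period", {
  obj <- make_usaf_target(list(c(7, 4)), pixel_pitch = 0.25)
  e <- obj$elements[obj$elements$orientation == "v", ]
  expect_equal(e$bar_w, e$period_um / 2)
  # a period (bar + gap) spans 1000/181.02/0.25 ~ 22 canvas pixels
  expect_equal(e$period_um / obj$pixel_pitch, 22.1, tolerance = 0.01)
  # count opaque pixels in one bar row: 3 bars x width x 5:1 length
  opaque <- sum(obj$amplitude == 0)
  bar_px <- (e$bar_w / 0.25) * (5 * e$bar_w / 0.25)
  expect_equal(opaque, 2 * 3 * bar_px, tolerance = 0.1)
  expect_error(make_usaf_target(list(c(9, 6)), pixel_pitch = 0.25),
               "under-sampled")
  blankobj <- make_usaf_target(list(), pixel_pitch = 1, canvas_um = 50)
  expect_true(all(blankobj$amplitude == 1))
})

test_that("hologram simulation obeys zero-depth and plane-wave limits", {
  obj <- make_usaf_target(list(c(6, 1)), pixel_pitch = 0.5, canvas_um = 80)
  geom <- make_source_geometry(h = 30000)
  h0 <- simulate_hologram(obj, geom, source_index = 1, d = 0)
  expect_equal(h0$intensity, obj$amplitude^2, tolerance = 1e-9)
  expect_equal(h0$shift_um, c(0, 0))
  u <- make_uniform_object(80, 0.5)
  hu <- simulate_hologram(u, geom, source_index = 2, d = 250)
  expect_equal(hu$intensity, matrix(1, nrow(u$amplitude), ncol(u$amplitude)),
               tolerance = 1e-7)
  expect_error(simulate_hologram(obj, geom, source_index = 9, d = 100),
               "out of range")
})

test_that("source shift follows the geometric similar-triangles law", {
  geom <- make_source_geometry(offsets = rbind(c(0, 0), c(550, 0)),
                               h = 30000)
  obj <- make_uniform_object(60, 0.5)
  h <- simulate_hologram(obj, geom, source_index = 2, d = 300)
  expect_equal(sqrt(sum(h$shift_um^2)), 550 * 300 / 30300, tolerance = 1e-12)
})

test_that("propagation conserves energy for band-limited fields", {
  set.seed(5)
  f <- matrix(runif(128^2), 128, 128)
  f <- as.matrix(EBImage::gblur(f, 3))          # band-limit
  U <- fibreholo:::propagate_forward(f, 0.5, 0.45, 200)
  expect_equal(sum(Mod(U)^2), sum(f^2), tolerance = 1e-3)
})

test_that("bundle sampling reproduces uniform and ramp fields", {
  lay <- make_bundle_layout(3, 60, jitter = 0.1, transmission_cv = 0,
                            seed = 2)
  n <- 160
  uniform <- matrix(0.7, n, n)
  s <- sample_through_bundle(uniform, 0.5, lay, noise_sigma = 0, seed = 1)
  expect_equal(s$core_values, rep(0.7, nrow(lay$positions)),
               tolerance = 1e-6)
  # point-sampling limit on a linear ramp
  ramp <- matrix(seq(0, 1, length.out = n), n, n, byrow = TRUE)
  s2 <- sample_through_bundle(ramp, 0.5, lay, collection_sigma = 0,
                              noise_sigma = 0, seed = 1)
  expected <- (lay$positions[, 1] / 0.5 + (n - 1) / 2) / (n - 1)
  expect_equal(s2$core_values, expected, tolerance = 1e-6)
  # determinism with noise
  a <- sample_through_bundle(uniform, 0.5, lay, noise_sigma = 0.05, seed = 9)
  b <- sample_through_bundle(uniform, 0.5, lay, noise_sigma = 0.05, seed = 9)
  expect_identical(a$frame, b$frame)
  expect_error(sample_through_bundle(matrix(1, 20, 20), 0.5, lay),
               "cover")
})

test_that("sample shift sequence spreads its prefixes", {
  s <- sample_shift_sequence(seed = 1)
  expect_equal(dim(s), c(16, 2))
  expect_equal(s[1, ], c(0, 0))
  # any 4-frame prefix already spans most of the 3-step grid extent
  expect_gt(diff(range(s[1:4, 1])), 6.2)
  expect_gt(diff(range(s[1:4, 2])), 6.2)
})
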
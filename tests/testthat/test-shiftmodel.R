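test_that("geometric shift prediction follows s*d/(d+h)", {
  expect_equal(predict_shift(550, 300, 30000), 550 * 300 / 30300)
  expect_equal(round(predict_shift(550, 300, 30000), 2), 5.45)
  expect_equal(predict_shift(550, 0, 30000), 0)
  expect_equal(predict_shift(0, 300, 30000), 0)
  # monotone in d and bounded above by s
  d <- seq(0, 5000, by = 100)
  s <- predict_shift(550, 0, 30000)
  vals <- vapply(d, function(dd) predict_shift(550, dd, 30000), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 550))
  expect_error(predict_shift(550, -1, 30000), "d")
})

test_that("through-origin fit recovers slope and constant angle from noiseless shifts", {
  geom <- make_source_geometry()
  depths <- c(60, 90, 120, 150)            # h >> d regime (h = 30 mm)
  shifts <- lapply(depths, function(d) geom$offsets * d / (d + geom$h))
  model <- fit_depth_model(depths, shifts)
  s_mag <- sqrt(rowSums(geom$offsets^2))
  expect_equal(model$slope[1], 0)
  rel <- abs(model$slope[-1] - s_mag[-1] / geom$h) / (s_mag[-1] / geom$h)
  expect_true(all(rel < 0.005))
  # the per-depth angles are identical, so the circular mean matches any one
  ang <- atan2(geom$offsets[-1, 2], geom$offsets[-1, 1])
  spread <- abs(Arg(exp(1i * (model$angle[-1] - ang))))
  expect_true(all(spread < 1e-9))
})

test_that("degenerate fits behave as documented", {
  m1 <- fit_depth_model(200, list(rbind(c(0, 0), c(3, 4))))
  expect_equal(m1$slope, c(0, 5 / 200))
  m0 <- fit_depth_model(c(100, 200),
                        list(matrix(0, 3, 2), matrix(0, 3, 2)))
  expect_true(all(m0$slope == 0))
  expect_true(all(is.na(m0$angle)))
  expect_error(fit_depth_model(c(100, 200),
                               list(matrix(0, 3, 2), matrix(0, 4, 2))),
               "shape")
})

test_that("fit then predict round-trips noiseless shift data", {
  geom <- make_source_geometry()
  depths <- c(60, 90, 120, 150)
  shifts <- lapply(depths, function(d) geom$offsets * d / (d + geom$h))
  model <- fit_depth_model(depths, shifts)
  for (i in seq_along(depths)) {
    expect_equal(shifts_at_depth(model, depths[i]), unname(shifts[[i]]),
                 tolerance = 0.01, ignore_attr = TRUE)
  }
  expect_equal(shifts_at_depth(model, 0), matrix(0, 7, 2),
               ignore_attr = TRUE)
  m <- fit_depth_model(100, list(rbind(c(0, 0), c(1.8, 0))))
  expect_equal(predict(m, 100)[2, ], c(1.8, 0), tolerance = 1e-12)
})

test_that("LUT construction and nearest-depth lookup follow the grid", {
  stack <- fx_stack()
  cores <- fx_cores()
  geom <- make_source_geometry()
  depths <- c(100, 200, 300, 400)
  shifts <- lapply(depths, function(d) geom$offsets * d / (d + geom$h))
  model <- fit_depth_model(depths, shifts)

  lut <- build_lut(cores, stack$blanks, model, 100, 500, 20,
                   cam_pitch = stack$cam_pitch, grid_size = 64)
  expect_equal(length(lut$depths), 21)
  expect_equal(lut$depths, seq(100, 500, by = 20))

  hit <- lut_lookup(lut, 178)
  expect_equal(hit$depth, 180)
  expect_equal(attr(hit, "depth_error"), 2)
  exact <- lut_lookup(lut, 300)
  expect_equal(attr(exact, "depth_error"), 0)
  # worst-case depth error on a 20 um grid is 10 um
  errs <- vapply(seq(100, 500, by = 3), function(d) {
    abs(attr(lut_lookup(lut, d), "depth_error"))
  }, numeric(1))
  expect_lte(max(errs), 10)
  # tie broken toward the smaller depth
  expect_equal(lut_lookup(lut, 190)$depth, 180)

  # a LUT entry equals a directly built calibration at that depth
  direct <- calibrate_enhancement(
    cores, stack$blanks,
    shifts = shifts_at_depth(model, 200) / stack$cam_pitch,
    grid_size = 64, cam_pitch = stack$cam_pitch, depth = 200)
  entry <- lut_lookup(lut, 200)
  attr(entry, "depth_error") <- NULL
  expect_equal(entry, direct)

  single <- build_lut(cores, stack$blanks, model, 150, 160, 50,
                      cam_pitch = stack$cam_pitch, grid_size = 64)
  expect_equal(single$depths, 150)
  expect_error(build_lut(cores, stack$blanks, model, 500, 100, 20),
               "depth_min")
})
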
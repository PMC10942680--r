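test_that("barycentric calibration hits the textbook triangle cases", {
  p <- rbind(c(0, 0), c(10, 0), c(0, 10))
  blank <- matrix(100, 12, 12)
  calib <- calibrate_single(p, blank, grid_size = 16)
  # pixel nearest a vertex -> weight concentrated on that vertex
  t <- calib$tables
  corner <- which(t$tri_id > 0)[1]
  expect_true(all(abs(rowSums(t$bary[t$tri_id > 0, , drop = FALSE]) - 1) <
                    1e-9))
  # centroid of the one triangle gets (1/3, 1/3, 1/3)
  g <- grid_bary_tables(p, calib$tri, x0 = 10 / 3, dx = 1, nx = 1,
                        y0 = 10 / 3, dy = 1, ny = 1)
  expect_equal(as.numeric(g$bary), rep(1 / 3, 3), tolerance = 1e-9)
  g2 <- grid_bary_tables(p, calib$tri, x0 = 0, dx = 1, nx = 1,
                         y0 = 0, dy = 1, ny = 1)
  expect_equal(sort(as.numeric(g2$bary)), c(0, 0, 1), tolerance = 1e-9)
  expect_error(calibrate_single(p, blank, grid_size = 8), "at least 16")
  expect_error(calibrate_single(rbind(c(0, 0), c(1, 1), c(2, 2)),
                                blank, 32), "collinear")
})

test_that("core value extraction uses the nearest-pixel convention", {
  img <- matrix(seq_len(30 * 30), 30, 30)   # value = y+1 + 30*x
  expect_equal(extract_core_values(img, rbind(c(10.6, 20.2))),
               img[21, 12])                 # rounds to (11, 20)
  expect_equal(extract_core_values(matrix(7, 5, 5),
                                   rbind(c(1, 1), c(3.2, 2.9))), c(7, 7))
  expect_error(extract_core_values(img, rbind(c(40, 2))), "outside")
  # bilinear option interpolates
  expect_equal(extract_core_values(img, rbind(c(10.5, 20)),
                                   bilinear = TRUE),
               (img[21, 11] + img[21, 12]) / 2)
})

test_that("contrast normalization inverts contrast against the blank", {
  expect_equal(contrast_normalize(100, 100), 0)
  expect_equal(contrast_normalize(0, 100), 1)
  expect_equal(contrast_normalize(80, 100), 0.2)
  expect_error(contrast_normalize(c(1, 2), c(1, 0)), "core")
})

test_that("reconstruction is exact for constant and affine core fields", {
  calib <- fx_calib()
  pos <- calib$core_positions
  # constant field
  raw <- matrix(3.5, 400, 400)
  hg <- reconstruct(raw, calib, normalize = FALSE)
  inside <- matrix(fx_calib()$tables$tri_id > 0, calib$grid_size)
  expect_true(all(abs(hg$values[inside] - 3.5) < 1e-9))
  # affine field sampled at the cores reproduces exactly (barycentric
  # interpolation is exact on affine functions)
  cv <- 0.2 * pos[, 1] - 0.1 * pos[, 2] + 5
  hol <- fibreholo:::interp_values(cv, calib)
  t <- calib$tables
  idx <- which(t$tri_id > 0)
  gx <- calib$x0 + ((idx - 1) %/% calib$grid_size) * calib$dx
  gy <- calib$y0 + ((idx - 1) %% calib$grid_size) * calib$dx
  expect_equal(as.numeric(hol$values)[idx], 0.2 * gx - 0.1 * gy + 5,
               tolerance = 1e-9)
  # outside the hull the hologram is zero
  expect_true(all(hg$values[!inside] == 0))
})

test_that("reconstructing the blank with normalization is identically zero", {
  stack <- fx_stack()
  calib <- fx_calib()
  hg <- reconstruct(stack$blanks[[1]], calib, normalize = TRUE)
  inside <- matrix(calib$tables$tri_id > 0, calib$grid_size)
  expect_true(all(abs(hg$values[inside]) < 1e-9))
})

test_that("calibration is idempotent and round-trips through the container", {
  stack <- fx_stack()
  a <- calibrate_single(fx_cores(), stack$blanks[[1]], 64, stack$cam_pitch)
  b <- calibrate_single(fx_cores(), stack$blanks[[1]], 64, stack$cam_pitch)
  expect_identical(a, b)
  path <- tempfile(fileext = ".rds")
  save_calibration(a, path)
  expect_identical(load_calibration(path), a)
  unlink(path)
})

test_that("rendered frames round-trip core intensities at fine camera sampling", {
  lay <- make_bundle_layout(3, 60, jitter = 0.12, transmission_cv = 0,
                            seed = 4)
  n <- 160
  set.seed(8)
  field <- as.matrix(EBImage::gblur(matrix(runif(n^2, 0.5, 1), n), 6))
  s <- sample_through_bundle(field, 0.5, lay, noise_sigma = 0, seed = 1,
                             cam_pitch = 0.2)
  got <- extract_core_values(s$frame, s$positions_px)
  rel <- (got - s$core_values) / s$core_values
  expect_lt(sqrt(mean(rel^2)), 0.02)
})
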
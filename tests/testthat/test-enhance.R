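test_that("NCC registration recovers constructed translations to sub-pixel", {
  calib <- fx_calib()
  hg <- reconstruct(fx_stack()$raws[[1]], calib)
  expect_lt(max(abs(as.numeric(estimate_shift(hg, hg)))), 0.05)
  # integer translation built by re-indexing the grid
  sh <- hg
  v <- hg$values
  n <- nrow(v)
  shifted <- matrix(0, n, n)
  shifted[(1 + 2):(n), (1 + 3):n] <- v[1:(n - 2), 1:(n - 3)]
  sh$values <- shifted                      # target = ref shifted by (3, 2)
  est <- estimate_shift(hg, sh)
  expect_lt(max(abs(as.numeric(est) - c(3, 2))), 0.2)
  # sub-pixel translation via Fourier shift
  sub <- hg
  sub$values <- fibreholo:::fourier_shift(v, 1, 2.4, -1.6)
  est2 <- estimate_shift(hg, sub)
  expect_lt(max(abs(as.numeric(est2) - c(2.4, -1.6))), 0.2)
  flat <- hg; flat$values <- matrix(1, n, n)
  expect_error(estimate_shift(hg, flat), "flat|variance")
})

test_that("NCC recovers the physical inter-source shifts", {
  stack <- fx_stack()
  calib <- calibrate_enhancement(fx_cores(), stack$blanks, stack$raws,
                                 grid_size = 256,
                                 cam_pitch = stack$cam_pitch, depth = 180)
  err <- calib$shifts_px - stack$shifts_um / stack$cam_pitch
  expect_lt(max(abs(err)), 1)              # camera px (= 0.62 um)
})

test_that("a one-source enhancement calibration reduces to the single calibration", {
  stack <- fx_stack()
  enh <- calibrate_enhancement(fx_cores(), stack$blanks[1], stack$raws[1],
                               grid_size = 256, cam_pitch = stack$cam_pitch)
  single <- calibrate_single(fx_cores(), stack$blanks[[1]], 256,
                             stack$cam_pitch)
  a <- reconstruct_enhanced(stack$raws[1], enh, mean_normalize = FALSE)
  b <- reconstruct(stack$raws[[1]], single)
  expect_lt(max(abs(a$values - b$values)), 1e-9)
})

test_that("merging seven shifted core sets multiplies sampling density", {
  stack <- fx_stack()
  cores <- fx_cores()
  enh <- calibrate_enhancement(cores, stack$blanks,
                               shifts = stack$shifts_um / stack$cam_pitch,
                               grid_size = 256, cam_pitch = stack$cam_pitch)
  # all cores from all sources, minus de-duplicated coincident points
  expect_lte(nrow(enh$core_positions), 7 * nrow(cores))
  expect_gte(nrow(enh$core_positions), 0.95 * 7 * nrow(cores))
  nn1 <- fibreholo:::median_nn_spacing(cores)
  nn7 <- fibreholo:::median_nn_spacing(enh$core_positions)
  expect_equal(nn7 / nn1, 1 / sqrt(7), tolerance = 0.25)
  # identical shifts collapse to the single-source density
  dup <- calibrate_enhancement(cores, stack$blanks[c(1, 1)],
                               shifts = matrix(0, 2, 2),
                               grid_size = 256, cam_pitch = stack$cam_pitch)
  expect_equal(nrow(dup$core_positions), nrow(cores))
})

test_that("enhanced reconstruction of blanks is zero and source gains cancel", {
  stack <- fx_stack()
  enh <- calibrate_enhancement(fx_cores(), stack$blanks, stack$raws,
                               grid_size = 256,
                               cam_pitch = stack$cam_pitch, depth = 180)
  hb <- reconstruct_enhanced(stack$blanks, enh)
  inside <- matrix(enh$tables$tri_id > 0, enh$grid_size)
  expect_lt(max(abs(hb$values[inside])), 1e-9)
  # per-source global intensity rescaling leaves the output unchanged
  set.seed(10)
  g <- runif(7, 0.6, 1.5)
  scaled <- lapply(seq_along(stack$raws), function(s) g[s] * stack$raws[[s]])
  a <- reconstruct_enhanced(stack$raws, enh)
  b <- reconstruct_enhanced(scaled, enh)
  expect_lt(max(abs(a$values - b$values)), 1e-6)
  expect_error(reconstruct_enhanced(stack$raws[1:3], enh), "sources")
})

test_that("enhanced reconstruction restricted to the reference cores equals single-frame", {
  # the merged-mesh machinery must agree with the single mesh wherever the
  # meshes coincide: with one source the meshes are identical
  stack <- fx_stack()
  cores <- fx_cores()
  enh1 <- calibrate_enhancement(cores, stack$blanks[1],
                                shifts = matrix(0, 1, 2),
                                grid_size = 256, cam_pitch = stack$cam_pitch)
  single <- calibrate_single(cores, stack$blanks[[1]], 256, stack$cam_pitch)
  expect_identical(enh1$tables, single$tables)
  a <- reconstruct_enhanced(stack$raws[1], enh1, mean_normalize = FALSE)
  b <- reconstruct(stack$raws[[1]], single)
  expect_lt(max(abs(a$values - b$values)), 1e-9)
})

test_that("the merged mesh reconstructs a translated smooth field better than one frame", {
  lay <- make_bundle_layout(3, 60, jitter = 0.15, transmission_cv = 0,
                            seed = 6)
  n <- 200
  set.seed(12)
  field <- as.matrix(EBImage::gblur(matrix(runif(n^2), n), 4))
  shifts <- rbind(c(0, 0), c(1.1, 0.4), c(-0.5, 1.2), c(0.7, -0.9))
  frames <- lapply(seq_len(4), function(s) {
    f <- fibreholo:::fourier_shift(field, 0.5, shifts[s, 1], shifts[s, 2])
    sample_through_bundle(f, 0.5, lay, noise_sigma = 0, seed = s)
  })
  blank <- sample_through_bundle(matrix(1, n, n), 0.5, lay,
                                 noise_sigma = 0, seed = 99)
  cam <- blank$cam_pitch
  enh <- calibrate_enhancement(blank$positions_px,
                               rep(list(blank$frame), 4),
                               shifts = shifts / cam,
                               grid_size = 256, cam_pitch = cam)
  single <- calibrate_single(blank$positions_px, blank$frame, 256, cam)
  rec_m <- reconstruct_enhanced(lapply(frames, `[[`, "frame"), enh,
                                mean_normalize = FALSE)
  rec_1 <- reconstruct(frames[[1]]$frame, single)
  # compare both contrast holograms against the true contrast field on the
  # interior
  truth_at <- function(calib) {
    idx <- which(calib$tables$tri_id > 0)
    gx <- calib$x0 + ((idx - 1) %/% calib$grid_size) * calib$dx
    gy <- calib$y0 + ((idx - 1) %% calib$grid_size) * calib$dx
    ux <- gx * cam - blank$offset_um
    uy <- gy * cam - blank$offset_um
    fx <- ux / 0.5 + (n - 1) / 2
    fy <- uy / 0.5 + (n - 1) / 2
    sm <- as.matrix(EBImage::gblur(field, sigma = (3 / 6) / 0.5))
    list(idx = idx, truth = 1 - fibreholo:::bilinear_sample(sm, fx, fy))
  }
  tm <- truth_at(enh)
  t1 <- truth_at(single)
  err_m <- sqrt(mean((as.numeric(rec_m$values)[tm$idx] - tm$truth)^2))
  err_1 <- sqrt(mean((as.numeric(rec_1$values)[t1$idx] - t1$truth)^2))
  expect_lt(err_m, err_1)
})
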
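band_limited_field <- function(n = 128, seed = 2) {
  set.seed(seed)
  as.matrix(EBImage::gblur(matrix(rnorm(n^2), n), 3))
}

test_that("kernel phase follows the angular spectrum dispersion relation", {
  k <- make_kernel(64, pixel_pitch = 0.5, wavelength = 0.45, z = 120)
  expect_equal(k$phase[1, 1], 2 * pi * 120 / 0.45)
  k0 <- make_kernel(64, 0.5, 0.45, 0)
  expect_true(all(k0$phase == 0))
  # direct evaluation at u = 1 cycle/um, v = 0 (z = 100, lambda = 0.45)
  expected <- (2 * pi * 100 / 0.45) * sqrt(1 - (0.45 * 1)^2)
  kk <- make_kernel(100, pixel_pitch = 0.25, wavelength = 0.45, z = 100)
  # frequency index 25 on a 100-px grid at 0.25 um pitch is exactly 1 /um
  expect_equal(kk$phase[1, 26], expected, tolerance = 1e-9)
  expect_equal(expected, 1246.92, tolerance = 1e-4)
  expect_error(make_kernel(64, 0.5, -1, 10), "wavelength")
})

test_that("evanescent components are masked", {
  k <- make_kernel(64, pixel_pitch = 0.2, wavelength = 0.45, z = 50)
  lu2 <- (0.45 * fibreholo:::fft_freq(64, 0.2))^2
  expect_identical(k$mask, outer(lu2, lu2, "+") <= 1)
  expect_false(all(k$mask))
})

test_that("refocus is unitary, invertible and the identity at z = 0", {
  f <- band_limited_field()
  hg <- hologram_grid(f, pixel_pitch = 0.5)
  expect_equal(refocus(hg, z = 0, wavelength = 0.45)$values, f + 0i)
  fwd <- refocus(hg, z = 150, wavelength = 0.45)
  expect_equal(sum(Mod(fwd$values)^2), sum(f^2), tolerance = 1e-6)
  back <- refocus(fwd, z = -150, wavelength = 0.45)
  expect_lt(sqrt(mean(Mod(back$values - f)^2)), 1e-9)
  # group property: two hops equal one combined hop
  two <- refocus(refocus(hg, z = 60, wavelength = 0.45),
                 z = 90, wavelength = 0.45)
  expect_lt(max(Mod(two$values - fwd$values)), 1e-9)
  expect_error(refocus(hg, kernel = make_kernel(32, 0.5, 0.45, 10)),
               "size")
})

test_that("a simulated hologram refocuses to a sharp image at the true depth", {
  # 10 um opaque disc at d = 300 um
  n <- 240
  xs <- ((0:(n - 1)) - (n - 1) / 2) * 0.5
  amp <- matrix(1, n, n)
  amp[sqrt(outer(xs^2, xs^2, "+")) < 5] <- 0
  obj <- make_uniform_object(n * 0.5, 0.5)
  obj$amplitude <- amp
  holo <- simulate_hologram(obj, make_source_geometry(), 1, d = 300)
  contrast <- 1 - holo$intensity
  hg <- hologram_grid(contrast, 0.5)
  zs <- seq(240, 360, by = 10)
  fm <- vapply(zs, function(z) {
    a <- refocus(hg, z = z, wavelength = 0.45)
    a$values <- Mod(a$values)
    focus_metric(a)
  }, numeric(1))
  expect_lte(abs(zs[which.max(fm)] - 300), 10)
  # the refocused disc is recovered: dark-interior mean well above rim haze
  best <- refocus(hg, z = 300, wavelength = 0.45)
  img <- Mod(best$values)
  inside <- sqrt(outer(xs^2, xs^2, "+")) < 3
  outside <- sqrt(outer(xs^2, xs^2, "+")) > 20 &
    sqrt(outer(xs^2, xs^2, "+")) < 40
  expect_gt(mean(img[inside]), 3 * mean(img[outside]))
})

test_that("cosine window follows its piecewise definition", {
  n <- 101
  m <- cosine_window(n, center = c(50, 50), R = 30, w = 10)
  r <- function(x, y) m[y + 1, x + 1]
  expect_equal(r(50, 50), 1)
  expect_equal(r(50 + 41, 50), 0)          # beyond R + w
  expect_equal(r(50 + 35, 50), cos(pi / 4)^2, tolerance = 1e-9) # midpoint
  expect_equal(r(50 + 35, 50), 0.5, tolerance = 1e-9)
  expect_warning(cosine_window(64, c(32, 32), R = 40, w = 10), "grid")
})

test_that("windowing suppresses rim ringing in the refocused image", {
  n <- 256
  xs <- (0:(n - 1)) - (n - 1) / 2
  r <- sqrt(outer(xs^2, xs^2, "+"))
  holo <- matrix(0.2, n, n)
  holo[r > 100] <- 0                       # bundle-edge step
  hg <- hologram_grid(holo, 0.5, center = c((n - 1) / 2, (n - 1) / 2),
                      radius = 100)
  plain <- refocus(hg, z = 150, wavelength = 0.45)
  win <- refocus(apply_window(hg, cosine_window(n, hg$center, R = 95, w = 5)),
                 z = 150, wavelength = 0.45)
  annulus <- r > 100 & r < 115
  expect_lt(sqrt(mean(Mod(win$values[annulus])^2)),
            sqrt(mean(Mod(plain$values[annulus])^2)))
})

test_that("focus metric is scale-invariant and prefers the focused image", {
  expect_equal(focus_metric(matrix(5, 32, 32)), 0)
  f <- band_limited_field()
  expect_equal(focus_metric(f), focus_metric(10 * f))
  defocused <- as.matrix(EBImage::gblur(f, 4))
  expect_gt(focus_metric(f), focus_metric(defocused))
  expect_error(focus_metric(f, mask = matrix(FALSE, 128, 128)), "no pixels")
})
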
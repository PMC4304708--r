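# Pixel-level operators: colour transform, guided filter, morphology,
# hysteresis.

test_that("YCbCr transform matches the full-range BT.601 matrix", {
  px <- function(rgb) array(rgb, dim = c(1, 1, 3))
  red <- rgb_to_ycbcr(px(c(1, 0, 0)))
  expect_equal(red$Y[1, 1], 0.299)
  expect_equal(red$Cb[1, 1], 0.331264)
  expect_equal(red$Cr[1, 1], 1.0)
  black <- rgb_to_ycbcr(px(c(0, 0, 0)))
  expect_equal(black$Y[1, 1], 0)
  expect_equal(black$Cb[1, 1], 0.5)
  expect_equal(black$Cr[1, 1], 0.5)
  # any achromatic image has Cb = Cr = 0.5 exactly
  set.seed(1)
  g <- matrix(runif(30), 5, 6)
  img <- array(c(g, g, g), dim = c(5, 6, 3))
  yc <- rgb_to_ycbcr(img)
  expect_lt(max(abs(yc$Cb - 0.5)), 1e-9)
  expect_lt(max(abs(yc$Cr - 0.5)), 1e-9)
  expect_equal(yc$Y, g, tolerance = 1e-12)
  # studio-range option: achromatic chroma sits at 128/255, luma is compressed
  st <- rgb_to_ycbcr(img, range = "studio")
  expect_lt(max(abs(st$Cb - 128 / 255)), 1e-9)
  expect_equal(st$Y, (16 + 219 * g) / 255, tolerance = 1e-9)
})

test_that("invalid images are rejected with a diagnostic", {
  bad <- array(0.5, dim = c(2, 2, 3)); bad[1, 1, 1] <- NaN
  expect_error(rgb_to_ycbcr(bad), "non-finite")
  expect_error(rgb_image(array(1.5, dim = c(2, 2, 3))), "\\[0, 1\\]")
  expect_error(rgb_image(matrix(0.5, 2, 2)), "H x W x 3")
})

test_that("erythema intensity is the chroma mean", {
  px <- function(rgb) array(rgb, dim = c(1, 1, 3))
  expect_equal(erythema_intensity(px(c(1, 0, 0)))[1, 1],
               (1.0 + 0.331264) / 2)
  expect_lt(erythema_intensity(px(c(0, 1, 0)))[1, 1], 0.5) # green: below baseline
  g <- matrix(seq(0, 1, length.out = 12), 3, 4)
  achro <- array(c(g, g, g), dim = c(3, 4, 3))
  expect_equal(erythema_intensity(achro), matrix(0.5, 3, 4), tolerance = 1e-12)
})

test_that("guided filter matches the per-window coefficient oracle", {
  set.seed(7)
  cases <- list(
    list(m = matrix(runif(25), 5, 5), w = 3, eps = 0.1),
    list(m = matrix(runif(63), 7, 9), w = 5, eps = 0.01),
    list(m = matrix(runif(40), 8, 5), w = 7, eps = 1)
  )
  # impulse on a flat field: the sharpest small case for edge preservation
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  cases[[4]] <- list(m = imp, w = 3, eps = 0.1)
  for (cs in cases) {
    expect_equal(guided_filter(cs$m, cs$w, cs$eps),
                 oracle_guided_filter(cs$m, cs$w, cs$eps),
                 tolerance = 1e-12)
  }
})

test_that("guided filter edge cases: identity at window 0, constant in -> constant out", {
  m <- matrix(runif(36), 6, 6)
  expect_identical(guided_filter(m, 0, 0.1), m)
  cm <- matrix(0.37, 5, 8)
  expect_equal(guided_filter(cm, 5, 0.01), cm, tolerance = 1e-12)
  expect_error(guided_filter(m, 4, 0.1), "odd")
  expect_error(guided_filter(m, 3, 0), "positive")
})

test_that("guided filter is shift-equivariant and reduces variance", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(runif(64, 0, 0.5), 8, 8)
    q <- guided_filter(m, 3, 0.05)
    expect_equal(guided_filter(m + 0.3, 3, 0.05), q + 0.3, tolerance = 1e-10)
    expect_lt(var(as.vector(q)), var(as.vector(m)))
  }
})

test_that("opening by reconstruction matches the erosion + geodesic-dilation oracle", {
  set.seed(23)
  for (i in 1:10) {
    m <- matrix(runif(144), 12, 12)
    r <- sample(1:3, 1)
    expect_equal(open_by_reconstruction(m, r),
                 oracle_open_by_reconstruction(m, r), tolerance = 1e-12)
  }
})

test_that("opening by reconstruction levels small plateaus and keeps flats", {
  cm <- matrix(0.4, 10, 10)
  expect_equal(open_by_reconstruction(cm, 3), cm)
  plat <- matrix(0.4, 12, 12)
  plat[6:7, 6:7] <- 0.6 # 2x2 plateau, disc radius 3 cannot fit
  expect_equal(open_by_reconstruction(plat, 3), matrix(0.4, 12, 12))
  peaks <- extract_peaks(plat, 3)
  expect_equal(peaks[6, 6], 0.2)
  expect_equal(sum(peaks > 0), 4)
})

test_that("opening by reconstruction is anti-extensive, increasing and idempotent", {
  set.seed(31)
  for (i in 1:10) {
    a <- matrix(runif(100), 10, 10)
    b <- pmin(a + matrix(runif(100, 0, 0.2), 10, 10), 1)
    oa <- open_by_reconstruction(a, 2)
    ob <- open_by_reconstruction(b, 2)
    expect_true(all(oa <= a + 1e-12))                    # anti-extensive
    expect_true(all(oa <= ob + 1e-12))                   # increasing (a <= b)
    expect_equal(open_by_reconstruction(oa, 2), oa,      # idempotent
                 tolerance = 1e-12)
  }
})

test_that("peak extraction is non-negative and zero on constants", {
  expect_equal(extract_peaks(matrix(0.7, 9, 9), 2), matrix(0, 9, 9))
  set.seed(5)
  m <- matrix(runif(121), 11, 11)
  p <- extract_peaks(m, 2)
  expect_true(all(p >= 0))
  expect_equal(p, pmax(m - oracle_open_by_reconstruction(m, 2), 0),
               tolerance = 1e-12)
})

test_that("disc radius larger than both image dimensions is rejected", {
  expect_error(open_by_reconstruction(matrix(0, 5, 5), 6), "exceeds")
  expect_no_error(open_by_reconstruction(matrix(0, 5, 20), 6)) # fits one dim
})

test_that("hysteresis matches the flood-fill oracle and its degenerate forms", {
  set.seed(13)
  for (i in 1:25) {
    m <- matrix(runif(100), 10, 10)
    tl <- runif(1, 0.2, 0.5); th <- runif(1, tl, 0.9)
    expect_identical(hysteresis_threshold(m, tl, th),
                     oracle_hysteresis(m, tl, th))
  }
  # t_low == t_high reduces to plain thresholding
  m <- matrix(runif(100), 10, 10)
  expect_identical(hysteresis_threshold(m, 0.5, 0.5), m >= 0.5)
  # all below t_low -> empty
  expect_false(any(hysteresis_threshold(matrix(0.1, 6, 6), 0.2, 0.4)))
  expect_error(hysteresis_threshold(m, 0.5, 0.4), "t_low")
})

test_that("hysteresis keeps whole connected regions reaching t_high and drops the rest", {
  m <- matrix(0, 8, 12)
  m[2:4, 2:4] <- 0.3; m[3, 3] <- 0.9    # region crossing t_high
  m[6:7, 9:11] <- 0.35                  # region that never reaches t_high
  out <- hysteresis_threshold(m, 0.25, 0.8)
  expect_true(all(out[2:4, 2:4]))
  expect_false(any(out[6:7, 9:11]))
})
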
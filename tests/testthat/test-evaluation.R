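# Pixel metrics, co-localization matching and confusion counting.

test_that("pixel metrics: identical, disjoint and hand-computed cases", {
  a <- matrix(FALSE, 6, 6); a[2:4, 2:4] <- TRUE
  m <- pixel_metrics(a, a)
  expect_equal(c(m$sensitivity, m$ppv, m$f2), c(1, 1, 1))
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  m2 <- pixel_metrics(a, b)
  expect_equal(c(m2$sensitivity, m2$ppv, m2$f2), c(0, 0, 0))
  expect_error(pixel_metrics(a, matrix(FALSE, 5, 6)), "shape")
  # F2 from the published pixel fractions, against the direct formula
  f2 <- f2_score(0.531, 0.398)
  expect_equal(f2, 5 * 0.531 * 0.398 / (4 * 0.398 + 0.531), tolerance = 1e-12)
  expect_equal(f2, 0.4977, tolerance = 1e-4)
})

test_that("F2 equals the generic F-beta formula at beta = 2", {
  fbeta <- function(p, r, beta) (1 + beta^2) * p * r / (beta^2 * p + r)
  set.seed(2)
  for (i in 1:20) {
    s <- runif(1, 0.05, 1); p <- runif(1, 0.05, 1)
    expect_equal(f2_score(s, p), fbeta(p, s, 2), tolerance = 1e-12)
  }
  expect_true(is.nan(pixel_metrics(matrix(FALSE, 3, 3),
                                   matrix(FALSE, 3, 3))$sensitivity))
})

test_that("co-localization pairs by centroid containment", {
  # one test lesion wholly inside one reference lesion
  ref <- rect_lesion_set(20, 20, 4, 12, 4, 12)
  tst <- rect_lesion_set(20, 20, 6, 8, 6, 8)
  m <- colocalize(ref, tst)
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$unmatched_reference, 0)
  expect_length(m$unmatched_test, 0)
  # opposite corners: no match either way
  far_ref <- rect_lesion_set(20, 20, 0, 2, 0, 2)
  far_tst <- rect_lesion_set(20, 20, 17, 19, 17, 19)
  m2 <- colocalize(far_ref, far_tst)
  expect_equal(nrow(m2$pairs), 0)
  expect_length(m2$unmatched_reference, 1)
  expect_length(m2$unmatched_test, 1)
  expect_error(colocalize(ref, rect_lesion_set(21, 20, 1, 2, 1, 2)), "shape")
})

test_that("extra matches to the same reference lesion are removed from consideration", {
  # one wide reference lesion, two small test lesions inside it
  refmask <- matrix(FALSE, 20, 30); refmask[6:15, 3:28] <- TRUE
  ref <- label_lesions(refmask)
  tstmask <- matrix(FALSE, 20, 30)
  tstmask[9:11, 6:8] <- TRUE
  tstmask[9:11, 20:22] <- TRUE
  tst <- label_lesions(tstmask)
  m <- colocalize(ref, tst)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$test_id, 1)          # the first (raster order) wins
  expect_equal(m$unmatched_test, 2)         # the second counts as test-only
  cc <- confusion_counts(m)
  expect_equal(c(cc$matched, cc$reference_only, cc$test_only), c(1, 0, 1))
})

test_that("match existence is symmetric for random single-lesion pairs", {
  set.seed(37)
  for (i in 1:30) {
    H <- 24; W <- 24
    mk <- function() {
      r0 <- sample(0:(H - 6), 1); c0 <- sample(0:(W - 6), 1)
      h <- sample(2:5, 1); w <- sample(2:5, 1)
      rect_lesion_set(H, W, r0, min(r0 + h, H - 1), c0, min(c0 + w, W - 1))
    }
    a <- mk(); b <- mk()
    expect_equal(nrow(colocalize(a, b)$pairs), nrow(colocalize(b, a)$pairs))
  }
})

test_that("confusion counts conserve totals", {
  scn <- generate_scene(scene_spec(height_px = 96, width_px = 96,
                                   n_lesions = 5, seed = 9))
  det <- label_lesions(detect(scn$image,
                              detection_params(9, 0.1, 16, 0.003, 0.008)))
  m <- colocalize(scn$lesions, det)
  cc <- confusion_counts(m)
  expect_equal(cc$matched + cc$reference_only, n_lesions(scn$lesions))
  expect_equal(cc$matched + cc$test_only, n_lesions(det))
})

test_that("lesion-level metrics reproduce the published confusion tables", {
  cc <- clinical_reference_counts()
  lm <- lesion_metrics(cc$matched, cc$reference_only, cc$test_only)
  expect_equal(round(100 * lm$sensitivity, 1), c(39.5, 53.1, 65.9, 75.9))
  expect_equal(round(100 * lm$ppv, 1), c(13.9, 39.8, 54.5, 66.6))
  expect_true(is.nan(lesion_metrics(0, 0, 0)$sensitivity))
})

test_that("per-image counts table feeds correlation analyses", {
  expect_equal(nrow(per_image_counts(list())), 0)
  sets <- list(rect_lesion_set(10, 10, 1, 2, 1, 2),
               label_lesions(matrix(FALSE, 10, 10), source_id = "empty"))
  sets[[1]]$source_id <- "one"
  tab <- per_image_counts(sets)
  expect_equal(tab$lesion_count, c(1, 0))
  expect_equal(tab$source_id, c("one", "empty"))
})
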
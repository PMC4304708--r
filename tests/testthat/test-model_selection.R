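# Grid search and nested leave-one-volunteer-out tuning.
# Scenes are kept small (96 px) so the full grids run in seconds.

small_cohort <- function(n_vol, seed, n_lesions = 4) {
  generate_cohort(n_vol, 1, high_burden = TRUE, seed = seed,
                  height_px = 96, width_px = 96, n_lesions = n_lesions)
}

test_that("a single-combination grid is returned as-is and equals plain evaluation", {
  coh <- small_cohort(2, seed = 301)
  g <- param_grid(window_px = 9, epsilon = 0.1, disc_radius_px = 14,
                  t_low = 0.003, t_high = 0.008)
  p <- grid_search(coh, g)
  expect_equal(p$window_px, 9L)
  expect_equal(p$disc_radius_px, 14L)
  expect_equal(c(p$t_low, p$t_high), c(0.003, 0.008))
  # nested LOOCV over a size-1 grid equals applying that combination directly
  cv <- nested_loocv(coh, g)
  tp <- 0; nref <- 0; ntest <- 0
  for (s in coh) {
    mask <- detect(s$image, p)
    ref <- s$labels > 0
    tp <- tp + sum(mask & ref); nref <- nref + sum(ref); ntest <- ntest + sum(mask)
  }
  expect_equal(cv$pooled$sensitivity, tp / nref)
  expect_equal(cv$pooled$ppv, tp / ntest)
})

test_that("grid search prefers a working threshold over one above all peaks", {
  coh <- small_cohort(2, seed = 303)
  g <- param_grid(window_px = 9, epsilon = 0.1, disc_radius_px = 14,
                  t_low = 0.003, t_high = c(0.008, 0.5))
  p <- grid_search(coh, g)
  expect_equal(p$t_high, 0.008)
  expect_gt(attr(p, "f2"), 0)
})

test_that("a planted contrast between two candidate t_high values selects the lower", {
  # noiseless disc of erythema contrast 0.05: peaks top out at ~0.05,
  # so t_high = 0.02 detects and t_high = 0.2 cannot
  fx <- flat_disc_image(H = 64, W = 64, radius = 6, contrast = 0.05)
  entry <- list(image = fx$image, reference = fx$mask, volunteer_id = "v1")
  g <- param_grid(window_px = 0, epsilon = 0.1, disc_radius_px = 10,
                  t_low = 0.005, t_high = c(0.02, 0.2))
  p <- grid_search(list(entry), g)
  expect_equal(p$t_high, 0.02)
})

test_that("selected parameters always lie within the grid and ties break deterministically", {
  coh <- small_cohort(2, seed = 305)
  g <- param_grid(window_px = c(0, 9), epsilon = c(0.01, 0.1),
                  disc_radius_px = c(14, 20), t_low = c(0.001, 0.003),
                  t_high = c(0.008, 0.012))
  p1 <- grid_search(coh, g)
  expect_true(p1$window_px %in% c(0L, 9L))
  expect_true(p1$epsilon %in% c(0.01, 0.1))
  expect_true(p1$disc_radius_px %in% c(14L, 20L))
  p2 <- grid_search(coh, g)
  expect_identical(unclass(p1), unclass(p2))
})

test_that("combinations with t_low > t_high are skipped, empty grids rejected", {
  g <- param_grid(window_px = 0, epsilon = 0.1, disc_radius_px = 10,
                  t_low = c(0.001, 0.01), t_high = 0.005)
  fx <- flat_disc_image(H = 48, W = 48)
  entry <- list(image = fx$image, reference = fx$mask, volunteer_id = "v1")
  p <- grid_search(list(entry), g)
  expect_equal(p$t_low, 0.001) # the invalid 0.01/0.005 pair never competes
  g_bad <- param_grid(window_px = 0, epsilon = 0.1, disc_radius_px = 10,
                      t_low = 0.01, t_high = 0.005)
  expect_error(grid_search(list(entry), g_bad), "no valid combination")
})

test_that("LOOCV folds are symmetric for identical volunteers and reject degenerate inputs", {
  fx <- flat_disc_image(H = 64, W = 64, radius = 6, contrast = 0.05)
  mk <- function(v) list(image = fx$image, reference = fx$mask, volunteer_id = v)
  g <- param_grid(window_px = c(0, 5), epsilon = 0.1, disc_radius_px = 10,
                  t_low = 0.005, t_high = 0.02)
  cv <- nested_loocv(list(mk("a"), mk("b")), g)
  expect_equal(nrow(cv$records), 2)
  expect_equal(cv$records$window_px[1], cv$records$window_px[2])
  expect_equal(cv$records$f2[1], cv$records$f2[2])
  expect_error(nested_loocv(list(mk("a")), g), "2 distinct volunteers")
})

test_that("published per-site presets carry the reported parameter values", {
  face <- ak_params("face")
  expect_equal(c(face$window_px, face$epsilon, face$disc_radius_px,
                 face$t_low, face$t_high), c(41, 1, 60, 0.005, 0.007))
  arm <- ak_params("arm")
  expect_equal(c(arm$window_px, arm$epsilon, arm$disc_radius_px,
                 arm$t_low, arm$t_high), c(21, 0.1, 50, 0.003, 0.008))
})

test_that("default grid spans the published search ranges and presets", {
  g <- param_grid()
  expect_true(all(c(0, 21, 41, 61) %in% g$window_px))
  expect_true(all(c(0.01, 0.1, 1) %in% g$epsilon))
  expect_true(all(c(50, 60) %in% g$disc_radius_px))
  expect_true(min(g$t_low) == 0 && max(g$t_low) == 0.008)
  expect_true(min(g$t_high) == 0.001 && max(g$t_high) == 0.012)
})
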
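# Parameter tuning: grid search over the five detector parameters,
# maximizing pooled pixel-level F2, wrapped in leave-one-volunteer-out
# cross-validation.  Stage results are cached per image so a full grid
# costs one erosion/reconstruction per (window, epsilon, disc) rather than
# one per threshold combination.

#' Parameter grid for the detector
#'
#' Defaults span the published search ranges at coarse resolution: windows 0
#' (no smoothing) to 61 px, epsilon 0.01 to 1, disc radius 10 to 70 px,
#' hysteresis thresholds 0 to 0.008 (low) and 0.001 to 0.012 (high),
#' including the per-site values the published tuning selected (window 41
#' and 21, epsilon 1 and 0.1, discs 60 and 50).  Combinations with
#' `t_low > t_high` are skipped, not errors.
#'
#' @param window_px,epsilon,disc_radius_px,t_low,t_high candidate values.
#' @return list of class `param_grid`.
#' @export
param_grid <- function(window_px = c(0L, 21L, 41L, 61L),
                       epsilon = c(0.01, 0.1, 1),
                       disc_radius_px = c(10L, 30L, 50L, 60L, 70L),
                       t_low = seq(0, 0.008, by = 0.002),
                       t_high = c(0.001, 0.004, 0.007, 0.010, 0.012)) {
  g <- list(window_px = unique(as.integer(window_px)),
            epsilon = unique(as.numeric(epsilon)),
            disc_radius_px = unique(as.integer(disc_radius_px)),
            t_low = unique(as.numeric(t_low)),
            t_high = unique(as.numeric(t_high)))
  if (any(vapply(g, length, integer(1)) == 0))
    stop("all grid dimensions must be non-empty")
  if (any(g$window_px < 0) || any(g$window_px > 0 & g$window_px %% 2 == 0))
    stop("window values must be 0 or odd")
  class(g) <- "param_grid"
  g
}

# All valid parameter combinations in the deterministic tie-break order:
# increasing (window, epsilon, disc, t_high, t_low).
.grid_combos <- function(grid) {
  co <- expand.grid(t_low = sort(grid$t_low), t_high = sort(grid$t_high),
                    disc_radius_px = sort(grid$disc_radius_px),
                    epsilon = sort(grid$epsilon),
                    window_px = sort(grid$window_px),
                    KEEP.OUT.ATTRS = FALSE)
  co <- co[co$t_low <= co$t_high, , drop = FALSE]
  if (nrow(co) == 0) stop("grid contains no valid combination (t_low > t_high everywhere)")
  co <- co[order(co$window_px, co$epsilon, co$disc_radius_px,
                 co$t_high, co$t_low), , drop = FALSE]
  rownames(co) <- NULL
  co
}

# Normalize the images argument: a list of scenes (from generate_scene /
# generate_cohort) or of lists with fields image, reference (logical or
# label matrix), volunteer_id.
.as_tuning_set <- function(images) {
  lapply(images, function(e) {
    img <- e$image
    ref <- if (!is.null(e$reference)) e$reference else e$labels
    if (is.null(img) || is.null(ref))
      stop("each entry needs `image` and `reference` (or `labels`)")
    list(image = img, reference = ref > 0,
         volunteer_id = if (!is.null(e$volunteer_id)) e$volunteer_id else "")
  })
}

# Pixel confusion counts (tp, n_ref, n_test) for every valid combination on
# one image, sharing stage computations.  Returns a matrix combo x 3.
.combo_counts_one <- function(entry, combos) {
  e_map <- erythema_intensity(entry$image)
  n_ref <- sum(entry$reference)
  out <- matrix(0, nrow(combos), 3)
  smooth_key <- paste(combos$window_px, combos$epsilon)
  for (sk in unique(smooth_key)) {
    i_s <- which(smooth_key == sk)
    s_map <- guided_filter(e_map, combos$window_px[i_s[1]],
                           combos$epsilon[i_s[1]])
    for (disc in unique(combos$disc_radius_px[i_s])) {
      i_d <- i_s[combos$disc_radius_px[i_s] == disc]
      peaks <- extract_peaks(s_map, disc)
      for (i in i_d) {
        mask <- hysteresis_threshold(peaks, combos$t_low[i], combos$t_high[i])
        out[i, ] <- c(sum(mask & entry$reference), n_ref, sum(mask))
      }
    }
  }
  out
}

.pooled_counts <- function(entries, combos) {
  acc <- matrix(0, nrow(combos), 3)
  for (e in entries) acc <- acc + .combo_counts_one(e, combos)
  acc
}

.f2_from_counts <- function(counts) {
  sens <- ifelse(counts[, 2] > 0, counts[, 1] / counts[, 2], NaN)
  ppv <- ifelse(counts[, 3] > 0, counts[, 1] / counts[, 3], 0)
  f2 <- f2_score(ifelse(is.nan(sens), 0, sens), ppv)
  f2
}

#' Grid search maximizing pooled pixel-level F2
#'
#' Runs the detector at every valid grid combination on every image, pools
#' the pixel confusion counts over all images (robust to images without
#' annotated lesions), and returns the combination with the highest F2.
#' Ties are broken towards the smallest `(window, epsilon, disc, t_high,
#' t_low)` in lexicographic order, so the search is deterministic.
#'
#' @param images list of scenes (as from [generate_scene()] /
#'   [generate_cohort()]) or lists with `image`, `reference` (logical mask
#'   or label matrix) and optional `volunteer_id`.
#' @param grid a [param_grid()].
#' @return the selected [detection_params()], with the achieved pooled F2 in
#'   attribute `"f2"`.
#' @export
grid_search <- function(images, grid) {
  stopifnot(inherits(grid, "param_grid"))
  entries <- .as_tuning_set(images)
  if (length(entries) == 0) stop("no images supplied")
  if (!any(vapply(entries, function(e) any(e$reference), logical(1))))
    stop("at least one image must have a non-empty reference mask")
  combos <- .grid_combos(grid)
  f2 <- .f2_from_counts(.pooled_counts(entries, combos))
  best <- which.max(f2) # first maximum = lexicographic tie-break order
  p <- detection_params(combos$window_px[best], combos$epsilon[best],
                        combos$disc_radius_px[best], combos$t_low[best],
                        combos$t_high[best])
  attr(p, "f2") <- f2[best]
  p
}

#' Nested leave-one-volunteer-out cross-validated tuning
#'
#' The outer loop holds out one volunteer at a time; the inner loop grid
#' searches the remaining volunteers' images for the F2-maximizing
#' parameters, which are then applied to the held-out volunteer's images.
#' Held-out pixel counts are pooled over all folds, so the reported
#' sensitivity/PPV/F2 carry no tuning optimism.
#'
#' @inheritParams grid_search
#' @return list with `records` (data.frame: one row per fold with the
#'   held-out volunteer, selected parameters and held-out metrics),
#'   `pooled` (held-out [pixel_metrics()] over all folds) and
#'   `fold_params` (list of [detection_params()]).
#' @export
nested_loocv <- function(images, grid) {
  stopifnot(inherits(grid, "param_grid"))
  entries <- .as_tuning_set(images)
  vols <- vapply(entries, `[[`, character(1), "volunteer_id")
  uv <- unique(vols)
  if (length(uv) < 2) stop("need at least 2 distinct volunteers")
  records <- NULL
  fold_params <- list()
  pooled <- c(tp = 0, n_ref = 0, n_test = 0)
  for (v in uv) {
    train <- entries[vols != v]
    held <- entries[vols == v]
    if (length(train) == 0)
      stop(sprintf("volunteer %s owns all images: cannot cross-validate", v))
    p <- grid_search(train, grid)
    fold_params[[v]] <- p
    cnt <- c(0, 0, 0)
    for (e in held) {
      mask <- detect(e$image, p)
      cnt <- cnt + c(sum(mask & e$reference), sum(e$reference), sum(mask))
    }
    pooled <- pooled + cnt
    hm <- .pixel_metrics_from_counts(cnt[1], cnt[2], cnt[3])
    records <- rbind(records, data.frame(
      held_out_volunteer = v, window_px = p$window_px, epsilon = p$epsilon,
      disc_radius_px = p$disc_radius_px, t_low = p$t_low, t_high = p$t_high,
      sensitivity = hm$sensitivity, ppv = hm$ppv, f2 = hm$f2
    ))
  }
  list(records = records,
       pooled = .pixel_metrics_from_counts(pooled[1], pooled[2], pooled[3]),
       fold_params = fold_params)
}

#' Published per-site detector presets
#'
#' The parameter sets the original clinical tuning selected: for face
#' photographs a 41 px guided-filter window with epsilon 1, a 60 px
#' reconstruction disc and hysteresis thresholds 0.005/0.007; for arm
#' photographs a 21 px window with epsilon 0.1, a 50 px disc and thresholds
#' 0.003/0.008.
#'
#' @param site `"face"` or `"arm"`.
#' @return a [detection_params()] object.
#' @export
ak_params <- function(site = c("face", "arm")) {
  site <- match.arg(site)
  switch(site,
         face = detection_params(41L, 1, 60L, 0.005, 0.007),
         arm = detection_params(21L, 0.1, 50L, 0.003, 0.008))
}

#' Write cross-validation fold records to CSV
#' @param cv result of [nested_loocv()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(cv, path) {
  write.csv(cv$records, path, row.names = FALSE)
  invisible(path)
}
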
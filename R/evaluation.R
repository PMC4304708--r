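# Evaluation protocol: pixel-level metrics and lesion-level co-localization.

#' Pixel-level sensitivity, PPV and F2 between two masks
#'
#' Sensitivity is the fraction of reference (annotated) pixels also marked by
#' the test mask; PPV the fraction of test pixels also marked by the
#' reference.  F2 is the Fbeta score with beta = 2,
#' `5 * sens * ppv / (4 * ppv + sens)`, weighting sensitivity twice as
#' heavily as PPV.  Conventions for degenerate inputs: sensitivity is `NaN`
#' when the reference is empty, PPV is `NaN` when the test mask is empty,
#' and F2 is 0 when either defined component is 0.
#'
#' @param reference,test logical matrices of identical shape.
#' @return list with `sensitivity`, `ppv`, `f2` (class `pixel_metrics`).
#' @export
pixel_metrics <- function(reference, test) {
  if (!is.matrix(reference) || !is.matrix(test) ||
      !identical(dim(reference), dim(test)))
    stop("`reference` and `test` must be matrices of identical shape")
  reference <- reference > 0; test <- test > 0
  tp <- sum(reference & test)
  .pixel_metrics_from_counts(tp, sum(reference), sum(test))
}

.pixel_metrics_from_counts <- function(tp, n_ref, n_test) {
  tp <- unname(tp); n_ref <- unname(n_ref); n_test <- unname(n_test)
  sens <- if (n_ref > 0) tp / n_ref else NaN
  ppv <- if (n_test > 0) tp / n_test else NaN
  structure(list(sensitivity = sens, ppv = ppv, f2 = f2_score(sens, ppv)),
            class = "pixel_metrics")
}

#' F2 score from sensitivity and PPV
#'
#' @param sensitivity,ppv values in `[0, 1]` (`NaN` propagates).
#' @return `5 * s * p / (4 * p + s)`; 0 when either component is 0.
#' @export
f2_score <- function(sensitivity, ppv) {
  ifelse(is.nan(sensitivity) | is.nan(ppv), NaN,
         ifelse(sensitivity == 0 | ppv == 0, 0,
                5 * sensitivity * ppv / (4 * ppv + sensitivity)))
}

#' @export
print.pixel_metrics <- function(x, ...) {
  cat(sprintf("<pixel_metrics> sensitivity %.4f, PPV %.4f, F2 %.4f\n",
              x$sensitivity, x$ppv, x$f2))
  invisible(x)
}

#' Co-localize two lesion sets by centroid containment
#'
#' A test lesion T is considered co-localized with a reference lesion R if
#' the centroid of one lies within the border of the other, i.e. the
#' centroid of T, rounded to the nearest pixel, belongs to R's pixel set, or
#' vice-versa.  Test lesions are visited in their deterministic (raster)
#' order and each is paired with the first eligible still-unmatched
#' reference lesion; when several test lesions match the same reference
#' lesion only the first counts as a match and the remainder are removed
#' from consideration, so no lesion is double-counted.
#'
#' @param reference,test `lesion_set`s sharing `image_shape`.
#' @return a `match_result`: `pairs` (data.frame `reference_id`, `test_id`),
#'   `unmatched_reference`, `unmatched_test` (id vectors), plus the two set
#'   sizes.
#' @export
colocalize <- function(reference, test) {
  stopifnot(inherits(reference, "lesion_set"), inherits(test, "lesion_set"))
  if (!identical(as.integer(reference$image_shape), as.integer(test$image_shape)))
    stop("lesion sets come from images of different shapes")
  rnd <- function(x) floor(x + 0.5) # round half up: deterministic on raster
  ref_lab <- .lesion_label_matrix(reference)
  test_lab <- .lesion_label_matrix(test)
  H <- reference$image_shape[1]; W <- reference$image_shape[2]
  at <- function(lab, rc) {
    r <- rnd(rc[1]); c <- rnd(rc[2])
    if (r < 0 || r >= H || c < 0 || c >= W) return(0L)
    lab[r + 1L + c * H]
  }
  ref_centroid_in_test <- vapply(reference$lesions, function(l)
    at(test_lab, l$centroid), integer(1)) # test id containing each ref centroid
  matched_ref <- logical(length(reference$lesions))
  pairs_ref <- integer(0); pairs_test <- integer(0)
  unmatched_test <- integer(0)
  for (tl in test$lesions) {
    # eligible references: T's centroid inside R, or R's centroid inside T
    cand <- integer(0)
    rid <- at(ref_lab, tl$centroid)
    if (rid > 0) cand <- rid
    if (length(ref_centroid_in_test) > 0)
      cand <- sort(unique(c(cand, which(ref_centroid_in_test == tl$id))))
    cand <- cand[!matched_ref[cand]]
    if (length(cand) > 0) {
      r <- cand[1]
      matched_ref[r] <- TRUE
      pairs_ref <- c(pairs_ref, r)
      pairs_test <- c(pairs_test, tl$id)
    } else {
      unmatched_test <- c(unmatched_test, tl$id)
    }
  }
  structure(list(
    pairs = data.frame(reference_id = pairs_ref, test_id = pairs_test),
    unmatched_reference = which(!matched_ref),
    unmatched_test = unmatched_test,
    reference_n = length(reference$lesions),
    test_n = length(test$lesions)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched, %d reference-only, %d test-only\n",
              nrow(x$pairs), length(x$unmatched_reference),
              length(x$unmatched_test)))
  invisible(x)
}

#' Confusion counts from a co-localization result
#'
#' @param m a `match_result` from [colocalize()].
#' @return a `confusion_counts` list: `matched`, `reference_only`,
#'   `test_only`.
#' @export
confusion_counts <- function(m) {
  stopifnot(inherits(m, "match_result"))
  structure(list(matched = nrow(m$pairs),
                 reference_only = length(m$unmatched_reference),
                 test_only = length(m$unmatched_test)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  lm <- lesion_metrics(x$matched, x$reference_only, x$test_only)
  cat(sprintf(
    "<confusion_counts> matched %d, reference-only %d, test-only %d (sens %.1f%%, PPV %.1f%%)\n",
    x$matched, x$reference_only, x$test_only,
    100 * lm$sensitivity, 100 * lm$ppv))
  invisible(x)
}

#' Lesion-level sensitivity and PPV from confusion counts
#'
#' Sensitivity = matched / (matched + reference_only); PPV =
#' matched / (matched + test_only).  Vectorized, so a table of confusion
#' counts (e.g. one row per body site and comparison) converts in one call.
#' Zero denominators yield `NaN`.
#'
#' @param matched,reference_only,test_only non-negative counts, or a single
#'   `confusion_counts` object as `matched`.
#' @return list (or data.frame when vectorized) with `sensitivity`, `ppv`.
#' @export
lesion_metrics <- function(matched, reference_only, test_only) {
  if (inherits(matched, "confusion_counts")) {
    cc <- matched
    matched <- cc$matched; reference_only <- cc$reference_only
    test_only <- cc$test_only
  }
  sens <- ifelse(matched + reference_only > 0,
                 matched / (matched + reference_only), NaN)
  ppv <- ifelse(matched + test_only > 0, matched / (matched + test_only), NaN)
  if (length(sens) == 1L) list(sensitivity = sens, ppv = ppv)
  else data.frame(sensitivity = sens, ppv = ppv)
}

#' Per-image lesion counts
#'
#' One row per lesion set, for feeding count-correlation analyses
#' ([pearson()]) and group comparisons ([welch_t_from_samples()]).
#'
#' @param sets list of `lesion_set`s.
#' @return data.frame with columns `source_id`, `lesion_count`.
#' @export
per_image_counts <- function(sets) {
  if (length(sets) == 0)
    return(data.frame(source_id = character(0), lesion_count = integer(0)))
  data.frame(
    source_id = vapply(sets, `[[`, character(1), "source_id"),
    lesion_count = vapply(sets, n_lesions, integer(1))
  )
}

#' Lesion co-localization counts from the original clinical evaluation
#'
#' Confusion counts reported by the clinical study that introduced this
#' detector, comparing (per body site) the automated output and a repeat
#' dermatologist annotation against the dermatologist's first annotation of
#' the same photographs.  `reference` is always dermatologist count 1.
#' These printed counts are inputs for reproducing the study's lesion-level
#' sensitivity/PPV figures without access to the photographs.
#'
#' @return data.frame with columns `site` (face/arm), `test` (automated /
#'   dermatologist2), `matched`, `reference_only`, `test_only`.
#' @export
clinical_reference_counts <- function() {
  data.frame(
    site = c("face", "arm", "face", "arm"),
    test = c("automated", "automated", "dermatologist2", "dermatologist2"),
    matched = c(51L, 296L, 85L, 423L),
    reference_only = c(78L, 261L, 44L, 134L),
    test_only = c(316L, 447L, 71L, 212L)
  )
}

#' Automated per-image lesion count summaries from the clinical evaluation
#'
#' Group means, standard deviations and photograph counts of the automated
#' detector's per-image lesion counts in the high-burden and lesion-free
#' volunteer groups, per body site, as reported by the original clinical
#' evaluation.  Inputs for the Welch group comparison ([welch_t()]).
#'
#' @return data.frame with columns `site`, `group`, `mean`, `sd`, `n`.
#' @export
clinical_group_summaries <- function() {
  data.frame(
    site = c("face", "face", "arm", "arm"),
    group = c("high_ak", "no_ak", "high_ak", "no_ak"),
    mean = c(12.60, 6.33, 42.05, 9.85),
    sd = c(6.18, 2.32, 18.2, 4.11),
    n = c(30L, 30L, 20L, 20L)
  )
}
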
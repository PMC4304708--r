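# End-to-end detector and extraction of discrete lesions from binary masks.

#' Run the full erythema detector on a photograph
#'
#' Composes the pipeline stages: erythema intensity map, guided filtering,
#' top-hat by reconstruction, hysteresis thresholding.  True pixels in the
#' returned mask mark regions likely to be actinic keratosis.
#'
#' @param img an [rgb_image()] or `H x W x 3` array in `[0, 1]`.
#' @param params a [detection_params()] object (see [ak_params()] for the
#'   published face/arm presets).
#' @return logical `H x W` matrix.
#' @examples
#' scn <- generate_scene(scene_spec(n_lesions = 3, seed = 7))
#' mask <- detect(scn$image, detection_params(9, 0.1, 16, 0.003, 0.008))
#' sum(mask) > 0
#' @export
detect <- function(img, params) {
  stopifnot(inherits(params, "detection_params"))
  e <- erythema_intensity(img)
  s <- guided_filter(e, params$window_px, params$epsilon)
  p <- extract_peaks(s, params$disc_radius_px)
  hysteresis_threshold(p, params$t_low, params$t_high)
}

#' Label discrete lesions in a binary mask
#'
#' A lesion is a connected group of true pixels completely surrounded by
#' background (8-connectivity, matching hysteresis).  Lesions are numbered in
#' raster order of each component's top-left-most pixel, which makes the
#' ordering -- and everything downstream that iterates over lesions --
#' deterministic.
#'
#' @param mask logical matrix.
#' @param source_id label identifying the source photograph (carried through
#'   to per-image count tables).
#' @return a `lesion_set`: list with `lesions` (each having `id`, `pixels`
#'   (n x 2 matrix of 0-based row/col), `centroid`, `area_px`),
#'   `image_shape`, `source_id`.
#' @export
label_lesions <- function(mask, source_id = "") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  lab <- .label_components_cpp(mask)
  n <- max(lab)
  lesions <- vector("list", n)
  if (n > 0) {
    idx <- which(lab > 0)
    rows0 <- (idx - 1L) %% nrow(mask)        # 0-based
    cols0 <- (idx - 1L) %/% nrow(mask)
    lvals <- lab[idx]
    ord <- order(lvals, cols0, rows0)        # within lesion: column-major, fine
    rows0 <- rows0[ord]; cols0 <- cols0[ord]; lvals <- lvals[ord]
    starts <- c(1L, which(diff(lvals) != 0L) + 1L)
    ends <- c(starts[-1L] - 1L, length(lvals))
    for (k in seq_len(n)) {
      sel <- starts[k]:ends[k]
      px <- cbind(row = rows0[sel], col = cols0[sel])
      lesions[[k]] <- list(
        id = k,
        pixels = px,
        centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
        area_px = nrow(px)
      )
    }
  }
  structure(list(lesions = lesions, image_shape = dim(mask),
                 source_id = source_id),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> %d lesion(s) in %d x %d image%s\n",
              length(x$lesions), x$image_shape[1], x$image_shape[2],
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Number of lesions in a lesion set
#' @param ls a `lesion_set`.
#' @return integer count.
#' @export
n_lesions <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  length(ls$lesions)
}

# Label matrix (integer, 0 = background) with lesion ids; inverse of
# label_lesions up to the deterministic id ordering.
.lesion_label_matrix <- function(ls) {
  lab <- matrix(0L, ls$image_shape[1], ls$image_shape[2])
  for (l in ls$lesions)
    lab[l$pixels[, 1] + 1L + l$pixels[, 2] * ls$image_shape[1]] <- l$id
  lab
}

#' Lesion set as a per-lesion table
#'
#' @param ls a `lesion_set`.
#' @return data.frame with columns `id`, `centroid_row`, `centroid_col`
#'   (0-based), `area_px`.
#' @export
lesion_table <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  data.frame(
    id = vapply(ls$lesions, `[[`, integer(1), "id"),
    centroid_row = vapply(ls$lesions, function(l) l$centroid[["row"]], numeric(1)),
    centroid_col = vapply(ls$lesions, function(l) l$centroid[["col"]], numeric(1)),
    area_px = vapply(ls$lesions, `[[`, integer(1), "area_px")
  )
}

#' Drop lesions below a clinical minimum diameter
#'
#' Mirrors the clinical criterion of circumscribing only distinct lesions
#' greater than a minimum size: a lesion is kept iff its equivalent-circle
#' diameter `2 sqrt(area / pi) / scale` (in mm) is `>= min_diameter_mm`.
#' The automated pipeline applies no size filter by default
#' (`min_diameter_mm = 0` is the identity).
#'
#' @param ls a `lesion_set`.
#' @param min_diameter_mm minimum equivalent-circle diameter in mm (0 = off).
#' @param scale_px_per_mm image scale in pixels per millimetre.
#' @return a filtered `lesion_set`; ids are reassigned consecutively in the
#'   retained order.
#' @export
filter_min_size <- function(ls, min_diameter_mm, scale_px_per_mm) {
  stopifnot(inherits(ls, "lesion_set"))
  if (!is.finite(min_diameter_mm) || min_diameter_mm < 0)
    stop("`min_diameter_mm` must be non-negative")
  if (!is.finite(scale_px_per_mm) || scale_px_per_mm <= 0)
    stop("`scale_px_per_mm` must be positive")
  if (min_diameter_mm == 0) return(ls)
  keep <- vapply(ls$lesions, function(l) {
    2 * sqrt(l$area_px / pi) / scale_px_per_mm >= min_diameter_mm
  }, logical(1))
  out <- ls
  out$lesions <- ls$lesions[keep]
  for (k in seq_along(out$lesions)) out$lesions[[k]]$id <- k
  out
}

#' Reconstruct the binary mask covered by a lesion set
#' @param ls a `lesion_set`.
#' @return logical matrix; the union of all lesion pixel sets.
#' @export
lesion_mask <- function(ls) {
  .lesion_label_matrix(ls) > 0L
}
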
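# Pixel-level operators of the detection pipeline: colour transform,
# erythema map, guided filtering, top-hat by reconstruction, hysteresis.

#' RGB photograph container
#'
#' Wraps an `H x W x 3` numeric array with channels in `[0, 1]` together with
#' an optional pixel scale.  All pipeline functions also accept a bare array;
#' the constructor exists to validate once and to carry the scale metadata
#' used by [filter_min_size()].
#'
#' @param pixels numeric `H x W x 3` array, all values finite and in `[0, 1]`.
#' @param scale_px_per_mm optional positive scalar, pixels per millimetre
#'   (clinical photographs are typically acquired at 9--11 px/mm).
#' @return an object of class `rgb_image` with elements `pixels` and
#'   `scale_px_per_mm`.
#' @export
rgb_image <- function(pixels, scale_px_per_mm = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image contains non-finite values (NA/NaN/Inf)")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image values must lie in [0, 1]; rescale on load")
  if (!is.null(scale_px_per_mm)) {
    if (!is.numeric(scale_px_per_mm) || length(scale_px_per_mm) != 1L ||
        !is.finite(scale_px_per_mm) || scale_px_per_mm <= 0)
      stop("`scale_px_per_mm` must be a positive number")
  }
  structure(list(pixels = pixels, scale_px_per_mm = scale_px_per_mm),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px%s\n", d[1], d[2],
              if (is.null(x$scale_px_per_mm)) "" else
                sprintf(" @ %g px/mm", x$scale_px_per_mm)))
  invisible(x)
}

.as_pixels <- function(img) {
  if (inherits(img, "rgb_image")) return(img$pixels)
  rgb_image(img)$pixels # validates
}

#' Full-range BT.601 YCbCr transform
#'
#' Converts an RGB photograph to luma and chroma planes using the full-range
#' (JPEG/JFIF) BT.601 matrix on the `[0, 1]` scale:
#' \deqn{Y = 0.299R + 0.587G + 0.114B}
#' \deqn{Cb = 0.5 - 0.168736R - 0.331264G + 0.5B}
#' \deqn{Cr = 0.5 + 0.5R - 0.418688G - 0.081312B}
#' Outputs are clipped to `[0, 1]` (this only matters for inputs that have
#' been through a lossy 8-bit round trip).  An achromatic pixel (r = g = b)
#' maps to Cb = Cr = 0.5 exactly under the full-range convention.
#'
#' The `"studio"` option applies the limited-range (16--235/240) scaling
#' used by some video toolchains instead; the detector itself always runs
#' full-range, but the option makes the convention explicit and testable.
#'
#' @param img an [rgb_image()] or `H x W x 3` array.
#' @param range `"full"` (default, JPEG/JFIF) or `"studio"` (limited range).
#' @return list with numeric matrices `Y`, `Cb`, `Cr`.
#' @export
rgb_to_ycbcr <- function(img, range = c("full", "studio")) {
  range <- match.arg(range)
  px <- .as_pixels(img)
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  H <- dim(px)[1]
  clip01 <- function(m) matrix(pmin(pmax(m, 0), 1), nrow = H)
  if (range == "full") {
    list(
      Y  = clip01(0.299 * r + 0.587 * g + 0.114 * b),
      Cb = clip01(0.5 - 0.168736 * r - 0.331264 * g + 0.5 * b),
      Cr = clip01(0.5 + 0.5 * r - 0.418688 * g - 0.081312 * b)
    )
  } else {
    list(
      Y  = clip01((16 + 65.481 * r + 128.553 * g + 24.966 * b) / 255),
      Cb = clip01((128 - 37.797 * r - 74.203 * g + 112 * b) / 255),
      Cr = clip01((128 + 112 * r - 93.786 * g - 18.214 * b) / 255)
    )
  }
}

#' Erythema intensity map
#'
#' The per-pixel mean of the Cb and Cr chroma channels.  On skin fields,
#' erythematous regions stand out as local maxima of this map; an achromatic
#' image maps to the constant chroma offset 0.5.
#'
#' @inheritParams rgb_to_ycbcr
#' @return numeric `H x W` matrix in `[0, 1]`.
#' @export
erythema_intensity <- function(img) {
  yc <- rgb_to_ycbcr(img)
  (yc$Cb + yc$Cr) / 2
}

# Normalized box mean with window truncation at the borders: the mean over
# the intersection of the (2k+1)^2 window with the image.  Computed with
# summed-area tables, O(HW) regardless of k.
.box_mean <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  if (k <= 0) return(m)
  cs <- rbind(0, matrix(apply(m, 2, cumsum), nrow = H))
  lo <- pmax(seq_len(H) - k, 1L); hi <- pmin(seq_len(H) + k, H)
  rows <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- cbind(0, matrix(t(apply(rows, 1, cumsum)), nrow = H))
  lo2 <- pmax(seq_len(W) - k, 1L); hi2 <- pmin(seq_len(W) + k, W)
  sums <- cs2[, hi2 + 1L, drop = FALSE] - cs2[, lo2, drop = FALSE]
  counts <- outer(hi - lo + 1L, hi2 - lo2 + 1L)
  sums / counts
}

#' Self-guided edge-preserving filter
#'
#' Guided filtering with the input as its own guide.  Within every square
#' window w the output is modelled as a local linear function of the input,
#' `a_w = var_w / (var_w + epsilon)`, `b_w = (1 - a_w) mean_w`, and each
#' pixel averages the coefficients of all windows covering it:
#' `q = mean(a) * I + mean(b)`.  Small `epsilon` preserves edges (windows with
#' variance well above `epsilon` pass through), large `epsilon` approaches a
#' box blur.  Window means are normalized over the truncated window at the
#' image borders, so the filter is exactly shift-equivariant
#' (`gf(I + c) = gf(I) + c`).
#'
#' @param map numeric matrix (typically an erythema intensity map).
#' @param window_px square window edge length in pixels; must be 0 (returns
#'   the input unchanged, i.e. no smoothing) or an odd positive integer.
#' @param epsilon positive texture regularization parameter.
#' @return numeric matrix of the same dimensions.
#' @export
guided_filter <- function(map, window_px, epsilon) {
  map <- .as_map(map)
  if (!is.numeric(window_px) || length(window_px) != 1L || window_px < 0 ||
      window_px != round(window_px))
    stop("`window_px` must be a single non-negative integer")
  if (window_px == 0) return(map)
  if (window_px %% 2 == 0)
    stop("`window_px` must be odd (or 0 for no smoothing): even windows have no centre pixel")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0)
    stop("`epsilon` must be a single positive number")
  k <- (window_px - 1L) / 2L
  mI  <- .box_mean(map, k)
  mII <- .box_mean(map * map, k)
  v <- pmax(mII - mI * mI, 0)       # guard tiny negatives from cancellation
  a <- v / (v + epsilon)
  b <- (1 - a) * mI
  .box_mean(a, k) * map + .box_mean(b, k)
}

.as_map <- function(map) {
  if (is.matrix(map) && is.logical(map)) storage.mode(map) <- "double"
  if (!is.matrix(map) || !is.numeric(map))
    stop("expected a numeric matrix")
  if (!all(is.finite(map))) stop("map contains non-finite values")
  map
}

#' Grayscale opening by reconstruction with a disc
#'
#' Erodes the map with a discrete Euclidean disc
#' (`{(dx, dy): dx^2 + dy^2 <= r^2}`) and then reconstructs the eroded image
#' under the original by geodesic dilation (4-connected, iterated to the
#' fixpoint).  Bright structures too small to contain the disc are levelled
#' to their surroundings while the shape of larger structures is preserved
#' exactly: the result is anti-extensive (`<=` input), increasing and
#' idempotent.
#'
#' @param map numeric matrix.
#' @param disc_radius_px disc radius in pixels, integer `>= 1`; must not
#'   exceed both image dimensions.
#' @return numeric matrix of the same dimensions.
#' @export
open_by_reconstruction <- function(map, disc_radius_px) {
  map <- .as_map(map)
  r <- disc_radius_px
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != round(r))
    stop("`disc_radius_px` must be a single integer >= 1")
  if (r > nrow(map) && r > ncol(map))
    stop(sprintf("disc radius %d exceeds both image dimensions (%d x %d)",
                 as.integer(r), nrow(map), ncol(map)))
  marker <- .erode_disc_cpp(map, as.integer(r))
  .reconstruct_dilate_cpp(marker, map)
}

#' Top-hat by reconstruction: extract small bright peaks
#'
#' The pointwise difference between the map and its opening by
#' reconstruction.  Non-negative everywhere; zero wherever the map carries no
#' structure smaller than the disc.
#'
#' @inheritParams open_by_reconstruction
#' @return numeric non-negative matrix of the same dimensions.
#' @export
extract_peaks <- function(map, disc_radius_px) {
  map <- .as_map(map)
  pmax(map - open_by_reconstruction(map, disc_radius_px), 0)
}

#' Hysteresis thresholding
#'
#' A pixel is retained iff its value is `>= t_low` and it is 8-connected,
#' through pixels `>= t_low`, to at least one pixel `>= t_high`.  Regions
#' whose maximum never reaches `t_high` are discarded entirely; regions that
#' do are kept down to the `t_low` contour, preserving lesion shape.
#' With `t_low == t_high` this reduces to plain thresholding.
#'
#' @param peaks numeric matrix (typically from [extract_peaks()]).
#' @param t_low,t_high thresholds with `0 <= t_low <= t_high`.
#' @return logical matrix of the same dimensions.
#' @export
hysteresis_threshold <- function(peaks, t_low, t_high) {
  peaks <- .as_map(peaks)
  if (!is.numeric(t_low) || !is.numeric(t_high) ||
      length(t_low) != 1L || length(t_high) != 1L ||
      !is.finite(t_low) || !is.finite(t_high) || t_low < 0)
    stop("thresholds must be single finite non-negative numbers")
  if (t_low > t_high)
    stop(sprintf("t_low (%g) must not exceed t_high (%g)", t_low, t_high))
  .hysteresis_cpp(peaks, t_low, t_high)
}

#' Detection pipeline parameters
#'
#' The five tunable parameters of the detector.  `window_px`/`epsilon`
#' control guided-filter smoothing, `disc_radius_px` sets the largest lesion
#' scale retained by the top-hat, and `t_low`/`t_high` are the hysteresis
#' thresholds on the (unit-scaled) peak map.
#'
#' @param window_px guided filter square window edge, 0 (no smoothing) or odd.
#' @param epsilon positive guided filter regularization.
#' @param disc_radius_px structuring disc radius, integer `>= 1`.
#' @param t_low,t_high hysteresis thresholds, `0 <= t_low <= t_high`.
#' @return object of class `detection_params`.
#' @seealso [ak_params()] for the published per-site presets.
#' @export
detection_params <- function(window_px, epsilon, disc_radius_px, t_low, t_high) {
  if (window_px < 0 || window_px != round(window_px) ||
      (window_px > 0 && window_px %% 2 == 0))
    stop("`window_px` must be 0 or an odd positive integer")
  if (!is.finite(epsilon) || epsilon <= 0) stop("`epsilon` must be positive")
  if (disc_radius_px < 1 || disc_radius_px != round(disc_radius_px))
    stop("`disc_radius_px` must be an integer >= 1")
  if (t_low < 0 || t_high <= 0 || t_low > t_high)
    stop("thresholds must satisfy 0 <= t_low <= t_high, t_high > 0")
  structure(list(window_px = as.integer(window_px), epsilon = epsilon,
                 disc_radius_px = as.integer(disc_radius_px),
                 t_low = t_low, t_high = t_high),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "<detection_params> window %d px, epsilon %g, disc %d px, t_low %g, t_high %g\n",
    x$window_px, x$epsilon, x$disc_radius_px, x$t_low, x$t_high))
  invisible(x)
}
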
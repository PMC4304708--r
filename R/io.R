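# File I/O: photographs, annotations (label masks and polygon JSON),
# detection outputs, metrics and YAML run configuration.
#
# Coordinate convention, used everywhere including JSON: 0-based (row, col),
# origin at the top-left pixel.

#' Read a photograph from disk
#'
#' Reads PNG or TIFF (8- or 16-bit; integer samples are normalized to
#' `[0, 1]` by the decoder), drops an alpha channel if present, and rejects
#' grayscale input, which carries no chroma and therefore no erythema
#' signal.  JPEG is not supported by this build; re-encode losslessly to
#' PNG first.
#'
#' @param path file path.
#' @param scale_px_per_mm optional pixel scale to attach.
#' @return an [rgb_image()].
#' @export
read_image <- function(path, scale_px_per_mm = NULL) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop(sprintf(
                     "cannot decode PNG '%s': %s", path, conditionMessage(e)))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop(sprintf(
                      "cannot decode TIFF '%s': %s", path, conditionMessage(e)))),
    jpg = ,
    jpeg = stop(sprintf(
      "JPEG input is not supported ('%s'); re-encode to PNG or TIFF", path)),
    stop(sprintf("unsupported image format '.%s' for '%s'", ext, path))
  )
  if (is.matrix(px) || (length(dim(px)) == 3 && dim(px)[3] == 1))
    stop(sprintf("'%s' is grayscale: an RGB photograph is required", path))
  if (length(dim(px)) == 3 && dim(px)[3] == 4)
    px <- px[, , 1:3, drop = FALSE] # drop alpha
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop(sprintf("'%s' has %s channels; expected RGB", path,
                 paste(dim(px), collapse = "x")))
  rgb_image(px, scale_px_per_mm)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask logical matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read lesion annotations
#'
#' Accepts either a label-mask PNG (0 = background, k = lesion k, stored as
#' gray levels k/255 or k/65535) or a polygon JSON file: a list of
#' polygons, each an array of `[row, col]` vertices (0-based).  Polygons are
#' rasterized with an even-odd fill that includes boundary pixels;
#' overlapping polygons are merged into one lesion with a warning.
#'
#' @param path annotation file (.png or .json).
#' @param image_shape `(H, W)` of the annotated image.
#' @return a `lesion_set`.
#' @export
read_annotation <- function(path, image_shape) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  H <- image_shape[1]; W <- image_shape[2]
  if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3) v <- v[, , 1]
    if (!identical(dim(v), as.integer(image_shape)))
      stop("label mask dimensions do not match the image")
    lab <- round(v * 255)
    if (max(abs(v * 255 - lab)) > 1e-6) lab <- round(v * 65535) # 16-bit labels
    return(.label_matrix_to_lesion_set(lab, basename(path)))
  }
  if (ext == "json") {
    polys <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    mask <- matrix(FALSE, H, W)
    overlap <- FALSE
    for (p in polys) {
      p <- matrix(as.numeric(unlist(p)), ncol = 2, byrow = TRUE)
      if (any(p[, 1] < 0) || any(p[, 1] > H - 1) ||
          any(p[, 2] < 0) || any(p[, 2] > W - 1))
        stop("polygon vertex outside image bounds")
      m <- rasterize_polygon(p, image_shape)
      if (any(m & mask)) overlap <- TRUE
      mask <- mask | m
    }
    if (overlap) warning("overlapping polygons merged into single lesions")
    return(label_lesions(mask, source_id = basename(path)))
  }
  stop(sprintf("unsupported annotation format '.%s'", ext))
}

.label_matrix_to_lesion_set <- function(lab, source_id = "") {
  vals <- sort(setdiff(unique(as.vector(lab)), 0))
  H <- nrow(lab)
  lesions <- vector("list", length(vals))
  for (k in seq_along(vals)) {
    idx <- which(lab == vals[k])
    px <- cbind(row = (idx - 1L) %% H, col = (idx - 1L) %/% H)
    lesions[[k]] <- list(id = k, pixels = px,
                         centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
                         area_px = nrow(px))
  }
  structure(list(lesions = lesions, image_shape = dim(lab),
                 source_id = source_id), class = "lesion_set")
}

#' Rasterize one polygon to a boundary-inclusive binary mask
#'
#' Even-odd (crossing-number) fill over pixel centres, with pixels lying
#' exactly on a polygon edge always included.  Degenerate polygons (single
#' vertex, segment) rasterize to the pixels on them.
#'
#' @param vertices `n x 2` matrix of `(row, col)` vertices, 0-based.
#' @param image_shape `(H, W)`.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(vertices, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  mask <- matrix(FALSE, H, W)
  v <- matrix(as.numeric(vertices), ncol = 2)
  n <- nrow(v)
  r0 <- max(0L, floor(min(v[, 1]))); r1 <- min(H - 1L, ceiling(max(v[, 1])))
  c0 <- max(0L, floor(min(v[, 2]))); c1 <- min(W - 1L, ceiling(max(v[, 2])))
  if (r1 < r0 || c1 < c0) return(mask)
  eps <- 1e-9
  for (r in r0:r1) {
    for (cc in c0:c1) {
      inside <- FALSE
      on_edge <- FALSE
      for (i in seq_len(n)) {
        a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
        # on-segment test
        d <- b - a; pr <- c(r, cc) - a
        cross <- d[1] * pr[2] - d[2] * pr[1]
        len2 <- sum(d * d)
        if (abs(cross) < 1e-7 * max(1, sqrt(len2))) {
          tpar <- if (len2 > 0) sum(pr * d) / len2 else 0
          if (len2 == 0) {
            if (all(abs(pr) < 1e-7)) { on_edge <- TRUE; break }
          } else if (tpar >= -eps && tpar <= 1 + eps) {
            proj <- a + tpar * d
            if (max(abs(proj - c(r, cc))) < 1e-7) { on_edge <- TRUE; break }
          }
        }
        # crossing-number ray cast along +col at this row
        if ((a[1] > r + eps) != (b[1] > r + eps)) {
          xint <- a[2] + (r - a[1]) / (b[1] - a[1]) * (b[2] - a[2])
          if (xint > cc) inside <- !inside
        }
      }
      if (inside || on_edge) mask[r + 1L, cc + 1L] <- TRUE
    }
  }
  mask
}

#' Trace lesion boundaries as polygons
#'
#' Returns, per lesion, the closed outer boundary as an ordered list of
#' boundary pixel coordinates (Moore neighbourhood tracing, clockwise in
#' (row, col) raster orientation).  Rasterizing these polygons with
#' [rasterize_polygon()] reproduces the original pixel set exactly for
#' solid axis-aligned shapes.
#'
#' @param ls a `lesion_set`.
#' @return list of `n x 2` matrices of `(row, col)` vertices, 0-based.
#' @export
lesion_polygons <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  lab <- .lesion_label_matrix(ls)
  lapply(ls$lesions, function(l) .trace_boundary(lab == l$id))
}

# Moore-neighbour boundary tracing (clockwise, terminates on returning to
# the start pixel).  The start is the component's top-left-most pixel, whose
# west neighbour is guaranteed empty.
.trace_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  idx <- which(m)
  rows <- (idx - 1L) %% H; cols <- (idx - 1L) %/% H
  o <- order(rows, cols)
  s <- c(rows[o[1]], cols[o[1]])
  if (length(idx) == 1L) return(cbind(s[1], s[2]))
  # clockwise ring starting west (row axis points down)
  ring <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  ring_idx <- function(d) which(ring[, 1] == d[1] & ring[, 2] == d[2])
  filled <- function(p) p[1] >= 0 && p[1] < H && p[2] >= 0 && p[2] < W &&
    m[p[1] + 1L, p[2] + 1L]
  boundary <- list(s)
  p <- s
  b <- s + c(0, -1)                     # came "from the west"
  k <- ring_idx(b - p)
  cc <- p + ring[(k %% 8L) + 1L, ]
  steps <- 0L
  while (!(cc[1] == s[1] && cc[2] == s[2])) {
    if (filled(cc)) {
      boundary[[length(boundary) + 1L]] <- cc
      b <- p; p <- cc
    } else {
      b <- cc
    }
    k <- ring_idx(b - p)
    cc <- p + ring[(k %% 8L) + 1L, ]
    steps <- steps + 1L
    if (steps > 8L * H * W) stop("boundary tracing failed to close")
  }
  unname(do.call(rbind, boundary))
}

#' Write a lesion set as CSV
#'
#' Columns `id`, `centroid_row`, `centroid_col`, `area_px` (coordinates
#' 0-based).
#' @param ls a `lesion_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lesions_csv <- function(ls, path) {
  write.csv(lesion_table(ls), path, row.names = FALSE)
  invisible(path)
}

#' Write lesion boundaries as polygon JSON
#' @param ls a `lesion_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polygons_json <- function(ls, path) {
  polys <- lapply(lesion_polygons(ls), function(p) unname(as.matrix(p)))
  jsonlite::write_json(polys, path, digits = NA)
  invisible(path)
}

#' Write detector parameters to a YAML config
#' @param params a [detection_params()].
#' @param path output file.
#' @param site optional site label stored alongside.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path, site = "custom") {
  stopifnot(inherits(params, "detection_params"))
  yaml::write_yaml(list(schema = "akdetect/params/v1", site = site,
                        params = unclass(params)), path)
  invisible(path)
}

#' Read detector parameters from a YAML config
#'
#' Unknown top-level keys produce a warning, not an error.
#' @param path YAML file written by [write_params_yaml()].
#' @return a [detection_params()].
#' @export
read_params_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("schema", "site", "params")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    warning(sprintf("ignoring unknown config keys: %s",
                    paste(extra, collapse = ", ")))
  p <- cfg$params
  detection_params(p$window_px, p$epsilon, p$disc_radius_px, p$t_low, p$t_high)
}
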
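# Brute-force reference implementations used as independent oracles.
# All deliberately favour clarity over speed and share no code with the
# package internals.

# Guided filter: explicit per-window linear coefficients, truncated windows.
oracle_guided_filter <- function(m, window_px, epsilon) {
  if (window_px == 0) return(m)
  k <- (window_px - 1) / 2
  H <- nrow(m); W <- ncol(m)
  asum <- matrix(0, H, W); bsum <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    ri <- max(1, i - k):min(H, i + k)
    rj <- max(1, j - k):min(W, j + k)
    win <- m[ri, rj]
    mu <- mean(win)
    va <- mean(win^2) - mu^2
    a <- va / (va + epsilon)
    b <- (1 - a) * mu
    asum[ri, rj] <- asum[ri, rj] + a
    bsum[ri, rj] <- bsum[ri, rj] + b
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  (asum / cnt) * m + bsum / cnt
}

# Erosion by the discrete disc, out-of-bounds treated as +Inf.
oracle_erode_disc <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(Inf, H, W)
  for (i in 1:H) for (j in 1:W) {
    v <- Inf
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 <= r^2) {
        ii <- i + dy; jj <- j + dx
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) v <- min(v, m[ii, jj])
      }
    }
    out[i, j] <- v
  }
  out
}

# Geodesic reconstruction by dilation to the fixpoint: dilate the marker
# with a 3x3 cross, clamp under the mask, repeat until stable.
oracle_reconstruct <- function(marker, mask) {
  H <- nrow(marker); W <- ncol(marker)
  J <- marker
  repeat {
    up <- rbind(-Inf, J[-H, , drop = FALSE])
    dn <- rbind(J[-1, , drop = FALSE], -Inf)
    lf <- cbind(-Inf, J[, -W, drop = FALSE])
    rt <- cbind(J[, -1, drop = FALSE], -Inf)
    Jn <- pmin(pmax(J, up, dn, lf, rt), mask)
    if (identical(Jn, J)) return(J)
    J <- Jn
  }
}

oracle_open_by_reconstruction <- function(m, r) {
  oracle_reconstruct(oracle_erode_disc(m, r), m)
}

# Hysteresis: flood fill seeded at >= t_high pixels, grown over >= t_low
# pixels (8-connectivity), by repeated shift-or until stable.
oracle_hysteresis <- function(m, t_low, t_high) {
  H <- nrow(m); W <- ncol(m)
  keep <- m >= t_low
  out <- m >= t_high
  repeat {
    grow <- out
    for (dy in -1:1) for (dx in -1:1) {
      sh <- matrix(FALSE, H, W)
      ri <- max(1, 1 + dy):min(H, H + dy)
      rj <- max(1, 1 + dx):min(W, W + dx)
      sh[ri, rj] <- out[ri - dy, rj - dx]
      grow <- grow | (sh & keep)
    }
    if (identical(grow, out)) return(out)
    out <- grow
  }
}

# 8-connected labelling by BFS flood fill, labels in raster order.
oracle_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (i in 1:H) for (j in 1:W) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dy in -1:1) for (dx in -1:1) {
          ii <- p[1] + dy; jj <- p[2] + dx
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Flat synthetic image with one centred erythematous disc of the given
# radius and erythema-map contrast; returns image plus the exact disc mask.
flat_disc_image <- function(H = 48, W = 48, radius = 6, contrast = 0.05,
                            base = c(0.8, 0.62, 0.55)) {
  img <- array(rep(base, each = H * W), dim = c(H, W, 3))
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  d <- sqrt(outer((0:(H - 1) - cy)^2, (0:(W - 1) - cx)^2, "+"))
  disc <- d <= radius
  x <- contrast / 0.540608 # erythema-map rise per unit of the +R/-G shift
  img[, , 1][disc] <- img[, , 1][disc] + x
  img[, , 2][disc] <- img[, , 2][disc] - x
  list(image = img, mask = disc)
}

# A lesion_set with one rectangular lesion, built through the public API.
rect_lesion_set <- function(H, W, r0, r1, c0, c1) {
  m <- matrix(FALSE, H, W)
  m[(r0:r1) + 1, (c0:c1) + 1] <- TRUE
  label_lesions(m)
}
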
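# Small image helpers shared by the pipeline and the scene generator.
# Images are plain numeric matrices indexed [row = y, col = x].

# Reflective padding by k pixels on every side (k < min(dim)).
pad_reflect <- function(image, k) {
  nr <- nrow(image)
  nc <- ncol(image)
  k <- min(k, nr - 1L, nc - 1L)
  ri <- c(seq(k + 1L, 2L), seq_len(nr), seq(nr - 1L, nr - k))
  ci <- c(seq(k + 1L, 2L), seq_len(nc), seq(nc - 1L, nc - k))
  image[ri, ci, drop = FALSE]
}

crop_center <- function(image, k, nr, nc) {
  image[(k + 1L):(k + nr), (k + 1L):(k + nc), drop = FALSE]
}

# Block minimum with block side s (edge blocks replicate the last row/col).
block_min <- function(image, s) {
  nr <- nrow(image)
  nc <- ncol(image)
  nrp <- ceiling(nr / s) * s
  ncp <- ceiling(nc / s) * s
  ri <- c(seq_len(nr), rep(nr, nrp - nr))
  ci <- c(seq_len(nc), rep(nc, ncp - nc))
  p <- image[ri, ci, drop = FALSE]
  out <- NULL
  for (a in seq_len(s)) {
    for (b in seq_len(s)) {
      sub <- p[seq(a, nrp, by = s), seq(b, ncp, by = s), drop = FALSE]
      out <- if (is.null(out)) sub else pmin(out, sub)
    }
  }
  out
}

# Bilinear enlargement of a block-reduced image back to (nr, nc), treating
# reduced samples as block centres.
enlarge_bilinear <- function(small, nr, nc, s) {
  map_axis <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) / s + 0.5
    pmin(pmax(x, 1), n_in)
  }
  rx <- map_axis(nr, nrow(small))
  cx <- map_axis(nc, ncol(small))
  r0 <- pmin(floor(rx), nrow(small) - 1L)
  r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cx), ncol(small) - 1L)
  c0 <- pmax(c0, 1L)
  fr <- rx - r0
  fc <- cx - c0
  a <- small[r0, c0, drop = FALSE]
  b <- small[r0 + 1L, c0, drop = FALSE]
  cc <- small[r0, c0 + 1L, drop = FALSE]
  d <- small[r0 + 1L, c0 + 1L, drop = FALSE]
  fr_m <- matrix(fr, nr, nc)
  fc_m <- matrix(fc, nr, nc, byrow = TRUE)
  a * (1 - fr_m) * (1 - fc_m) + b * fr_m * (1 - fc_m) +
    cc * (1 - fr_m) * fc_m + d * fr_m * fc_m
}

# Rasterized disc structuring element (dx^2 + dy^2 <= r^2) as a 0/1 matrix.
disc_kernel <- function(radius_px) {
  r <- max(0L, floor(radius_px))
  d <- seq(-r, r)
  g <- outer(d^2, d^2, "+")
  (g <= radius_px^2) * 1
}

# Mirror (reflect-without-edge-repeat) index lookup for out-of-range indices.
mirror_index <- function(x, n) {
  if (n == 1L) return(rep(1L, length(x)))
  p <- 2L * n - 2L
  y <- ((x - 1L) %% p + p) %% p
  as.integer(ifelse(y < n, y + 1L, 2L * n - 1L - y))
}

# Separable Gaussian blur with mirrored boundary handling. Direct (non-FFT)
# convolution, so a constant image stays exactly constant.
gaussian_blur_reflect <- function(image, sigma_px) {
  if (sigma_px <= 0) return(image)
  nr <- nrow(image)
  nc <- ncol(image)
  rad <- ceiling(3 * sigma_px)
  w <- stats::dnorm(seq(-rad, rad), sd = sigma_px)
  w <- w / sum(w)
  ri <- mirror_index(seq(1L - rad, nr + rad), nr)
  pr <- image[ri, , drop = FALSE]
  accr <- matrix(0, nr, nc)
  for (k in seq_along(w)) {
    accr <- accr + w[k] * pr[k:(k + nr - 1L), , drop = FALSE]
  }
  ci <- mirror_index(seq(1L - rad, nc + rad), nc)
  pc <- accr[, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(w)) {
    out <- out + w[k] * pc[, k:(k + nc - 1L), drop = FALSE]
  }
  out
}

# Bounding-box crops of every label: list of (mask, i0, j0) per label id.
label_crops <- function(labels, pad = 2L) {
  n <- max(labels)
  if (n == 0) return(list())
  pos <- which(labels > 0)
  ids <- labels[pos]
  i <- (pos - 1L) %% nrow(labels) + 1L
  j <- (pos - 1L) %/% nrow(labels) + 1L
  purrr::map(split(seq_along(pos), factor(ids, levels = seq_len(n))),
             function(sel) {
    ii <- i[sel]
    jj <- j[sel]
    r0 <- max(1L, min(ii) - pad)
    c0 <- max(1L, min(jj) - pad)
    r1 <- min(nrow(labels), max(ii) + pad)
    c1 <- min(ncol(labels), max(jj) + pad)
    mask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    mask[cbind(ii - r0 + 1L, jj - c0 + 1L)] <- TRUE
    list(mask = mask, i0 = r0, j0 = c0,
         centroid_y_px = mean(ii) - 1, centroid_x_px = mean(jj) - 1)
  })
}

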
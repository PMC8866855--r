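# Independent oracles, deliberately brute-force.

# Grayscale opening with a ball structuring element by exhaustive
# min/max over the offset list, and the background subtraction built on it.
oracle_ball_subtract <- function(img, r) {
  d <- seq(-floor(r), floor(r))
  g <- expand.grid(dy = d, dx = d)
  g <- g[g$dy^2 + g$dx^2 <= r^2, ]
  h <- sqrt(r^2 - g$dy^2 - g$dx^2)
  nr <- nrow(img)
  nc <- ncol(img)
  er <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- Inf
      for (t in seq_len(nrow(g))) {
        ii <- i + g$dy[t]
        jj <- j + g$dx[t]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          v <- min(v, img[ii, jj] - h[t])
        }
      }
      er[i, j] <- v
    }
  }
  op <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- -Inf
      for (t in seq_len(nrow(g))) {
        ii <- i - g$dy[t]
        jj <- j - g$dx[t]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          v <- max(v, er[ii, jj] + h[t])
        }
      }
      op[i, j] <- v
    }
  }
  pmax(img - op, 0)
}

# Connected components by breadth-first flood fill.
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          ii <- p[1] + nb[k, 1]
          jj <- p[2] + nb[k, 2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# All non-empty 8-connected subsets of a 3 x 4 pixel window (<= 12 pixels).
oracle_connected_masks_3x4 <- function() {
  out <- list()
  for (code in 1:4095) {
    bits <- as.logical(bitwAnd(code, 2^(0:11)))
    m <- matrix(bits, 3, 4)
    if (max(oracle_components(m, 8)) == 1) out[[length(out) + 1]] <- m
  }
  out
}
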
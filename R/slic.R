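## Simple linear iterative clustering (SLIC) superpixels: localized k-means
## in a joint color + position space. Centers start on a regular grid with
## spacing S = sqrt(HW/k); each center only competes for pixels within a
## 2S x 2S window, and the distance is
## D^2 = dc^2 + (ds/S)^2 * m^2 with color measured on [0,1] RGB scaled by
## 100 (Lab-like magnitudes) and m the compactness.

#' SLIC superpixel labels of an image
#'
#' @param image grayscale matrix or RGB array in \[0, 255\].
#' @param n_segments requested number of superpixels (>= 2 and at most the
#'   pixel count).
#' @param compactness spatial regularization weight m (default 10).
#' @param iterations assignment/update sweeps (default 10).
#' @return integer H x W matrix of superpixel labels (1-based; at most
#'   `n_segments` distinct labels).
#' @export
slic_superpixels <- function(image, n_segments = 200, compactness = 10,
                             iterations = 10) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  h <- dim(image)[1]; w <- dim(image)[2]
  if (n_segments < 2) stop("n_segments must be at least 2")
  if (n_segments > h * w) stop("n_segments exceeds the pixel count")
  col <- image / 255 * 100
  S <- sqrt(h * w / n_segments)
  gr <- max(1L, round(h / S)); gc <- max(1L, round(w / S))
  cr <- (seq_len(gr) - 0.5) * h / gr
  cc <- (seq_len(gc) - 0.5) * w / gc
  centers <- cbind(rep(cr, times = gc), rep(cc, each = gr))
  k <- nrow(centers)
  ccol <- matrix(0, k, 3)
  for (i in seq_len(k))
    ccol[i, ] <- col[round(centers[i, 1]), round(centers[i, 2]), ]
  labels <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  m2s2 <- (compactness / S)^2
  for (it in seq_len(iterations)) {
    best[] <- Inf
    for (i in seq_len(k)) {
      r0 <- max(1L, floor(centers[i, 1] - S)); r1 <- min(h, ceiling(centers[i, 1] + S))
      c0 <- max(1L, floor(centers[i, 2] - S)); c1 <- min(w, ceiling(centers[i, 2] + S))
      rr <- r0:r1; cc2 <- c0:c1
      dr <- (rr - centers[i, 1])^2
      dc <- (cc2 - centers[i, 2])^2
      ds2 <- outer(dr, dc, "+")
      dcol <- (col[rr, cc2, 1] - ccol[i, 1])^2 +
        (col[rr, cc2, 2] - ccol[i, 2])^2 +
        (col[rr, cc2, 3] - ccol[i, 3])^2
      d <- dcol + ds2 * m2s2
      sub <- best[rr, cc2]
      upd <- d < sub
      sub[upd] <- d[upd]
      best[rr, cc2] <- sub
      lab <- labels[rr, cc2]
      lab[upd] <- i
      labels[rr, cc2] <- lab
    }
    # orphans can occur if windows miss a pixel after center drift
    if (any(labels == 0L)) {
      miss <- which(labels == 0L, arr.ind = TRUE)
      for (j in seq_len(nrow(miss))) {
        d <- (centers[, 1] - miss[j, 1])^2 + (centers[, 2] - miss[j, 2])^2
        labels[miss[j, 1], miss[j, 2]] <- which.min(d)
      }
    }
    if (it == iterations) break
    rr_idx <- matrix(seq_len(h), h, w)
    cc_idx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(k)) {
      inl <- labels == i
      n <- sum(inl)
      if (n == 0) next
      centers[i, ] <- c(mean(rr_idx[inl]), mean(cc_idx[inl]))
      ccol[i, ] <- c(mean(col[, , 1][inl]), mean(col[, , 2][inl]),
                     mean(col[, , 3][inl]))
    }
  }
  labels
}
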
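## Correlation-based fusion of two optimized feature streams: pad the
## shorter stream to the longer one's width (entropy or zero padding),
## Pearson-correlate positionally paired columns, and retain both members
## of every pair whose correlation reaches the threshold.

#' Fusion configuration
#'
#' @param correlation_threshold retain pairs with correlation at or above
#'   this value in \[0, 1\] (default 0.5 — a permissive reading of
#'   "near 1"; tests pass explicit thresholds).
#' @param padding_mode `"entropy"` (each padded column holds, per sample,
#'   the normalized Shannon entropy of that sample's original feature row)
#'   or `"zero"`.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(correlation_threshold = 0.5,
                          padding_mode = c("entropy", "zero")) {
  padding_mode <- match.arg(padding_mode)
  if (correlation_threshold < 0 || correlation_threshold > 1)
    stop("correlation_threshold must be in [0, 1]")
  structure(list(correlation_threshold = correlation_threshold,
                 padding_mode = padding_mode), class = "fusion_config")
}

## per-sample entropy of a feature row: 10-bin histogram over the row's
## own range, natural log normalized by log 10
row_entropies <- function(x) {
  apply(x, 1L, binned_entropy, bins = 10L)
}

#' Pad the shorter of two feature matrices to the longer one's width
#'
#' In entropy mode every padded column of a sample holds that sample's
#' row entropy (a constant per sample); in zero mode the padding is zero.
#' Original columns are unchanged.
#'
#' @param v1,v2 feature matrices with equal row counts.
#' @param mode `"entropy"` or `"zero"`.
#' @return list with padded `v1` and `v2`.
#' @export
pad_to_max_length <- function(v1, v2, mode = c("entropy", "zero")) {
  mode <- match.arg(mode)
  if (nrow(v1) != nrow(v2)) stop("sample counts differ between streams")
  d1 <- ncol(v1); d2 <- ncol(v2)
  if (d1 == d2) return(list(v1 = v1, v2 = v2))
  pad <- function(x, d_target) {
    extra <- d_target - ncol(x)
    block <- if (mode == "zero") matrix(0, nrow(x), extra)
    else matrix(row_entropies(x), nrow(x), extra)
    colnames(block) <- sprintf("pad%d", seq_len(extra))
    cbind(x, block)
  }
  if (d1 < d2) list(v1 = pad(v1, d2), v2 = v2)
  else list(v1 = v1, v2 = pad(v2, d1))
}

#' Pearson correlation of two feature columns
#'
#' `Cov(x, y) / sqrt(Var(x) Var(y))`; defined as 0 when either column has
#' zero variance.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
pairwise_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) return(0)
  stats::cov(x, y) / sqrt(vx * vy)
}

#' Fuse two feature streams by maximal pairwise correlation
#'
#' After padding to equal width d, column i of stream 1 is paired with
#' column i of stream 2 and their Pearson correlation computed. Every pair
#' whose correlation reaches the threshold contributes BOTH of its columns
#' to the fused matrix (stream-1 column then stream-2 column), pairs
#' ordered by descending correlation with ties to the lower index, so the
#' fused width `k3` is twice the number of retained pairs.
#'
#' @param v1,v2 feature matrices with equal row counts (selected streams).
#' @param cfg a [fusion_config()].
#' @return object of class `fused_features`: `values` (N x k3),
#'   `source_pairs` (data.frame `i`, `j`, `rho`), `k3`.
#' @export
fuse_features <- function(v1, v2, cfg = fusion_config()) {
  stopifnot(inherits(cfg, "fusion_config"))
  p <- pad_to_max_length(v1, v2, mode = cfg$padding_mode)
  if (ncol(p$v1) != ncol(p$v2)) stop("width mismatch after padding")
  d <- ncol(p$v1)
  rho <- vapply(seq_len(d), function(i)
    pairwise_correlation(p$v1[, i], p$v2[, i]), numeric(1))
  keep <- which(rho >= cfg$correlation_threshold)
  if (length(keep) == 0) {
    warning("empty fusion: no pair reaches the correlation threshold")
    return(structure(list(values = matrix(0, nrow(v1), 0),
                          source_pairs = data.frame(i = integer(0),
                                                    j = integer(0),
                                                    rho = numeric(0)),
                          k3 = 0L), class = "fused_features"))
  }
  keep <- keep[order(-rho[keep], keep)]
  cols <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    cols[[k]] <- cbind(p$v1[, i], p$v2[, i])
  }
  values <- do.call(cbind, cols)
  colnames(values) <- as.vector(rbind(sprintf("s1_%d", keep),
                                      sprintf("s2_%d", keep)))
  structure(list(values = values,
                 source_pairs = data.frame(i = keep, j = keep,
                                           rho = rho[keep]),
                 k3 = ncol(values)), class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat(sprintf("Fused features: %d retained pairs -> k3 = %d columns\n",
              nrow(x$source_pairs), x$k3))
  invisible(x)
}
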
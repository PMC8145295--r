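#' @keywords internal
"_PACKAGE"

## Shared low-level helpers: 8-bit image conventions, Otsu statistics, RNG
## scoping. Grayscale images are numeric H x W matrices in [0, 255]; RGB
## images are H x W x 3 arrays in [0, 255]; binary masks are 0/1 matrices.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their spec seed without disturbing the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Convert an image to 8-bit luminance
#'
#' RGB inputs are reduced with the Rec. 601 luminance weights
#' (0.299, 0.587, 0.114); grayscale inputs are passed through. Values are
#' rounded to integers in \[0, 255\].
#' @param image matrix (gray) or H x W x 3 array (RGB), values in \[0, 255\].
#' @return numeric matrix in \[0, 255\].
#' @export
as_gray <- function(image) {
  if (is.matrix(image)) return(round(clip255(image)))
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  round(clip255(g))
}

## Between-class variance of a 256-level histogram split at threshold t
## (class 0: levels <= t). Vectorized over all candidate thresholds.
otsu_scan <- function(counts) {
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)
  mu_t <- cumsum(p * levels)
  mu_total <- mu_t[256]
  w1 <- 1 - w0
  # guard 0/0 at degenerate splits
  num <- (mu_total * w0 - mu_t)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, 0)
  bcv  # bcv[t+1] is the between-class variance for threshold t
}

#' Otsu threshold of a grayscale image or histogram
#'
#' Maximizes the between-class variance over all 256 split points; ties go
#' to the lowest threshold.
#' @param x grayscale matrix in \[0, 255\] or a 256-bin count vector.
#' @return list with `threshold` (gray level) and `bcv` (the maximized
#'   between-class variance).
#' @export
otsu_threshold <- function(x) {
  counts <- if (is.matrix(x)) tabulate(as.integer(x) + 1L, nbins = 256L) else x
  stopifnot(length(counts) == 256L, sum(counts) > 0)
  bcv <- otsu_scan(counts)
  t <- which.max(bcv) - 1L
  list(threshold = t, bcv = bcv[t + 1L])
}

## Maximum achievable between-class variance for an image (Otsu objective),
## used as a contrast separability score.
otsu_separability <- function(image) {
  otsu_threshold(as_gray(image))$bcv
}

## normalize a vector/matrix to [0,1]; constant input maps to all zeros
minmax01 <- function(x) {
  r <- range(x)
  if (!is.finite(r[1]) || !is.finite(r[2])) stop("non-finite values")
  if (r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

## Shannon entropy of a 10-bin histogram of values, natural log, normalized
## by log(10) so the result lies in [0, 1]. `values` are binned over
## `range_` (defaults to their own range; constant input has entropy 0).
binned_entropy <- function(values, bins = 10L, range_ = NULL) {
  if (is.null(range_)) range_ <- range(values)
  if (range_[2] - range_[1] <= 0) return(0)
  br <- seq(range_[1], range_[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(values, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p)) / log(bins)
}

## coerce lesion-mask representations (list(values=..) or plain matrix)
mask_values <- function(mask) {
  if (is.list(mask)) mask$values else mask
}

stop_if_empty_image <- function(image) {
  if (length(image) == 0L) stop("empty image")
}
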
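## Hybrid local contrast stretching for dermoscopy images: locate the dark
## lesion band on the histogram, weight it by the image variance, equalize
## inside the band, blend with the original, then two sequential gain-search
## passes that maximize Otsu separability.

#' Compute the 256-level histogram of a grayscale image
#'
#' Color inputs are converted to luminance first.
#' @param image grayscale matrix or RGB array in \[0, 255\].
#' @return list of class `gray_histogram` with `counts` (length-256 integer
#'   vector, `counts[j+1]` = pixels at level `j`) and `K = 256`.
#' @export
compute_histogram <- function(image) {
  stop_if_empty_image(image)
  g <- as_gray(image)
  counts <- tabulate(as.integer(g) + 1L, nbins = 256L)
  structure(list(counts = counts, K = 256L), class = "gray_histogram")
}

#' Locate the lesion gray-level band
#'
#' Lesions are the darker mode in dermoscopy, so the band is the contiguous
#' low-intensity range `[k1, kn]` with `k1` the lowest occupied level and
#' `kn` the Otsu split of the histogram. Constant or effectively unimodal
#' images (zero between-class variance) return the full occupied range with
#' `degenerate = TRUE`.
#'
#' @param hist a [compute_histogram()] result.
#' @param image the image the histogram came from (for the patch mask).
#' @return list of class `lesion_range` with `k1`, `kn`, `patch_mask`
#'   (0/1 matrix of pixels whose level lies in the band) and `degenerate`.
#' @export
locate_lesion_range <- function(hist, image) {
  stopifnot(inherits(hist, "gray_histogram"), sum(hist$counts) > 0)
  g <- as_gray(image)
  occupied <- which(hist$counts > 0) - 1L
  ot <- otsu_threshold(hist$counts)
  degenerate <- length(occupied) < 2L || ot$bcv <= 0
  if (degenerate) {
    k1 <- min(occupied); kn <- max(occupied)
  } else {
    k1 <- min(occupied); kn <- ot$threshold
  }
  pm <- (g >= k1 & g <= kn) * 1
  structure(list(k1 = k1, kn = kn, patch_mask = pm, degenerate = degenerate),
            class = "lesion_range")
}

#' Population mean and variance of a grayscale image
#'
#' @param image grayscale matrix or RGB array in \[0, 255\].
#' @return list with `sigma2` (population variance, second raw moment minus
#'   squared mean) and `mu`.
#' @export
image_variance <- function(image) {
  stop_if_empty_image(image)
  g <- as_gray(image)
  mu <- mean(g)
  list(sigma2 = mean(g^2) - mu^2, mu = mu)
}

## textbook CDF-mapping histogram equalization restricted to the pixels
## where mask == 1; single-level patches are left unchanged
equalize_in_patch <- function(image, mask) {
  v <- image[mask == 1]
  if (length(v) == 0) return(image)
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(v)
  if (n == cdf_min) return(image)  # one occupied level: degenerate
  map <- round((cdf - cdf_min) / (n - cdf_min) * 255)
  out <- image
  out[mask == 1] <- map[as.integer(v) + 1L]
  out
}

#' Variance-weighted in-patch histogram equalization
#'
#' The image variance enters as a normalized gain weight
#' `w = sigma2 / 16256.25` (the largest variance an 8-bit image can have);
#' the output inside the patch is the convex blend
#' `(1 - w) * patch + w * equalized(patch)` where the equalization is the
#' standard CDF mapping computed on the patch pixels only. Pixels outside
#' the patch are unchanged; a zero-variance image passes through.
#'
#' @param range a [locate_lesion_range()] result.
#' @param sigma2 image variance from [image_variance()].
#' @param image grayscale matrix in \[0, 255\].
#' @return grayscale matrix in \[0, 255\].
#' @export
weight_and_equalize_patch <- function(range, sigma2, image) {
  stopifnot(inherits(range, "lesion_range"))
  g <- as_gray(image)
  pm <- range$patch_mask
  if (sum(pm) == 0) return(g)
  w <- sigma2 / 16256.25
  eq <- equalize_in_patch(g, pm)
  out <- g
  out[pm == 1] <- round((1 - w) * g[pm == 1] + w * eq[pm == 1])
  clip255(out)
}

#' Blend the weighted patch image with the original
#'
#' `fused = clip(alpha * image + (1 - alpha) * patch)`. The patch image
#' equals the original outside the lesion band, so pixels outside the band
#' are returned unchanged.
#'
#' @param image original grayscale matrix.
#' @param patch the [weight_and_equalize_patch()] output (same shape).
#' @param alpha blend weight in \[0, 1\]; `alpha = 1` returns the original.
#' @return grayscale matrix in \[0, 255\].
#' @export
fuse_with_original <- function(image, patch, alpha = 0.5) {
  if (!identical(dim(image), dim(patch))) stop("shape mismatch")
  clip255(round(alpha * image + (1 - alpha) * patch))
}

#' Two sequential contrast-gain search passes
#'
#' Each pass evaluates candidate images `clip(mu + g * (in - mu))` for gains
#' `g` in 1..5 about the image mean and keeps the candidate with the largest
#' Otsu between-class variance (ties to the smallest gain); the second pass
#' repeats the search on the first pass's output.
#'
#' @param image grayscale matrix in \[0, 255\].
#' @param gains candidate gain vector (default `1:5`).
#' @return list with `pass1`, `pass2` (matrices) and the chosen `gain1`,
#'   `gain2`.
#' @export
apply_gain_passes <- function(image, gains = 1:5) {
  one_pass <- function(img) {
    mu <- mean(img)
    best <- NULL; best_score <- -Inf; best_g <- gains[1]
    for (g in gains) {
      cand <- clip255(round(mu + g * (img - mu)))
      sc <- otsu_separability(cand)
      if (sc > best_score + 1e-12) {
        best <- cand; best_score <- sc; best_g <- g
      }
    }
    list(img = best, gain = best_g)
  }
  g <- as_gray(image)
  p1 <- one_pass(g)
  p2 <- one_pass(p1$img)
  list(pass1 = p1$img, pass2 = p2$img, gain1 = p1$gain, gain2 = p2$gain)
}

#' Hybrid local contrast enhancement of a lesion image
#'
#' Full chain on the luminance channel: histogram, lesion-band location,
#' variance weighting with in-band equalization, blend with the original,
#' and two gain-search passes. For RGB inputs the chroma is preserved by
#' rescaling each channel by the per-pixel luminance ratio.
#'
#' @param image grayscale matrix or H x W x 3 RGB array in \[0, 255\].
#' @param alpha blend weight passed to [fuse_with_original()].
#' @param intermediates if `TRUE`, return the intermediate stages too.
#' @return enhanced image with the input's dimensions (and, with
#'   `intermediates = TRUE`, a list with `enhanced`, `fused`, `pass1`,
#'   `pass2`, `sigma2`, `mu`).
#' @export
enhance <- function(image, alpha = 0.5, intermediates = FALSE) {
  stop_if_empty_image(image)
  is_rgb <- !is.matrix(image)
  lum <- as_gray(image)
  hist <- compute_histogram(lum)
  rng <- locate_lesion_range(hist, lum)
  v <- image_variance(lum)
  patch <- weight_and_equalize_patch(rng, v$sigma2, lum)
  fused <- fuse_with_original(lum, patch, alpha = alpha)
  passes <- apply_gain_passes(fused)
  out_lum <- passes$pass2
  out <- if (!is_rgb) out_lum else {
    ratio <- ifelse(lum > 0, out_lum / lum, 1)
    res <- image
    for (k in 1:3) res[, , k] <- clip255(image[, , k] * ratio)
    res
  }
  if (!intermediates) return(out)
  list(enhanced = out, fused = fused, pass1 = passes$pass1,
       pass2 = passes$pass2, sigma2 = v$sigma2, mu = v$mu)
}
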
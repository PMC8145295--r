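## Deep saliency segmentation, post-CNN stages: superpixel refinement of
## the saliency map, mean thresholding into a binary lesion mask,
## morphological cleanup, active-contour boundary extraction, and mask
## evaluation against ground truth.

#' Homogenize a saliency map over SLIC superpixels
#'
#' Superpixels are computed on the image (typically the enhanced image);
#' within each superpixel the saliency is replaced by its mean, and the
#' result is min-max renormalized to \[0, 1\] (a constant result maps to
#' all zeros).
#'
#' @param map H x W saliency matrix in \[0, 1\].
#' @param image image of the same spatial size used for the SLIC
#'   boundaries.
#' @param n_segments number of superpixels (>= 2).
#' @param compactness,iterations passed to [slic_superpixels()].
#' @return refined H x W saliency matrix in \[0, 1\].
#' @export
refine_with_superpixels <- function(map, image, n_segments = 200,
                                    compactness = 10, iterations = 10) {
  stopifnot(all(is.finite(map)))
  labels <- slic_superpixels(image, n_segments = n_segments,
                             compactness = compactness,
                             iterations = iterations)
  means <- tapply(as.vector(map), as.vector(labels), mean)
  out <- matrix(means[as.character(labels)], nrow(map), ncol(map))
  minmax01(out)
}

#' Threshold a saliency map at its mean
#'
#' `tau` is the arithmetic mean of all map values; pixels strictly greater
#' than `tau` become foreground (ties go to background).
#'
#' @param map H x W saliency matrix (finite values).
#' @return list of class `lesion_mask` with `values` (0/1 matrix) and
#'   `tau`.
#' @export
threshold_saliency <- function(map) {
  stopifnot(all(is.finite(map)))
  tau <- mean(map)
  structure(list(values = (map > tau) * 1, tau = tau), class = "lesion_mask")
}

#' Morphological cleanup of a binary lesion mask
#'
#' Fills holes (no background component fully enclosed by foreground) and
#' keeps only the largest connected foreground component.
#'
#' @param mask `lesion_mask` or 0/1 matrix.
#' @return 0/1 matrix with attribute `empty = TRUE` (plus a warning) when
#'   the input had no foreground.
#' @export
postprocess_mask <- function(mask) {
  m <- mask_values(mask)
  if (sum(m) == 0) {
    warning("empty mask: nothing to postprocess")
    attr(m, "empty") <- TRUE
    return(m)
  }
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(filled)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- (lab == keep) * 1
  attr(out, "empty") <- FALSE
  out
}

## Minimal Chan-Vese region-based active contour on a level set initialized
## from a binary mask. Piecewise-constant two-phase energy; the curve moves
## by the sign of (I-c2)^2 - (I-c1)^2 plus curvature smoothing.
chan_vese_refine <- function(mask, image, iterations = 50, mu = 0.2,
                             dt = 0.5) {
  if (iterations <= 0) return(mask)
  I <- as_gray(image) / 255
  phi <- 2 * mask - 1
  eps <- 1e-8
  for (it in seq_len(iterations)) {
    inside <- phi > 0
    if (!any(inside) || all(inside)) break
    c1 <- mean(I[inside]); c2 <- mean(I[!inside])
    force <- (I - c2)^2 - (I - c1)^2
    # curvature of phi by central differences
    px <- (shift_mat(phi, 0, -1) - shift_mat(phi, 0, 1)) / 2
    py <- (shift_mat(phi, -1, 0) - shift_mat(phi, 1, 0)) / 2
    pxx <- shift_mat(phi, 0, -1) - 2 * phi + shift_mat(phi, 0, 1)
    pyy <- shift_mat(phi, -1, 0) - 2 * phi + shift_mat(phi, 1, 0)
    pxy <- (shift_mat(phi, -1, -1) + shift_mat(phi, 1, 1) -
              shift_mat(phi, -1, 1) - shift_mat(phi, 1, -1)) / 4
    kappa <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
      (px^2 + py^2 + eps)^1.5
    mx <- max(abs(force))
    if (mx > 0) force <- force / mx
    phi <- phi + dt * (force + mu * kappa)
    phi <- pmin(pmax(phi, -3), 3)
  }
  (phi > 0) * 1
}

## shift a matrix by (dr, dc) with edge replication
shift_mat <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  x[pmin(pmax(seq_len(h) + dr, 1), h), pmin(pmax(seq_len(w) + dc, 1), w)]
}

#' Extract the lesion boundary as an ordered closed polygon
#'
#' The binary mask is optionally refined by a fixed number of Chan-Vese
#' active-contour iterations on the image, then the contour of the
#' (largest-component) mask is traced.
#'
#' @param mask postprocessed `lesion_mask` or 0/1 matrix (nonempty).
#' @param image image used by the active-contour refinement.
#' @param iterations Chan-Vese iterations; `0` returns the contour of the
#'   input mask exactly.
#' @param mu curvature smoothing weight.
#' @return matrix with columns `row`, `col`: ordered boundary coordinates
#'   of a closed polygon (first vertex repeated at the end).
#' @export
extract_lesion_boundary <- function(mask, image, iterations = 50, mu = 0.2) {
  m <- mask_values(mask)
  if (sum(m) == 0) stop("empty mask: no boundary to extract")
  refined <- chan_vese_refine(m, image, iterations = iterations, mu = mu)
  if (sum(refined) == 0) refined <- m  # refinement collapsed; keep input
  lab <- EBImage::bwlabel(EBImage::Image(refined))
  ct <- EBImage::ocontour(lab)
  # largest contour (EBImage returns 0-based x=row-dim coords per object)
  ct <- ct[[which.max(vapply(ct, nrow, integer(1)))]]
  poly <- cbind(row = ct[, 1] + 1, col = ct[, 2] + 1)
  rbind(poly, poly[1, , drop = FALSE])
}

#' Evaluate a predicted lesion mask against ground truth
#'
#' @param pred,truth `lesion_mask` objects or 0/1 matrices of equal shape.
#' @return list of class `segmentation_report` with `accuracy` (% pixels
#'   agreeing), `error` (= 100 - accuracy), `dice` (2TP/(2TP+FP+FN); 1 when
#'   both masks are empty) and the confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  p <- mask_values(pred); t <- mask_values(truth)
  if (!identical(dim(p), dim(t))) stop("shape mismatch between masks")
  tp <- sum(p == 1 & t == 1); tn <- sum(p == 0 & t == 0)
  fp <- sum(p == 1 & t == 0); fn <- sum(p == 0 & t == 1)
  acc <- 100 * (tp + tn) / length(p)
  dice <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(accuracy = acc, error = 100 - acc, dice = dice,
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("Segmentation: accuracy %.2f%% | error %.2f%% | Dice %.4f\n",
              x$accuracy, x$error, x$dice))
  invisible(x)
}

#' Segment one image with the deep-saliency chain
#'
#' Convenience wrapper: saliency map, superpixel refinement, mean
#' thresholding, morphological cleanup.
#'
#' @param net trained `saliency_net`.
#' @param image matrix or RGB array in \[0, 255\].
#' @param n_segments SLIC superpixel count; `NULL` uses the
#'   scale-consistent default from [scale_n_segments()].
#' @return 0/1 lesion mask matrix at the network input size.
#' @export
segment_image <- function(net, image, n_segments = NULL) {
  if (is.null(n_segments))
    n_segments <- scale_n_segments(net$spec$input_size)
  sal <- compute_saliency_map(net, image)
  ref <- refine_with_superpixels(sal, resize_to(image, net$spec$input_size),
                                 n_segments = n_segments)
  mk <- threshold_saliency(ref)
  suppressWarnings(postprocess_mask(mk))
}

#' Scale-consistent superpixel count
#'
#' Superpixel refinement works through superpixel *size*, not count: 200
#' superpixels on a 224 x 224 image are ~16 px wide. For other image sizes
#' the count is scaled with image area so the superpixel size (relative to
#' lesion scale) is preserved: `round(200 * (s/224)^2)`, floored at 9.
#'
#' @param input_size square image side in pixels.
#' @param reference_count,reference_size the reference configuration
#'   (200 superpixels at 224 px).
#' @return integer superpixel count.
#' @export
scale_n_segments <- function(input_size, reference_count = 200,
                             reference_size = 224) {
  max(9L, as.integer(round(reference_count * (input_size / reference_size)^2)))
}

## resize an image to a square side s in the package [0,255] convention
resize_to <- function(image, s) {
  d <- dim(image)
  if (d[1] == s && d[2] == s) return(image)
  if (is.matrix(image)) {
    EBImage::imageData(EBImage::resize(EBImage::Image(image / 255),
                                       w = s, h = s)) * 255
  } else {
    as.array(EBImage::resize(EBImage::Image(image / 255, colormode = "Color"),
                             w = s, h = s)) * 255
  }
}
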
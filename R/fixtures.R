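## Synthetic dermoscopy-like fixtures: lesion images with exact ground-truth
## masks, and labeled feature matrices with known informative columns. These
## generators define the desk-scale study conditions for every downstream
## stage; identical spec + seed always reproduces identical output.

#' Specification of a synthetic lesion image
#'
#' Describes an elliptical low-contrast lesion on a textured skin-like
#' background. The luminance gap between background and lesion is
#' `lesion_contrast * 255`: background luminance is `255*(0.5+c/2)` and
#' lesion luminance `255*(0.5-c/2)`, symmetric about mid-gray so any
#' contrast in \[0, 1\] stays in gamut without clipping.
#'
#' @param height,width image size in pixels.
#' @param center lesion center `c(row, col)`; default image center.
#' @param axes ellipse semi-axes `c(a, b)` in pixels.
#' @param rotation ellipse rotation in radians.
#' @param lesion_contrast fraction in \[0, 1\]: mean luminance gap between
#'   lesion and background as a fraction of 255.
#' @param background_texture_sd standard deviation (intensity units) of the
#'   Gaussian texture noise before low-pass filtering.
#' @param hair_artifacts number of thin dark hair-like polylines; default 0.
#' @param lesion_color `"brown"` or `"red"`: chroma of the lesion at the
#'   specified luminance (two discriminable lesion classes).
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return object of class `lesion_image_spec`.
#' @export
lesion_image_spec <- function(height = 64, width = 64, center = NULL,
                              axes = c(18, 12), rotation = 0,
                              lesion_contrast = 0.4,
                              background_texture_sd = 8,
                              hair_artifacts = 0,
                              lesion_color = c("brown", "red"),
                              seed = 1) {
  lesion_color <- match.arg(lesion_color)
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  if (lesion_contrast < 0 || lesion_contrast > 1)
    stop("lesion_contrast must be in [0, 1]")
  if (any(axes <= 0)) stop("axes must be positive")
  # extent of the rotated ellipse along the row/col directions
  a <- axes[1]; b <- axes[2]; th <- rotation
  ext_c <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ext_r <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  if (center[1] - ext_r < 1 || center[1] + ext_r > height ||
      center[2] - ext_c < 1 || center[2] + ext_c > width)
    stop("axes exceed image: the lesion ellipse must fit inside the image")
  structure(list(height = height, width = width, center = center,
                 axes = axes, rotation = rotation,
                 lesion_contrast = lesion_contrast,
                 background_texture_sd = background_texture_sd,
                 hair_artifacts = hair_artifacts,
                 lesion_color = lesion_color, seed = seed),
            class = "lesion_image_spec")
}

## scale an RGB chroma vector so its Rec.601 luminance equals `lum`
chroma_at_luminance <- function(chroma, lum) {
  w <- c(0.299, 0.587, 0.114)
  chroma * lum / sum(w * chroma)
}

## hard-boundary point-in-ellipse test on the pixel-center grid
ellipse_mask <- function(height, width, center, axes, rotation) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  u <- dc * cos(rotation) + dr * sin(rotation)
  v <- -dc * sin(rotation) + dr * cos(rotation)
  m <- (u / axes[1])^2 + (v / axes[2])^2 <= 1
  storage.mode(m) <- "double"
  m
}

## 5x5 box low-pass filter with edge replication (fixed small kernel)
boxfilter5 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  xp <- x[pmin(pmax(seq(-1, h + 2), 1), h), pmin(pmax(seq(-1, w + 2), 1), w)]
  out <- matrix(0, h, w)
  for (di in 0:4) for (dj in 0:4)
    out <- out + xp[seq_len(h) + di, seq_len(w) + dj]
  out / 25
}

## thin dark polyline resembling a hair shaft
draw_hair <- function(img, height, width) {
  r <- stats::runif(1, 1, height); c0 <- stats::runif(1, 1, width)
  ang <- stats::runif(1, 0, 2 * pi)
  len <- stats::runif(1, 0.4, 0.9) * min(height, width)
  n <- 3L  # segments with small random bends
  pts <- matrix(0, n + 1, 2); pts[1, ] <- c(r, c0)
  for (s in seq_len(n)) {
    ang <- ang + stats::runif(1, -0.5, 0.5)
    pts[s + 1, ] <- pts[s, ] + (len / n) * c(sin(ang), cos(ang))
  }
  for (s in seq_len(n)) {
    m <- ceiling(max(abs(pts[s + 1, ] - pts[s, ]))) + 1L
    rr <- round(seq(pts[s, 1], pts[s + 1, 1], length.out = m))
    cc <- round(seq(pts[s, 2], pts[s + 1, 2], length.out = m))
    ok <- rr >= 1 & rr <= height & cc >= 1 & cc <= width
    for (k in 1:3) img[cbind(rr[ok], cc[ok], k)] <- 40
  }
  img
}

#' Generate a synthetic lesion image and its ground-truth mask
#'
#' Renders a hard-edged (no anti-aliasing) ellipse of lesion-colored pixels
#' on a skin-toned background with low-pass-filtered Gaussian texture, so
#' the mask is unambiguous: `mask == 1` exactly on pixels whose center lies
#' inside the ellipse.
#'
#' @param spec a [lesion_image_spec()].
#' @return list with `image` (H x W x 3 array in \[0, 255\]) and `mask`
#'   (H x W 0/1 matrix).
#' @export
generate_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_image_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    mask <- ellipse_mask(h, w, spec$center, spec$axes, spec$rotation)
    bg_lum <- 255 * (0.5 + spec$lesion_contrast / 2)
    le_lum <- 255 * (0.5 - spec$lesion_contrast / 2)
    bg_rgb <- chroma_at_luminance(c(1.10, 1.00, 0.90), bg_lum)
    le_chroma <- switch(spec$lesion_color,
                        brown = c(1.25, 0.95, 0.65),
                        red = c(1.55, 0.75, 0.75))
    le_rgb <- chroma_at_luminance(le_chroma, le_lum)
    # texture: filtered Gaussian noise, shared across channels (luminance
    # texture); filtering leaves the mean at ~0 so the contrast gap holds
    tex <- boxfilter5(matrix(stats::rnorm(h * w, 0, spec$background_texture_sd), h, w))
    tex <- tex * 5  # undo the box filter's ~1/5 sd shrinkage
    img <- array(0, c(h, w, 3))
    for (k in 1:3)
      img[, , k] <- mask * le_rgb[k] + (1 - mask) * bg_rgb[k] + tex
    if (spec$hair_artifacts > 0)
      for (i in seq_len(spec$hair_artifacts)) img <- draw_hair(img, h, w)
    img <- clip255(img)
    list(image = img, mask = mask)
  })
}

#' Specification of a synthetic labeled feature dataset
#'
#' Informative features carry class-dependent means spaced
#' `class_separation` noise-SDs apart (centered across classes); the
#' remaining features are pure Gaussian noise.
#'
#' @param n_samples_per_class integer vector, one count per class.
#' @param n_features total feature count.
#' @param n_informative number of class-informative features
#'   (`<= n_features`).
#' @param class_separation effect size between adjacent class means, in
#'   units of `noise_sd`.
#' @param noise_sd within-class feature standard deviation.
#' @param seed integer seed.
#' @return object of class `feature_dataset_spec`.
#' @export
feature_dataset_spec <- function(n_samples_per_class = c(100, 100),
                                 n_features = 200, n_informative = 20,
                                 class_separation = 2.0, noise_sd = 1.0,
                                 seed = 1) {
  if (any(n_samples_per_class <= 0) || length(n_samples_per_class) == 0)
    stop("all class counts must be positive")
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features")
  if (n_features <= 0 || n_informative < 0) stop("invalid feature counts")
  structure(list(n_samples_per_class = as.integer(n_samples_per_class),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 class_separation = class_separation, noise_sd = noise_sd,
                 seed = seed),
            class = "feature_dataset_spec")
}

#' Generate a synthetic labeled feature matrix
#'
#' @param spec a [feature_dataset_spec()].
#' @return list with `features` (N x d matrix, columns `f1..fd`), `labels`
#'   (factor) and `informative_indices` (integer vector) for recovery tests.
#' @export
generate_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "feature_dataset_spec"))
  with_seed(spec$seed, {
    k <- length(spec$n_samples_per_class)
    n <- sum(spec$n_samples_per_class)
    d <- spec$n_features
    x <- matrix(stats::rnorm(n * d, 0, spec$noise_sd), n, d)
    labels <- factor(rep(seq_len(k), spec$n_samples_per_class),
                     levels = seq_len(k),
                     labels = sprintf("class%d", seq_len(k)))
    info <- seq_len(spec$n_informative)
    # class c mean offset, centered so the grand mean stays ~0
    offsets <- (seq_len(k) - (k + 1) / 2) * spec$class_separation * spec$noise_sd
    for (j in info)
      x[, j] <- x[, j] + offsets[as.integer(labels)]
    colnames(x) <- sprintf("f%d", seq_len(d))
    list(features = x, labels = labels, informative_indices = info)
  })
}

#' Per-class image counts of the HAM10000 dermoscopy archive
#'
#' The seven-class imbalance shape (AKIEC, BCC, BKL, DF, NV, MEL, VASC)
#' used, scaled down, by the fixture generators.
#' @return named integer vector.
#' @export
ham10000_class_counts <- function() {
  c(AKIEC = 327L, BCC = 541L, BKL = 1099L, DF = 155L, NV = 6705L,
    MEL = 1113L, VASC = 142L)
}

#' Scale class counts proportionally with a floor of one
#'
#' @param counts integer vector of class counts.
#' @param factor multiplicative scale in (0, 1\].
#' @return integer vector `pmax(round(counts * factor), 1)`.
#' @export
scale_class_counts <- function(counts, factor) {
  if (length(counts) == 0) stop("empty class list")
  pmax(as.integer(round(counts * factor)), 1L)
}

#' Write a directory of synthetic per-class lesion images
#'
#' One subdirectory per class; image counts follow
#' `spec$n_samples_per_class` (which may emulate the HAM10000 imbalance via
#' [scale_class_counts()]). Class appearance alternates lesion color and
#' size so the classes are discriminable.
#'
#' @param spec a [feature_dataset_spec()] whose `n_samples_per_class`
#'   defines the per-class image counts.
#' @param out_dir output directory (created if missing).
#' @param image_size image side length in pixels.
#' @return invisibly, a data.frame with `path` and `class` per image.
#' @export
generate_class_directory <- function(spec, out_dir, image_size = 64) {
  stopifnot(inherits(spec, "feature_dataset_spec"))
  counts <- spec$n_samples_per_class
  if (length(counts) == 0) stop("empty class list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (cls in seq_along(counts)) {
    cdir <- file.path(out_dir, sprintf("class%02d", cls))
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(counts[cls])) {
      ispec <- random_lesion_spec(image_size,
                                  seed = spec$seed + cls * 10000L + i,
                                  class_id = cls)
      im <- generate_lesion_image(ispec)
      path <- file.path(cdir, sprintf("img%04d.png", i))
      write_image_png(im$image, path)
      rows[[length(rows) + 1L]] <- data.frame(path = path,
                                              class = sprintf("class%02d", cls),
                                              stringsAsFactors = FALSE)
    }
  }
  invisible(do.call(rbind, rows))
}

## randomized per-image spec with class-dependent appearance
random_lesion_spec <- function(image_size, seed, class_id = 1,
                               contrast = 0.4) {
  with_seed(seed, {
    colr <- if (class_id %% 2 == 1) "brown" else "red"
    scale <- 1 - 0.25 * ((class_id - 1) %/% 2 %% 2)  # alternate sizes
    a <- stats::runif(1, 0.22, 0.30) * image_size * scale
    b <- stats::runif(1, 0.14, 0.20) * image_size * scale
    rot <- stats::runif(1, 0, pi)
    ext <- sqrt(max(a, b)^2)  # conservative extent bound
    ctr <- c(stats::runif(1, 1 + ext, image_size - ext),
             stats::runif(1, 1 + ext, image_size - ext))
    lesion_image_spec(height = image_size, width = image_size, center = ctr,
                      axes = c(a, b), rotation = rot,
                      lesion_contrast = contrast,
                      lesion_color = colr, seed = seed + 1L)
  })
}

#' Write an RGB or grayscale image as 8-bit PNG
#' @param image matrix or H x W x 3 array in \[0, 255\].
#' @param path output file.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read a PNG image into the package's \[0, 255\] convention
#' @param path PNG file; gray PNGs give a matrix, color PNGs an H x W x 3
#'   array (alpha dropped).
#' @return matrix or array in \[0, 255\].
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3 && dim(x)[3] >= 3) x <- x[, , 1:3]
  x * 255
}

#' Write a binary mask as a single-channel PNG with values \{0, 255\}
#' @param mask 0/1 matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask_values(mask), target = path)
  invisible(path)
}

#' Read a binary mask PNG written by [write_mask_png()]
#' @param path PNG file.
#' @return 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  (x > 0.5) * 1
}
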
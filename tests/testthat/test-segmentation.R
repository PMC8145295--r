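test_that("mean-thresholding matches the brute-force loop exactly", {
  m <- matrix(c(0.2, 0.8), 1, 2)
  mk <- threshold_saliency(m)
  expect_equal(mk$tau, 0.5)
  expect_equal(as.vector(mk$values), c(0, 1))

  # constant map: strict > sends everything to background
  cm <- matrix(0.4, 4, 4)
  expect_true(all(threshold_saliency(cm)$values == 0))

  set.seed(10)
  for (rep in 1:5) {
    mp <- matrix(runif(256), 16, 16)
    mk2 <- threshold_saliency(mp)
    # naive loop oracle
    tau <- sum(mp) / length(mp)
    ref <- matrix(0, 16, 16)
    for (i in 1:16) for (j in 1:16) if (mp[i, j] > tau) ref[i, j] <- 1
    expect_identical(mk2$values, ref)
  }
})

test_that("superpixel refinement homogenizes and keeps fixed points", {
  im <- generate_lesion_image(lesion_image_spec(height = 32, width = 32,
                                                axes = c(8, 6), seed = 3))
  set.seed(2)
  mp <- matrix(runif(32 * 32), 32, 32)
  ref <- refine_with_superpixels(mp, im$image, n_segments = 40)
  labels <- slic_superpixels(im$image, n_segments = 40)
  # constant within every superpixel (up to the final renormalization)
  vars <- tapply(as.vector(ref), as.vector(labels), stats::var)
  expect_true(all(vars < 1e-20 | is.na(vars)))

  # a map already constant on superpixels and spanning [0,1] is unchanged
  means01 <- minmax01_map <- NULL
  pc <- matrix(stats::ave(as.vector(mp), as.vector(labels)), 32, 32)
  pc <- (pc - min(pc)) / (max(pc) - min(pc))
  expect_equal(refine_with_superpixels(pc, im$image, n_segments = 40), pc,
               tolerance = 1e-12)

  expect_error(refine_with_superpixels(mp, im$image, n_segments = 1), "at least 2")
  expect_error(refine_with_superpixels(mp, im$image, n_segments = 1e6),
               "exceeds")
})

test_that("morphological cleanup fills holes and keeps the largest blob", {
  # ring -> solid disk
  ring <- matrix(0, 21, 21)
  for (r in 1:21) for (c in 1:21) {
    d <- sqrt((r - 11)^2 + (c - 11)^2)
    if (d >= 4 && d <= 8) ring[r, c] <- 1
  }
  filled <- postprocess_mask(ring)
  expect_true(all(filled[sqrt(outer((1:21) - 11, rep(0, 21), "+")^2 +
                                outer(rep(0, 21), (1:21) - 11, "+")^2) <= 7] == 1))

  # two components: only the larger survives
  two <- matrix(0, 20, 20)
  two[2:11, 2:11] <- 1          # area 100
  two[16:17, 16:18] <- 1        # area 6
  out <- postprocess_mask(two)
  expect_equal(sum(out), 100)
  expect_true(all(out[16:17, 16:18] == 0))

  # Euler characteristic 1: one component, no holes
  lab <- EBImage::bwlabel(EBImage::Image(out))
  expect_equal(max(lab), 1)
  inv <- EBImage::bwlabel(EBImage::Image(1 - out))
  # every background component touches the border (no enclosed holes)
  border_labels <- unique(c(inv[1, ], inv[nrow(out), ], inv[, 1], inv[, ncol(out)]))
  expect_true(all(unique(as.vector(inv))[unique(as.vector(inv)) > 0] %in%
                    border_labels))

  expect_warning(postprocess_mask(matrix(0, 5, 5)), "empty")
})

test_that("boundary extraction traces the mask and refines toward the lesion", {
  disk <- matrix(0, 48, 48)
  for (r in 1:48) for (c in 1:48)
    if ((r - 24)^2 + (c - 24)^2 <= 20^2) disk[r, c] <- 1
  flat <- matrix(128, 48, 48)
  poly0 <- extract_lesion_boundary(disk, flat, iterations = 0)
  # zero iterations: identical to the traced contour of the input mask
  ct <- EBImage::ocontour(EBImage::bwlabel(EBImage::Image(disk)))[[1]]
  expect_equal(poly0[-nrow(poly0), ], cbind(row = ct[, 1] + 1, col = ct[, 2] + 1))
  # closed polygon
  expect_equal(poly0[1, ], poly0[nrow(poly0), ])
  # centroid within 1 px of the disk center
  cen <- colMeans(poly0[-nrow(poly0), ])
  expect_lt(max(abs(cen - c(24, 24))), 1)

  # fixture lesion: boundary stays within ~2 px of the true ellipse rim
  im <- generate_lesion_image(lesion_image_spec(seed = 17))
  poly <- extract_lesion_boundary(im$mask, as_gray(im$image), iterations = 25)
  sp <- lesion_image_spec(seed = 17)
  th <- seq(0, 2 * pi, length.out = 720)
  er <- sp$center[1] + sp$axes[1] * cos(th) * sin(sp$rotation) +
    sp$axes[2] * sin(th) * cos(sp$rotation)
  ec <- sp$center[2] + sp$axes[1] * cos(th) * cos(sp$rotation) -
    sp$axes[2] * sin(th) * sin(sp$rotation)
  d <- vapply(seq_len(nrow(poly)), function(k)
    min(sqrt((poly[k, 1] - er)^2 + (poly[k, 2] - ec)^2)), numeric(1))
  expect_lt(mean(d), 2)

  expect_error(extract_lesion_boundary(matrix(0, 5, 5), flat), "empty")
})

test_that("segmentation reports obey their defining identities", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  r <- evaluate_segmentation(a, a)
  expect_equal(r$accuracy, 100)
  expect_equal(r$error, 0)
  expect_equal(r$dice, 1)

  half <- matrix(c(1, 1, 0, 0), 2, 2)
  r2 <- evaluate_segmentation(1 - half, half)
  expect_equal(r2$accuracy, 0)

  # hand-counted 4x4 toy: TP=4, TN=8, FP=2, FN=2
  truth <- matrix(0, 4, 4); truth[1:2, 1:3] <- 1   # 6 true foreground
  pred <- matrix(0, 4, 4); pred[1:2, 1:2] <- 1; pred[3:4, 1] <- 1
  r3 <- evaluate_segmentation(pred, truth)
  expect_equal(r3$tp, 4); expect_equal(r3$fp, 2); expect_equal(r3$fn, 2)
  expect_equal(r3$accuracy, 75.0)
  expect_equal(r3$dice, 8 / 12, tolerance = 1e-12)
  expect_equal(r3$accuracy + r3$error, 100)

  expect_error(evaluate_segmentation(matrix(0, 2, 2), matrix(0, 3, 3)),
               "mismatch")
})
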
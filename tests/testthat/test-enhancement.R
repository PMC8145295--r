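test_that("histograms tally gray levels exactly", {
  img <- matrix(42, 10, 10)
  h <- compute_histogram(img)
  expect_equal(h$counts[43], 100L)
  expect_equal(sum(h$counts), 100L)

  # 4x4 image with levels 0..15 once each, against a naive per-pixel tally
  img2 <- matrix(0:15, 4, 4)
  h2 <- compute_histogram(img2)
  naive <- integer(256)
  for (v in as.vector(img2)) naive[v + 1] <- naive[v + 1] + 1L
  expect_identical(h2$counts, naive)
  expect_error(compute_histogram(matrix(numeric(0), 0, 0)), "empty")
})

test_that("lesion range matches brute-force Otsu on bimodal images", {
  img <- bimodal_image(40, 200)
  rng <- locate_lesion_range(compute_histogram(img), img)
  bf <- brute_force_otsu(img)
  expect_equal(rng$k1, 40)
  expect_equal(rng$kn, bf$threshold)
  expect_false(rng$degenerate)
  expect_equal(sum(rng$patch_mask), 50)

  const <- matrix(7, 5, 5)
  rngc <- locate_lesion_range(compute_histogram(const), const)
  expect_true(rngc$degenerate)
  expect_true(all(rngc$patch_mask == 1))
})

test_that("lesion-range patch overlaps the true lesion on fixtures", {
  im <- generate_lesion_image(lesion_image_spec(seed = 5))
  g <- as_gray(im$image)
  rng <- locate_lesion_range(compute_histogram(g), g)
  jaccard <- sum(rng$patch_mask & im$mask) / sum(rng$patch_mask | im$mask)
  expect_gt(jaccard, 0.5)
})

test_that("image variance matches the two-pass definition", {
  expect_equal(image_variance(matrix(9, 4, 4))$sigma2, 0)
  v <- image_variance(matrix(c(0, 255), 2, 1))
  expect_equal(v$mu, 127.5)
  expect_equal(v$sigma2, 16256.25)

  set.seed(3)
  img <- matrix(sample(0:255, 1024, replace = TRUE), 32, 32)
  ref_mu <- sum(img) / 1024
  ref_var <- sum((img - ref_mu)^2) / 1024   # naive two-pass loop
  v2 <- image_variance(img)
  expect_equal(v2$sigma2, ref_var, tolerance = 1e-9)
})

test_that("variance weighting and in-patch equalization behave at the limits", {
  const <- matrix(100, 8, 8)
  rng <- locate_lesion_range(compute_histogram(const), const)
  out <- weight_and_equalize_patch(rng, 0, const)
  expect_equal(out, const)

  # two-level patch: the w = 1 equalization maps levels to the extremes,
  # matching the standard CDF-mapping formula applied by hand
  img <- matrix(c(rep(60, 32), rep(80, 32)), 8, 8)
  rng2 <- structure(list(k1 = 60, kn = 80, patch_mask = matrix(1, 8, 8),
                         degenerate = FALSE), class = "lesion_range")
  eq <- weight_and_equalize_patch(rng2, 16256.25, img)  # w = 1
  # by hand: cdf(60) = 32 = cdf_min -> 0; cdf(80) = 64 -> 255
  expect_true(all(eq[img == 60] == 0))
  expect_true(all(eq[img == 80] == 255))

  # full-image patch at w = 1 equals textbook histogram equalization
  set.seed(8)
  img3 <- matrix(sample(0:127, 256, replace = TRUE), 16, 16)
  rng3 <- structure(list(k1 = 0, kn = 127, patch_mask = matrix(1, 16, 16),
                         degenerate = FALSE), class = "lesion_range")
  got <- weight_and_equalize_patch(rng3, 16256.25, img3)
  cnt <- tabulate(as.vector(img3) + 1L, 256)
  cdf <- cumsum(cnt); cdfm <- min(cdf[cdf > 0])
  ref <- matrix(round((cdf[img3 + 1] - cdfm) / (256 - cdfm) * 255), 16, 16)
  expect_equal(got, ref)
})

test_that("fusion with the original respects identity and limit cases", {
  set.seed(2)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(fuse_with_original(img, img), img)
  patch <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(fuse_with_original(img, patch, alpha = 1), img)
  expect_error(fuse_with_original(img, matrix(0, 4, 4)), "mismatch")
})

test_that("lesion-region spread does not shrink through the blend stage", {
  im <- generate_lesion_image(lesion_image_spec(seed = 13))
  g <- as_gray(im$image)
  h <- compute_histogram(g)
  rng <- locate_lesion_range(h, g)
  v <- image_variance(g)
  patch <- weight_and_equalize_patch(rng, v$sigma2, g)
  fused <- fuse_with_original(g, patch)
  expect_gte(stats::sd(fused[im$mask == 1]), 0.5 * stats::sd(g[im$mask == 1]))
})

test_that("gain passes pick the most separable candidate", {
  const <- matrix(50, 6, 6)
  p <- apply_gain_passes(const)
  expect_equal(p$pass1, const)
  expect_equal(p$pass2, const)

  # two-level image {100, 150}: enumerate all five candidates by hand
  img <- matrix(c(rep(100, 18), rep(150, 18)), 6, 6)
  best <- NULL; best_v <- -1
  for (g in 1:5) {
    cand <- pmin(pmax(round(125 + g * (img - 125)), 0), 255)
    v <- brute_force_otsu(cand)$bcv
    if (v > best_v + 1e-9) { best_v <- v; best <- cand }
  }
  p2 <- apply_gain_passes(img)
  expect_equal(p2$pass1, best)
  expect_equal(p2$gain1, 5)
  expect_true(all(p2$pass1 %in% c(0, 250)))
})

test_that("enhance preserves shape, range, and constant images", {
  const <- matrix(77, 12, 9)
  expect_equal(enhance(const), const)

  im <- generate_lesion_image(lesion_image_spec(height = 48, width = 40,
                                                axes = c(10, 7), seed = 21))
  out <- enhance(im$image)
  expect_equal(dim(out), dim(im$image))
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(out, enhance(im$image))  # pure function
})

test_that("enhancement raises Otsu separability on most fixture images", {
  wins <- 0L
  n <- 40L
  for (i in seq_len(n)) {
    im <- generate_lesion_image(lesion_image_spec(
      seed = 1000 + i, axes = c(14 + (i %% 5), 9 + (i %% 3))))
    if (otsu_separability(enhance(im$image)) >=
        otsu_separability(im$image)) wins <- wins + 1L
  }
  expect_gte(wins / n, 0.95)
})
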
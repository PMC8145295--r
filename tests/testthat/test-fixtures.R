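test_that("lesion images honor the contrast spec and are deterministic", {
  spec <- lesion_image_spec(height = 128, width = 128, axes = c(30, 20),
                            lesion_contrast = 0.4, seed = 7)
  a <- generate_lesion_image(spec)
  b <- generate_lesion_image(spec)
  expect_identical(a, b)

  g <- as_gray(a$image)
  gap <- mean(g[a$mask == 1]) - mean(g[a$mask == 0])
  expect_lt(abs(gap - (-0.4 * 255)), 3 * spec$background_texture_sd)

  # zero-contrast case: mask still marks the ellipse, no luminance gap
  z <- generate_lesion_image(lesion_image_spec(lesion_contrast = 0, seed = 3))
  expect_gt(sum(z$mask), 0)
  gz <- as_gray(z$image)
  expect_lt(abs(mean(gz[z$mask == 1]) - mean(gz[z$mask == 0])), 10)
})

test_that("the rendered mask equals an independent point-in-ellipse test", {
  spec <- lesion_image_spec(height = 60, width = 80, center = c(28, 45),
                            axes = c(16, 9), rotation = 0.7, seed = 2)
  m <- generate_lesion_image(spec)$mask
  ref <- matrix(0, 60, 80)
  for (r in 1:60) for (c in 1:80) {
    dr <- r - 28; dc <- c - 45
    u <- dc * cos(0.7) + dr * sin(0.7)
    v <- -dc * sin(0.7) + dr * cos(0.7)
    ref[r, c] <- as.numeric((u / 16)^2 + (v / 9)^2 <= 1)
  }
  expect_identical(m, ref)
})

test_that("invalid lesion specs are rejected", {
  expect_error(lesion_image_spec(height = 32, width = 32, axes = c(30, 20)),
               "exceed")
  expect_error(lesion_image_spec(lesion_contrast = 1.2), "contrast")
})

test_that("feature datasets separate classes only on informative columns", {
  spec <- feature_dataset_spec(n_samples_per_class = c(100, 100),
                               n_features = 200, n_informative = 20,
                               class_separation = 2.0, seed = 11)
  a <- generate_feature_dataset(spec)
  expect_identical(a, generate_feature_dataset(spec))
  expect_equal(dim(a$features), c(200L, 200L))
  expect_equal(a$informative_indices, 1:20)

  # informative columns carry the class signal, noise columns do not:
  # hold-out error on informative columns beats matched random noise columns
  sp <- split_dataset(a$features, a$labels, 0.7, seed = 1)
  err_on <- function(cols) {
    m <- e1071::svm(sp$train$x[, cols], sp$train$labels, kernel = "polynomial",
                    degree = 3, coef0 = 1, scale = FALSE)
    mean(predict(m, sp$test$x[, cols]) != sp$test$labels)
  }
  noise_cols <- 101:120
  expect_lt(err_on(a$informative_indices), err_on(noise_cols))

  # no-signal case: hold-out error near the majority baseline
  z <- generate_feature_dataset(feature_dataset_spec(
    n_samples_per_class = c(60, 60), n_features = 20, n_informative = 5,
    class_separation = 0, seed = 5))
  spz <- split_dataset(z$features, z$labels, 0.7, seed = 1)
  m <- e1071::svm(spz$train$x, spz$train$labels, kernel = "polynomial",
                  degree = 3, coef0 = 1, scale = FALSE)
  errz <- mean(predict(m, spz$test$x) != spz$test$labels)
  expect_gt(errz, 0.25)  # majority baseline is 0.5 here
})

test_that("invalid feature specs are rejected", {
  expect_error(feature_dataset_spec(n_features = 10, n_informative = 11),
               "n_informative")
  expect_error(feature_dataset_spec(n_samples_per_class = integer(0)),
               "positive")
})

test_that("class directories follow proportionally scaled counts", {
  counts <- scale_class_counts(ham10000_class_counts(), 1 / 100)
  # independent recomputation of the rounding rule
  expect_identical(counts,
                   pmax(as.integer(round(c(327, 541, 1099, 155, 6705, 1113, 142) / 100)), 1L))

  td <- withr::local_tempdir()
  spec <- feature_dataset_spec(n_samples_per_class = rep(10, 7),
                               n_features = 2, n_informative = 1, seed = 1)
  manifest <- generate_class_directory(spec, td, image_size = 32)
  pngs <- list.files(td, pattern = "\\.png$", recursive = TRUE)
  expect_length(pngs, 70L)
  expect_length(list.dirs(td, recursive = FALSE), 7L)

  expect_error(generate_class_directory(
    structure(list(n_samples_per_class = integer(0)),
              class = "feature_dataset_spec"), td), "empty class list")
})

test_that("PNG round-trips preserve images and masks", {
  im <- generate_lesion_image(lesion_image_spec(height = 32, width = 32,
                                                axes = c(8, 6), seed = 9))
  td <- withr::local_tempdir()
  p1 <- file.path(td, "img.png"); p2 <- file.path(td, "mask.png")
  write_image_png(im$image, p1)
  write_mask_png(im$mask, p2)
  back <- read_image_png(p1)
  expect_equal(dim(back), dim(im$image))
  expect_lt(max(abs(back - round(im$image))), 0.51)  # 8-bit quantization
  expect_identical(read_mask_png(p2), im$mask)
})
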
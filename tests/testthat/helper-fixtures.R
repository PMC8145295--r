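# Shared tiny fixtures built in code at test time.

# a small bimodal grayscale image: n0 pixels at v0, n1 at v1
bimodal_image <- function(v0 = 40, v1 = 200, n0 = 50, n1 = 50) {
  matrix(c(rep(v0, n0), rep(v1, n1)), nrow = 10)
}

# brute-force Otsu: exhaustive between-class-variance search over all 256
# thresholds, straight from the defining sums
brute_force_otsu <- function(image) {
  g <- as.vector(image)
  best_t <- 0L; best_v <- -1
  for (t in 0:255) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(g); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-9) { best_v <- v; best_t <- t }
  }
  list(threshold = best_t, bcv = max(best_v, 0))
}

# small separable two-class feature fixture
tiny_feature_fixture <- function(n_per_class = 30, d = 6, d_info = 2,
                                 sep = 3, seed = 42) {
  generate_feature_dataset(feature_dataset_spec(
    n_samples_per_class = c(n_per_class, n_per_class), n_features = d,
    n_informative = d_info, class_separation = sep, seed = seed))
}

# cache heavyweight shared computations across test files
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}
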
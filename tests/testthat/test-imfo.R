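# Wrapper feature selection: population mechanics, gates, fitness, and
# agreement with the exhaustive oracle on small dimensions.

test_that("population initialization is uniform, shaped, and deterministic", {
  st <- initialize_population(20, 100, seed = 5)
  expect_equal(dim(st$positions), c(20L, 100L))
  expect_true(all(st$positions >= 0 & st$positions <= 1))
  expect_identical(st$positions, initialize_population(20, 100, seed = 5)$positions)
  expect_gt(mean(st$positions), 0.45)
  expect_lt(mean(st$positions), 0.55)
  expect_error(initialize_population(1, 10), "n_pop")
})

test_that("the fitness combines hold-out error and sparsity per its formula", {
  fd <- tiny_feature_fixture()
  split <- make_holdout_split(fd$labels, 0.3, seed = 1)
  gate <- rep(0, 6); gate[fd$informative_indices] <- 1

  # r = 1: pure error; r = 0: pure sparsity
  f1 <- evaluate_fitness(gate, fd$features, fd$labels,
                         fitness_config(r_weight = 1), split = split)
  err <- lesionkit:::cubic_svm_error(
    fd$features[split$train_idx, which(gate == 1)], fd$labels[split$train_idx],
    fd$features[split$test_idx, which(gate == 1)], fd$labels[split$test_idx])
  expect_equal(f1, err)

  gate10 <- c(rep(1, 3), rep(0, 3))
  f0 <- evaluate_fitness(gate10, fd$features, fd$labels,
                         fitness_config(r_weight = 0), split = split)
  expect_equal(f0, 0.5)  # 3 of 6 features

  # direct substitution: r = 0.5, error e, k/d sparsity
  f5 <- evaluate_fitness(gate, fd$features, fd$labels,
                         fitness_config(r_weight = 0.5), split = split)
  expect_equal(f5, 0.5 * err + 0.5 * (2 / 6))

  # all-zero gate is the worst solution by convention
  expect_equal(evaluate_fitness(rep(0, 6), fd$features, fd$labels), 1.0)
  expect_error(evaluate_fitness(gate, fd$features, rep("x", nrow(fd$features)),
                                fitness_config()), "2 classes")
})

test_that("the sigmoid mean-gate uses a strict row-mean threshold", {
  # position 0 -> sigmoid 0.5; explicit V = 0.4 opens the gate
  expect_equal(as.vector(binarize_positions(matrix(0, 1, 1), V = 0.4)), 1)
  # equal positions: V equals the common sigmoid value, strict > closes all
  expect_true(all(binarize_positions(matrix(0.7, 3, 5)) == 0))
  # V lands in the row-mean of sigmoids
  set.seed(1)
  p <- matrix(rnorm(10), 2, 5)
  g <- binarize_positions(p)
  s <- 1 / (1 + exp(-p))
  expect_identical(g, (s > rowMeans(s)) * 1)
})

test_that("the spiral update follows the hand-evaluated formula", {
  # d = 0, l = -1 limit: moth lands exactly on its flame
  st <- initialize_population(2, 1, seed = 1)
  st$positions[] <- 0.8
  st$flames <- list(positions = matrix(0.8, 2, 1), fitness = c(0.1, 0.2),
                    gates = matrix(1, 2, 1))
  up <- update_moths(st, max_iter = 10)
  expect_equal(up$positions[1, 1], 0.8, tolerance = 1e-12)

  # scalar arithmetic oracle: l = 0.5, b = 1, flame = 0.8, moth = 0.3
  d <- abs(0.8 - 0.3)
  expect_equal(d * exp(0.5) * cos(2 * pi * 0.5) + 0.8, 0.8 - 0.5 * exp(0.5),
               tolerance = 1e-12)

  # flame count schedule hits 1 at the final iteration
  n_pop <- 20
  sched <- function(t, max_iter) max(1, round(n_pop - t * (n_pop - 1) / max_iter))
  expect_equal(sched(30, 30), 1)
  expect_equal(sched(100, 100), 1)
  expect_error(update_moths(initialize_population(3, 2, 1), 10), "flames")
})

test_that("the entropy gate follows the normalized-histogram entropy", {
  # identical flame positions: one occupied bin, H = 0, all gates open
  st <- initialize_population(3, 4, seed = 2)
  st$flames <- list(positions = matrix(0.5, 3, 4), fitness = c(1, 2, 3) / 10,
                    gates = matrix(1, 3, 4))
  expect_true(all(entropy_gate(st) == 1))

  # hand-built histogram with counts (5,5,0,...,0): H = ln2/ln10
  vals <- c(rep(0.05, 5), rep(0.15, 5))
  expect_equal(lesionkit:::binned_entropy(vals, 10, c(0, 1)),
               log(2) / log(10), tolerance = 1e-12)

  # positions spread evenly over the 10 bins: H = 1, all gates shut
  sp <- qlogis(seq(0.05, 0.95, by = 0.1))  # sigmoids at bin centers
  st2 <- initialize_population(2, 10, seed = 3)
  st2$flames <- list(positions = rbind(sp, sp), fitness = c(0.1, 0.2),
                     gates = matrix(1, 2, 10))
  expect_true(all(entropy_gate(st2) == 0))
})

test_that("selection is elitist and recovers a separable optimum", {
  fd <- tiny_feature_fixture(n_per_class = 30, d = 8, d_info = 2, sep = 3)
  cfg <- fitness_config(r_weight = 0.9, seed = 1)
  split <- make_holdout_split(fd$labels, 0.3, seed = 1)
  sel <- select_features(fd$features, fd$labels, cfg, n_iter = 15,
                         n_pop = 10, seed = 2, split = split)
  # monotone best-fitness record (elitism contract)
  expect_true(all(diff(sel$best_fitness_history) <= 0))
  expect_gt(length(sel$selected_indices), 0)
  expect_false(any(duplicated(sel$selected_indices)))
  expect_equal(ncol(sel$reduced_matrix), length(sel$selected_indices))

  # oracle bound: metaheuristic can never beat the exhaustive optimum
  or <- exhaustive_oracle(fd$features, fd$labels, cfg, split = split)
  expect_gte(sel$final_fitness, or$best_fitness - 1e-12)
  # the exhaustive optimum beats the trivial all-ones gate
  f_all <- evaluate_fitness(rep(1, 8), fd$features, fd$labels, cfg, split)
  expect_lte(or$best_fitness, f_all)
})

test_that("the exhaustive oracle is exact on a single dimension and guarded", {
  fd <- tiny_feature_fixture(n_per_class = 15, d = 1, d_info = 1)
  cfg <- fitness_config(seed = 1)
  split <- make_holdout_split(fd$labels, 0.3, 1)
  or <- exhaustive_oracle(fd$features, fd$labels, cfg, split = split)
  expect_equal(or$best_gate, 1L)
  expect_equal(or$best_fitness,
               evaluate_fitness(1, fd$features, fd$labels, cfg, split))
  expect_error(exhaustive_oracle(matrix(0, 4, 16), rep(c("a", "b"), 2)),
               "15 dimensions")
})

test_that("a perfectly separating feature is singled out at high r", {
  # dim 3, one perfect separator, r = 0.9: optimum = that single feature
  set.seed(9)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(ifelse(y == "a", -2, 2) + rnorm(n, 0, 0.05),
             rnorm(n), rnorm(n))
  cfg <- fitness_config(r_weight = 0.9, seed = 4)
  split <- make_holdout_split(factor(y), 0.3, 4)
  or <- exhaustive_oracle(x, y, cfg, split = split)
  expect_equal(or$best_gate, c(1L, 0L, 0L))
  expect_equal(or$best_fitness, 0.9 * 0 + 0.1 * (1 / 3), tolerance = 1e-12)
})
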
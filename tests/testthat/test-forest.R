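test_that("forests are byte-identical under the same seed", {
  sim <- make_dataset(n = 300, p = 25, seed = 41)
  a <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 60, seed = 9,
                    compute_permutation = TRUE)
  b <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 60, seed = 9,
                    compute_permutation = TRUE)
  expect_identical(a$trees, b$trees)
  expect_identical(a$importance_corrected, b$importance_corrected)
  expect_identical(a$importance_permutation, b$importance_permutation)
  c <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 60, seed = 10)
  expect_false(identical(a$trees, c$trees))
})

test_that("tree structures are consistent: leaf counts sum to in-bag size", {
  sim <- make_dataset(n = 250, p = 15, seed = 42)
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 40, seed = 5,
                    min_node_fraction = 0.05)
  for (tr in f$trees) {
    leaves <- is.na(tr$feature)
    expect_equal(sum(tr$n[leaves]), 250L)          # root draws = n
    expect_equal(tr$n[1L], 250L)
    expect_equal(tr$n_case + tr$n_ctrl, tr$n)
    # children partition the parent flow
    for (v in which(!leaves)) {
      expect_equal(tr$n[tr$left[v]] + tr$n[tr$right[v]], tr$n[v])
      expect_equal(tr$n_case[tr$left[v]] + tr$n_case[tr$right[v]],
                   tr$n_case[v])
    }
    expect_true(all(tr$split[!leaves] %in% c(0.5, 1.5)))
  }
})

test_that("selection frequency equals a brute-force scan of tree node lists", {
  sim <- make_dataset(n = 200, p = 20, seed = 43)
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 50, seed = 6)
  p_i <- selection_frequency(f)
  brute <- numeric(f$n_features)
  for (tr in f$trees) {
    feats <- unique(tr$feature[!is.na(tr$feature)])
    brute[feats] <- brute[feats] + 1
  }
  expect_identical(unname(p_i), brute / 50)
})

test_that("weighted bootstrap draws cases and controls evenly", {
  # cohort imbalance of the reference dataset: 1718 cases / 4172 controls
  set.seed(44)
  n <- 5890
  y <- c(rep(1L, 1718), rep(0L, 4172))
  X <- matrix(rbinom(n * 5L, 2L, 0.3), n, 5L)
  f <- train_forest(X, y, n_trees = 100, seed = 7)
  expect_gte(mean(f$case_draw_fraction), 0.48)
  expect_lte(mean(f$case_draw_fraction), 0.52)
})

test_that("a perfectly separating feature dominates the root split", {
  set.seed(45)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(sample(0:2, n * 51, replace = TRUE), n, 51)
  X[, 17] <- ifelse(y == 1L, 2L, 0L)
  # mtry = all features: every tree sees the separator at the root
  f <- train_forest(X, y, n_trees = 100, seed = 8, mtry_fraction = 1)
  roots <- vapply(f$trees, function(tr) tr$feature[1L], integer(1))
  expect_gt(mean(roots == 17L), 0.9)
})

test_that("corrected importance separates a planted effect from noise", {
  sim <- make_dataset(n = 1500, p = 250,
                      main = data.frame(index = 5L, beta = 0.8), seed = 46)
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 200, seed = 11)
  imp <- corrected_impurity(f)
  expect_gt(imp$importance_corrected[5L], 0)
  expect_lt(imp$pvalue[5L], 0.01)
  expect_false(attr(imp, "pvalue_unstable"))
})

test_that("a forest with no splits has zero corrected importance everywhere", {
  sim <- make_dataset(n = 100, p = 10, seed = 47)
  # min_node_fraction 1: the root is at or below the size limit -> no
  # candidate draws anywhere
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 10, seed = 2,
                    min_node_fraction = 1)
  expect_true(all(f$importance_corrected == 0))
  expect_true(all(f$candidate_nodes == 0L))
  imp <- suppressWarnings(corrected_impurity(f))
  expect_true(attr(imp, "pvalue_unstable"))
})

test_that("permutation importance is zero for absent features and finds effects", {
  set.seed(48)
  n <- 600
  X <- matrix(sample(0:2, n * 40, replace = TRUE), n, 40)
  X[, 3] <- 1L  # constant: can never be split on
  y <- rbinom(n, 1, plogis(-0.8 + 0.9 * (X[, 9] >= 1)))
  f <- train_forest(X, y, n_trees = 150, seed = 12,
                    compute_permutation = TRUE)
  pi <- permutation_importance(f)
  expect_identical(pi$importance_permutation[3L], 0)
  noise <- pi$importance_permutation[-c(3L, 9L)]
  expect_gt(pi$importance_permutation[9L], quantile(noise, 0.95))
})

test_that("stored and recomputed permutation importance use the same estimator", {
  sim <- make_dataset(n = 600, p = 12, maf = c(0.2, 0.4),
                      main = data.frame(index = 2L, beta = 1.0), seed = 49)
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 200, seed = 13,
                    compute_permutation = TRUE, keep_inbag = TRUE)
  f_bare <- f
  f_bare$importance_permutation <- NULL
  pr <- permutation_importance(f_bare, sim$genotypes, sim$phenotypes,
                               seed = 999)
  # different permutation draws, same estimand: top feature agrees
  expect_equal(which.max(pr$importance_permutation),
               which.max(f$importance_permutation))
  expect_gt(cor(pr$importance_permutation, f$importance_permutation), 0.8)
})

test_that("OOB balanced accuracy is at chance on pure noise", {
  set.seed(50)
  n <- 1000
  X <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  y <- rbinom(n, 1, 0.3)
  f <- train_forest(X, y, n_trees = 500, seed = 14)
  expect_gte(f$oob_balanced_accuracy, 0.47)
  expect_lte(f$oob_balanced_accuracy, 0.53)
})

test_that("forest JSON round trip preserves tree structure", {
  sim <- make_dataset(n = 120, p = 8, seed = 51)
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 12, seed = 3)
  path <- tempfile(fileext = ".json")
  write_forest_json(f, path)
  g <- read_forest_json(path)
  expect_equal(length(g$trees), 12L)
  expect_identical(g$trees[[1L]]$feature, f$trees[[1L]]$feature)
  expect_identical(g$trees[[5L]]$split, f$trees[[5L]]$split)
  expect_identical(g$feature_names, f$feature_names)
  # statistics computed on the reloaded forest agree
  expect_identical(selection_frequency(g), selection_frequency(f))
})

test_that("single-class phenotypes are rejected", {
  X <- matrix(rbinom(100 * 5, 2, 0.3), 100, 5)
  expect_error(train_forest(X, rep(1L, 100), n_trees = 5, seed = 1),
               "class")
})
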
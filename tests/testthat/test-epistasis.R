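test_that("pair co-occurrence counts trees containing both features", {
  # trees with feature sets {1,2}, {1}, {2}
  f <- make_chain_forest(list(c(1L, 2L), 1L, 2L), n_features = 3L)
  co <- pair_cooccurrence(f, 1:3)
  expect_equal(co$t_ij[1L, 2L], 1L)
  expect_equal(unname(co$p_i[1:2]), c(2 / 3, 2 / 3))
  expect_equal(co$N, 3L)
  # a feature used at several nodes of one tree still counts once
  f2 <- make_chain_forest(list(c(1L, 2L, 1L)), n_features = 2L)
  expect_equal(pair_cooccurrence(f2, 1:2)$t_ij[1L, 2L], 1L)
  # single tree containing all features
  f3 <- make_chain_forest(list(1:4), n_features = 4L)
  co3 <- pair_cooccurrence(f3, 1:4)
  expect_true(all(co3$t_ij[upper.tri(co3$t_ij)] == 1L))
})

test_that("co-occurrence counts match a brute-force double loop on a real forest", {
  sim <- make_dataset(n = 250, p = 12, seed = 91)
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 60, seed = 7,
                    min_node_fraction = 0.05)
  co <- pair_cooccurrence(f, 1:12)
  fs <- tree_feature_sets(f)
  for (i in 1:11) for (j in (i + 1):12) {
    brute <- sum(vapply(fs, function(s) (i %in% s) && (j %in% s),
                        logical(1)))
    expect_identical(unname(co$t_ij[i, j]), brute)
  }
  # t_ij bounded by the marginal tree counts
  marg <- round(co$p_i * co$N)
  for (i in 1:11) for (j in (i + 1):12)
    expect_lte(co$t_ij[i, j], min(marg[i], marg[j]))
})

test_that("paired selection test is the exact binomial upper tail", {
  expect_equal(paired_selection_test(0, 0.5, 0.5, 10), 1)
  expect_equal(paired_selection_test(10, 1, 1, 10), 1)
  expect_equal(paired_selection_test(5, 0, 0.5, 10), 1)
  # direct-summation oracle, randomized instances
  set.seed(92)
  for (k in 1:120) {
    N <- sample(5:400, 1)
    pi_ <- runif(1); pj <- runif(1)
    t <- sample(0:N, 1)
    oracle <- sum(dbinom(t:N, N, pi_ * pj))
    expect_equal(paired_selection_test(t, pi_, pj, N), oracle,
                 tolerance = 1e-12)
  }
  # the spec'd large-deviation case is far in the tail
  p <- paired_selection_test(100, 0.3, 0.2, 1000)
  expect_lt(p, 0.001)
  expect_equal(p, sum(dbinom(100:1000, 1000, 0.06)), tolerance = 1e-12)
})

test_that("selection asymmetry counts subtree membership per daughter", {
  # chain tree: 1 splits, 2 in its left subtree only
  f <- make_chain_forest(list(c(1L, 2L)), n_features = 2L)
  asym <- selection_asymmetry(f, 1:2)
  expect_equal(asym$n_L[1L, 2L], 1L)
  expect_equal(asym$n_R[1L, 2L], 0L)
  expect_equal(asym$n_L[2L, 1L], 0L)  # 1 is upstream, not downstream, of 2
  expect_equal(asym$n_L_pooled[1L, 2L], asym$n_L_pooled[2L, 1L])
})

test_that("asymmetry counts match a recursive oracle on a real forest", {
  sim <- make_dataset(n = 250, p = 10, seed = 93)
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 40, seed = 8,
                    min_node_fraction = 0.05)
  feats <- c(2L, 5L, 7L, 9L)
  asym <- selection_asymmetry(f, feats)
  oracle <- asymmetry_oracle(f, feats)
  expect_identical(unname(unclass(asym$n_L)), oracle$n_L)
  expect_identical(unname(unclass(asym$n_R)), oracle$n_R)
})

test_that("asymmetry test is two-sided exact binomial at one half", {
  expect_equal(asymmetry_test(5, 5), 1)
  expect_equal(asymmetry_test(10, 0), 2 * 0.5^10)
  expect_equal(asymmetry_test(0, 0), 1)  # no observations -> convention
  set.seed(94)
  for (k in 1:50) {
    nl <- sample(0:30, 1); nr <- sample(0:30, 1)
    if (nl + nr == 0) next
    expect_equal(asymmetry_test(nl, nr),
                 stats::binom.test(nl, nl + nr, 0.5)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Fisher combination matches the closed-form chi-square(4) survival", {
  expect_equal(fisher_combine(1, 1), 1)
  expect_equal(fisher_combine(0.5, 0.5), 0.5966, tolerance = 1e-3)
  expect_equal(fisher_combine(0.01, 0.02), 0.0019, tolerance = 5e-3)
  set.seed(95)
  p1 <- runif(200); p2 <- runif(200)
  X <- -2 * (log(p1) + log(p2))
  expect_equal(fisher_combine(p1, p2),
               pchisq(X, df = 4, lower.tail = FALSE), tolerance = 1e-12)
  # monotone: decreasing either input never increases the combination
  expect_true(all(fisher_combine(p1 * 0.5, p2) <= fisher_combine(p1, p2)))
  expect_true(all(fisher_combine(p1, p2 * 0.1) <= fisher_combine(p1, p2)))
  expect_warning(fisher_combine(0, 0.5), "clamped")
})

test_that("BH adjustment in the screen matches the step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4L))  # the worked step-up example
  set.seed(96)
  for (k in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("screen_pairs assembles the full pair table and retention rule", {
  sim <- make_dataset(n = 1000, p = 20, maf = c(0.3, 0.3),
                      interactions = data.frame(i = 1L, j = 2L,
                                                model = "AND", gamma = 1.5),
                      seed = 97)
  f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 150, seed = 9)
  scr <- screen_pairs(f, 1:20, fdr_threshold = 0.05)
  expect_equal(nrow(scr), choose(20, 2))
  expect_true(all(scr$p_fisher > 0 & scr$p_fisher <= 1))
  expect_true(all(scr$q_ensemble >= scr$p_fisher - 1e-12))
  expect_true(all(scr$retained == (scr$q_ensemble < 0.05 &
                                   scr$direction == "epistasis-candidate")))
  # fewer than two features -> empty
  expect_equal(nrow(screen_pairs(f, 1L, 0.05)), 0L)
  expect_equal(nrow(screen_pairs(f, integer(0), 0.05)), 0L)
})

test_that("LD-emulated duplicate columns co-occur less often than expected", {
  ld_like <- 0L
  for (rep in 1:5) {
    spec <- simulation_spec(n_subjects = 600, n_variants = 20,
                            maf_range = c(0.2, 0.4), case_fraction = 0.3,
                            main_effects = data.frame(index = 3L,
                                                      beta = 0.7),
                            ld_blocks = data.frame(anchor = 3L,
                                                   n_copies = 1L,
                                                   flip_prob = 0.05),
                            seed = 200 + rep)
    sim <- simulate_dataset(spec)
    f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 150,
                      seed = rep)
    co <- pair_cooccurrence(f, c(3L, 21L))  # anchor and its noisy copy
    if (co$t_ij[1L, 2L] < co$N * co$p_i[1L] * co$p_i[2L])
      ld_like <- ld_like + 1L
  }
  expect_gte(ld_like, 3L)
})

test_that("a planted XOR pair fed to the screen is retained", {
  # the stage the screen owns: the XOR pair has survived selection and
  # sits among noise features in the final forest. XOR surfaces through
  # elevated co-occurrence, whose binomial tail sharpens with tree count,
  # so the final forest here is grown near reference scale (5000 trees)
  hit <- 0L
  for (rep in 1:3) {
    sim <- make_dataset(n = 4000, p = 25, maf = c(0.3, 0.3),
                        interactions = data.frame(i = 1L, j = 2L,
                                                  model = "XOR",
                                                  gamma = 1.5),
                        seed = 210 + rep)
    f <- train_forest(sim$genotypes, sim$phenotypes, n_trees = 5000,
                      seed = rep)
    scr <- screen_pairs(f, 1:25, fdr_threshold = 0.05)
    row <- scr[scr$feature_i == "snp00001" & scr$feature_j == "snp00002", ]
    expect_lt(row$p_cooccur, 0.01)  # the co-occurrence channel carries XOR
    if (nrow(row) == 1L && row$retained) hit <- hit + 1L
  }
  expect_gte(hit, 2L)
})
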
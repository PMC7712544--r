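test_that("genotypes are drawn in Hardy-Weinberg proportions", {
  spec <- simulation_spec(n_subjects = 100000, n_variants = 1,
                          maf_range = c(0.5, 0.5), case_fraction = 0.3,
                          seed = 21)
  gm <- simulate_genotypes(spec)
  obs <- tabulate(gm$dosages[, 1L] + 1L, 3L)
  expv <- 100000 * c(0.25, 0.5, 0.25)
  chi <- sum((obs - expv)^2 / expv)
  expect_gt(pchisq(chi, df = 2, lower.tail = FALSE), 0.001)
})

test_that("LD copies equal the anchor at flip probability 0 and decay with it", {
  spec <- simulation_spec(n_subjects = 500, n_variants = 5,
                          maf_range = c(0.2, 0.4), case_fraction = 0.3,
                          ld_blocks = data.frame(anchor = 2L, n_copies = 1L,
                                                 flip_prob = 0),
                          seed = 22)
  gm <- simulate_genotypes(spec)
  expect_equal(ncol(gm$dosages), 6L)
  expect_identical(unname(gm$dosages[, 6L]), unname(gm$dosages[, 2L]))
  spec2 <- simulation_spec(n_subjects = 2000, n_variants = 5,
                          maf_range = c(0.2, 0.4), case_fraction = 0.3,
                          ld_blocks = data.frame(anchor = 2L, n_copies = 1L,
                                                 flip_prob = 0.2),
                          seed = 23)
  gm2 <- simulate_genotypes(spec2)
  expect_gt(cor(gm2$dosages[, 2L], gm2$dosages[, 6L]), 0.6)
  expect_lt(cor(gm2$dosages[, 2L], gm2$dosages[, 6L]), 0.95)
})

test_that("the same seed reproduces the dataset exactly", {
  spec <- simulation_spec(n_subjects = 200, n_variants = 20,
                          case_fraction = 0.3,
                          main_effects = data.frame(index = 3L, beta = 0.5),
                          seed = 24)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes$status, b$phenotypes$status)
})

test_that("baseline-logit calibration hits the target case fraction", {
  spec <- simulation_spec(n_subjects = 5000, n_variants = 10,
                          case_fraction = 0.29, seed = 25)
  sim <- simulate_dataset(spec)
  fr <- mean(sim$phenotypes$status)
  expect_gte(fr, 0.27)
  expect_lte(fr, 0.31)
})

test_that("spec validation rejects out-of-range inputs", {
  expect_error(simulation_spec(maf_range = c(0.001, 0.5)), "maf_range")
  expect_error(simulation_spec(case_fraction = 1.2), "case_fraction")
  expect_error(simulation_spec(
    n_variants = 10,
    main_effects = data.frame(index = 11L, beta = 1)), "out of range")
  expect_error(simulation_spec(
    n_variants = 10,
    interactions = data.frame(i = 1L, j = 1L, model = "AND", gamma = 1)),
    "distinct")
})

test_that("AND and XOR penetrance indicators follow the carrier definition", {
  # AND with a non-carrier contributes 0 to the logit
  expect_equal(epiforest:::interaction_indicator(0L, 2L, "AND", "dominant"), 0)
  expect_equal(epiforest:::interaction_indicator(1L, 2L, "AND", "dominant"), 1)
  expect_equal(epiforest:::interaction_indicator(1L, 0L, "XOR", "dominant"), 1)
  expect_equal(epiforest:::interaction_indicator(1L, 1L, "XOR", "dominant"), 0)
  expect_equal(epiforest:::interaction_indicator(1L, 1L, "AND", "recessive"), 0)
  expect_equal(epiforest:::interaction_indicator(2L, 2L, "AND", "recessive"), 1)
})

test_that("XOR raises risk only in the exactly-one-carrier stratum", {
  spec <- simulation_spec(n_subjects = 50000, n_variants = 4,
                          maf_range = c(0.3, 0.3), case_fraction = 0.3,
                          interactions = data.frame(i = 1L, j = 2L,
                                                    model = "XOR",
                                                    gamma = 1.5),
                          seed = 26)
  sim <- simulate_dataset(spec)
  g <- sim$genotypes$dosages
  y <- sim$phenotypes$status
  carriers <- (g[, 1L] >= 1L) + (g[, 2L] >= 1L)
  rate <- tapply(y, carriers, mean)
  expect_gt(rate[["1"]], rate[["0"]])
  expect_gt(rate[["1"]], rate[["2"]])
})

test_that("a pure XOR pair near carrier frequency 1/2 is marginally invisible", {
  # dominant carrier coding makes the carrier frequency 1 - (1-maf)^2, so
  # the marginal-null point of a pure XOR pair is MAF = 1 - sqrt(1/2) ~ 0.29
  # (not MAF 0.5, where carriers are 75% and a strong marginal appears)
  spec <- simulation_spec(n_subjects = 20000, n_variants = 6,
                          maf_range = c(0.293, 0.293), case_fraction = 0.3,
                          interactions = data.frame(i = 1L, j = 2L,
                                                    model = "XOR",
                                                    gamma = 1.5),
                          seed = 27)
  sim <- simulate_dataset(spec)
  scan <- additive_scan(sim$genotypes, sim$phenotypes)
  # despite a strong joint effect, the XOR members' marginal p-values are
  # not extreme at n = 20,000 (the premise of forest-based screening)
  expect_gt(min(scan$p[1:2]), 1e-3)
  # while the joint penetrance clearly differs
  g <- sim$genotypes$dosages
  f <- xor(g[, 1L] >= 1L, g[, 2L] >= 1L)
  expect_gt(abs(mean(sim$phenotypes$status[f]) -
                mean(sim$phenotypes$status[!f])), 0.1)
})

test_that("case/control counts partition the cohort and truth set is written", {
  spec <- simulation_spec(n_subjects = 300, n_variants = 8,
                          case_fraction = 0.4,
                          interactions = data.frame(i = 1L, j = 2L,
                                                    model = "AND",
                                                    gamma = 1),
                          seed = 28)
  sim <- simulate_dataset(spec)
  expect_equal(sum(sim$phenotypes$status) +
               sum(1 - sim$phenotypes$status), 300L)
  pre <- tempfile("simout")
  write_simulation(sim, pre)
  truth <- read.delim(paste0(pre, ".truth.tsv"))
  expect_equal(truth$id_i, "snp00001")
  expect_equal(truth$id_j, "snp00002")
  expect_true(file.exists(paste0(pre, ".tped")))
})
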
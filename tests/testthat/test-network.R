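test_that("networks are connected components condensed on shared members", {
  pairs <- data.frame(feature_i = c("A", "A", "D"),
                      feature_j = c("B", "C", "E"),
                      stringsAsFactors = FALSE)
  nets <- condense_networks(pairs)
  expect_length(nets, 2L)
  expect_equal(nets[[1L]]$members, c("A", "B", "C"))
  expect_equal(nets[[2L]]$members, c("D", "E"))
  expect_equal(nrow(nets[[1L]]$pairs), 2L)

  expect_length(condense_networks(pairs[0, ]), 0L)

  ring <- data.frame(feature_i = c("A", "B", "C"),
                     feature_j = c("B", "C", "A"),
                     stringsAsFactors = FALSE)
  nets_ring <- condense_networks(ring)
  expect_length(nets_ring, 1L)
  expect_equal(nets_ring[[1L]]$members, c("A", "B", "C"))
})

test_that("a perfectly separating feature gives a depth-1 pure tree", {
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  dos <- cbind(v1 = ifelse(y == 1L, 2L, 0L),
               v2 = rep(0:1, n / 2))
  meta <- data.frame(id = c("v1", "v2"), chrom = "1", pos = 1:2,
                     ref = "A", alt = "G")
  gm <- genotype_matrix(dos, meta, sprintf("s%d", 1:n))
  ph <- phenotype_table(gm$subject_ids, y)
  tr <- fit_network_tree(c("v1", "v2"), gm, ph)
  expect_equal(tr$nodes[[1L]]$feature, "v1")
  leaves <- Filter(function(nd) is.na(nd$feature), tr$nodes)
  expect_length(leaves, 2L)
  purity <- vapply(leaves, function(nd)
    max(nd$n_case, nd$n_ctrl) / nd$n, numeric(1))
  expect_true(all(purity == 1))
})

test_that("null features give a root-only tree at alpha 0.05", {
  root_only <- 0L
  for (rep in 1:50) {
    sim <- make_dataset(n = 2000, p = 3, maf = c(0.2, 0.4),
                        seed = 400 + rep)
    tr <- fit_network_tree(sim$genotypes$variants$id, sim$genotypes,
                           sim$phenotypes, alpha = 0.05)
    if (length(tr$nodes) == 1L) root_only <- root_only + 1L
  }
  expect_gte(root_only, 45L)
})

test_that("a planted AND pair appears on one root-to-leaf path", {
  used_both <- 0L
  for (rep in 1:5) {
    sim <- make_dataset(n = 3000, p = 4, maf = c(0.3, 0.3),
                        interactions = data.frame(i = 1L, j = 2L,
                                                  model = "AND",
                                                  gamma = 1.5),
                        seed = 500 + rep)
    tr <- fit_network_tree(c("snp00001", "snp00002"), sim$genotypes,
                           sim$phenotypes)
    feats <- unlist(lapply(tr$nodes, function(nd) nd$feature))
    if (all(c("snp00001", "snp00002") %in% feats)) used_both <- used_both + 1L
  }
  expect_gte(used_both, 4L)
})

test_that("terminal odds ratios reproduce the worked arithmetic", {
  # a hand-built one-split tree over the reference cohort: leaf of 30
  # cases / 10 controls against 1718 cases / 4172 controls in total
  tree <- structure(list(
    nodes = list(
      list(feature = "v1", left_levels = list(c(0, 1)),
           p_adjusted = 1e-6, left = 2L, right = 3L, n = 5890L,
           n_case = 1718L, n_ctrl = 4172L),
      list(feature = NA_character_, left_levels = NA, p_adjusted = NA,
           left = NA_integer_, right = NA_integer_, n = 5850L,
           n_case = 1688L, n_ctrl = 4162L),
      list(feature = NA_character_, left_levels = NA, p_adjusted = NA,
           left = NA_integer_, right = NA_integer_, n = 40L,
           n_case = 30L, n_ctrl = 10L)),
    features = "v1", n_case = 1718L, n_ctrl = 4172L,
    alpha = 0.05, min_leaf = 20L), class = "network_tree")
  ors <- terminal_odds_ratios(tree, mode = "overall")
  leaf <- ors[ors$node == 3L, ]
  expect_equal(leaf$or_overall, (30 / 10) / (1718 / 4172),
               tolerance = 1e-12)
  expect_equal(round(leaf$or_overall, 2), 7.29)
  expect_equal(leaf$or_complement, (30 / 10) / (1688 / 4162),
               tolerance = 1e-12)
  expect_equal(round(leaf$or_complement, 2), 7.4)
  expect_equal(leaf$odds_ratio, leaf$or_overall)
  # exact count conservation across leaves
  expect_equal(sum(ors$n_case), 1718L)
  expect_equal(sum(ors$n_ctrl), 4172L)
})

test_that("a root-only tree has odds ratio 1 in overall mode", {
  sim <- make_dataset(n = 500, p = 2, seed = 105)
  tr <- fit_network_tree("snp00001", sim$genotypes, sim$phenotypes,
                         alpha = 1e-12)
  expect_length(tr$nodes, 1L)
  ors <- terminal_odds_ratios(tr, mode = "overall")
  expect_equal(ors$odds_ratio, 1)
})

test_that("leaves partition the cohort and weighted leaf odds conserve overall odds", {
  sim <- make_dataset(n = 2500, p = 5, maf = c(0.2, 0.4),
                      main = data.frame(index = c(1L, 2L),
                                        beta = c(0.7, 0.5)), seed = 106)
  tr <- fit_network_tree(sim$genotypes$variants$id[1:3], sim$genotypes,
                         sim$phenotypes, alpha = 0.5, min_leaf = 50)
  ors <- terminal_odds_ratios(tr, mode = "overall")
  expect_gt(nrow(ors), 1L)
  expect_equal(sum(ors$n), 2500L)
  expect_equal(sum(ors$n_case), sum(sim$phenotypes$status))
  # overall-normalized: counts recombine to the cohort odds exactly
  expect_equal(sum(ors$n_case) / sum(ors$n_ctrl),
               tr$n_case / tr$n_ctrl, tolerance = 1e-12)
})

test_that("raising alpha never yields a shallower tree", {
  sim <- make_dataset(n = 2000, p = 4, maf = c(0.25, 0.35),
                      main = data.frame(index = 1L, beta = 0.5),
                      seed = 107)
  feats <- sim$genotypes$variants$id[1:3]
  n_strict <- length(fit_network_tree(feats, sim$genotypes,
                                      sim$phenotypes, alpha = 0.001)$nodes)
  n_loose <- length(fit_network_tree(feats, sim$genotypes,
                                     sim$phenotypes, alpha = 0.5)$nodes)
  expect_gte(n_loose, n_strict)
})

test_that("dot rendering writes a parseable outline", {
  sim <- make_dataset(n = 600, p = 2, maf = c(0.3, 0.4),
                      main = data.frame(index = 1L, beta = 1.0), seed = 108)
  tr <- fit_network_tree("snp00001", sim$genotypes, sim$phenotypes,
                         alpha = 0.5)
  f <- tempfile(fileext = ".dot")
  network_tree_dot(tr, f)
  txt <- readLines(f)
  expect_equal(txt[1L], "digraph network_tree {")
  expect_true(any(grepl("->", txt)))
})
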
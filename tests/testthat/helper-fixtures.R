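# shared fixture builders: everything generated in code, nothing on disk

# small complete case-control dosage dataset with optional planted effects
make_dataset <- function(n = 400, p = 30, maf = c(0.1, 0.5),
                         case_fraction = 0.3, main = NULL,
                         interactions = NULL, seed = 1) {
  spec <- simulation_spec(n_subjects = n, n_variants = p,
                          maf_range = maf, case_fraction = case_fraction,
                          main_effects = main, interactions = interactions,
                          seed = seed)
  simulate_dataset(spec)
}

# hand-built epi_forest from per-tree feature chains: each element of
# `chains` is an integer vector of features split along a left-going chain
# (feature k splits, its left child is the next split, right child a leaf)
make_chain_forest <- function(chains, n_features,
                              feature_names = sprintf("f%d", seq_len(n_features))) {
  trees <- lapply(chains, function(ch) {
    k <- length(ch)
    if (k == 0L) {
      return(list(feature = NA_integer_, split = NA_real_,
                  left = NA_integer_, right = NA_integer_, n = 10L,
                  n_case = 5L, n_ctrl = 5L, pred = 1L))
    }
    nn <- 2L * k + 1L
    feature <- rep(NA_integer_, nn); split <- rep(NA_real_, nn)
    left <- rep(NA_integer_, nn); right <- rep(NA_integer_, nn)
    node <- 1L
    for (i in seq_len(k)) {
      feature[node] <- ch[i]; split[node] <- 0.5
      left[node] <- node + 2L; right[node] <- node + 1L
      node <- node + 2L
    }
    sz <- rep(10L, nn)
    list(feature = feature, split = split, left = left, right = right,
         n = sz, n_case = sz %/% 2L, n_ctrl = sz - sz %/% 2L,
         pred = rep(1L, nn))
  })
  structure(list(trees = trees, feature_names = feature_names,
                 n_features = n_features, n_subjects = 10L,
                 n_case = 5L, n_ctrl = 5L),
            class = "epi_forest")
}

# tped/tfam text fixture written to a tempdir; returns the prefix
write_tped_fixture <- function(tped_lines, tfam_lines,
                               prefix = tempfile("fix")) {
  writeLines(tped_lines, paste0(prefix, ".tped"))
  writeLines(tfam_lines, paste0(prefix, ".tfam"))
  prefix
}

# independent reference for BH step-up adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    prev <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- prev
  }
  q
}

# independent reference for subtree-membership asymmetry counts
asymmetry_oracle <- function(forest, features) {
  K <- length(features)
  nL <- matrix(0L, K, K); nR <- matrix(0L, K, K)
  subtree_feats <- function(tr, node) {
    if (is.na(tr$feature[node])) return(integer(0))
    unique(c(tr$feature[node],
             subtree_feats(tr, tr$left[node]),
             subtree_feats(tr, tr$right[node])))
  }
  for (tr in forest$trees) {
    for (v in seq_along(tr$feature)) {
      f <- tr$feature[v]
      if (is.na(f) || !(f %in% features)) next
      ki <- match(f, features)
      lf <- subtree_feats(tr, tr$left[v])
      rf <- subtree_feats(tr, tr$right[v])
      for (kj in seq_len(K)) {
        if (kj == ki) next
        if (features[kj] %in% lf) nL[ki, kj] <- nL[ki, kj] + 1L
        if (features[kj] %in% rf) nR[ki, kj] <- nR[ki, kj] + 1L
      }
    }
  }
  list(n_L = nL, n_R = nR)
}

# mirror of the package-internal seed fan-out, so seed-stream reduction
# properties are checked against an explicit construction
derive_seed_for_test <- function(seed, offset) {
  (seed * 48271 + offset * 1000003) %% 2147483647
}
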
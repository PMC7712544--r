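#' Train a class-weighted random forest on genotype dosages
#'
#' Grows `n_trees` binary CART-style trees on a *weighted bootstrap*: each
#' of the n draws picks a case or a control with probability 1/2 and then a
#' subject uniformly within the class, so the expected in-bag class balance
#' is 50:50 regardless of cohort imbalance. Dosages are treated as ordered
#' numeric, so candidate splits are at 0.5 and 1.5; the best Gini-decrease
#' split is chosen among `ceiling(mtry_fraction * p)` candidate features
#' sampled without replacement at each node (candidate order is shuffled
#' under the tree's RNG stream, which also breaks Gini ties
#' deterministically). Nodes at or below `min_node_fraction * n` subjects
#' become leaves, limiting tree depth.
#'
#' Shadow bookkeeping for the corrected impurity importance is always on:
#' at every node, each candidate's best split decrease is compared with the
#' best decrease achieved by a within-node permuted copy of the same
#' feature (realised by drawing the permuted dosage x class table from its
#' exact multivariate-hypergeometric distribution).
#'
#' @param gm a [genotype_matrix()] or a plain integer matrix of dosages
#'   (subjects x features, values 0/1/2).
#' @param pheno an aligned [phenotype_table()] (or a 0/1 vector).
#' @param n_trees number of trees (reference setting: 1000 for the first
#'   screening forest, 10000 inside r2VIM).
#' @param mtry_fraction fraction of features tried at each split
#'   (reference: 1/3).
#' @param min_node_fraction nodes at or below this fraction of the cohort
#'   are not split (reference: 0.10).
#' @param seed integer seed; the forest is byte-identical given it.
#' @param compute_permutation also compute class-weighted OOB permutation
#'   importance during training (costs roughly one extra pass per tree and
#'   in-tree feature).
#' @param keep_inbag retain the subjects x trees in-bag multiplicity
#'   matrix (needed to recompute permutation importance afterwards).
#' @return an object of class `epi_forest`: tree structures (feature /
#'   split / children / per-node counts), importance accumulators,
#'   per-tree bootstrap case fractions, the class-weighted OOB accuracy of
#'   the forest vote, and the training parameters.
#' @export
train_forest <- function(gm, pheno, n_trees = 1000, mtry_fraction = 1 / 3,
                         min_node_fraction = 0.1, seed = 1L,
                         compute_permutation = FALSE, keep_inbag = FALSE) {
  X <- if (inherits(gm, "genotype_matrix")) gm$dosages else gm
  storage.mode(X) <- "integer"
  y <- if (inherits(pheno, "phenotype_table")) pheno$status else
    as.integer(pheno)
  if (inherits(gm, "genotype_matrix") && inherits(pheno, "phenotype_table"))
    check_aligned(gm, pheno)
  if (anyNA(X)) stopf("dosage matrix contains missing values")
  if (anyNA(y)) stopf("phenotype contains missing values")
  if (length(unique(y)) < 2L) stopf("phenotype has a single class")
  stopifnot(n_trees >= 1, mtry_fraction > 0, mtry_fraction <= 1)
  n <- nrow(X); p <- ncol(X)
  mtry <- max(1L, as.integer(ceiling(mtry_fraction * p)))
  min_node <- as.integer(floor(min_node_fraction * n))
  fit <- .rf_train_cpp(X, y, as.integer(n_trees), mtry, min_node,
                       as.numeric(seed), isTRUE(compute_permutation),
                       isTRUE(keep_inbag))
  structure(list(
    trees = fit$trees,
    feature_names = colnames(X) %||% sprintf("f%d", seq_len(p)),
    n_features = p, n_subjects = n,
    n_case = sum(y), n_ctrl = n - sum(y),
    importance_gini = fit$importance_gini,
    importance_corrected = fit$importance_corrected,
    candidate_nodes = fit$candidate_nodes,
    importance_permutation = if (compute_permutation)
      fit$importance_permutation else NULL,
    case_draw_fraction = fit$case_draw_fraction,
    oob_balanced_accuracy = fit$oob_balanced_accuracy,
    inbag = if (keep_inbag) fit$inbag else NULL,
    params = list(n_trees = n_trees, mtry = mtry,
                  mtry_fraction = mtry_fraction,
                  min_node_fraction = min_node_fraction,
                  min_node_size = min_node, seed = seed)),
    class = "epi_forest")
}

#' @export
print.epi_forest <- function(x, ...) {
  cat(sprintf(
    "epi_forest: %d trees, %d features, %d subjects (%d cases / %d controls)\n",
    length(x$trees), x$n_features, x$n_subjects, x$n_case, x$n_ctrl))
  cat(sprintf("  mtry %d, min node size %d, OOB balanced accuracy %.3f\n",
              x$params$mtry, x$params$min_node_size,
              x$oob_balanced_accuracy))
  invisible(x)
}

#' Per-tree sets of split features
#'
#' @param forest an `epi_forest`.
#' @return list (one element per tree) of sorted unique feature indices
#'   used as split variables in that tree.
#' @export
tree_feature_sets <- function(forest) {
  lapply(forest$trees, function(tr) sort(unique(tr$feature[!is.na(tr$feature)])))
}

#' Tree selection frequency
#'
#' `p_i` = fraction of trees whose split set contains feature i; the
#' building block of the paired-selection-frequency expectation.
#'
#' @param forest an `epi_forest`.
#' @return numeric vector of length `n_features`.
#' @export
selection_frequency <- function(forest) {
  N <- length(forest$trees)
  cnt <- integer(forest$n_features)
  for (fs in tree_feature_sets(forest)) cnt[fs] <- cnt[fs] + 1L
  setNames(cnt / N, forest$feature_names)
}

#' Corrected impurity importance table
#'
#' Per feature: raw (Gini) impurity importance, corrected importance (the
#' accumulated difference between each candidate evaluation's actual best
#' split decrease and that of its within-node permuted shadow copy — a
#' debiasing that is exactly zero-mean for uninformative features
#' regardless of allele frequency), an empirical p-value from the
#' mirrored-null heuristic (all non-positive corrected scores, mirrored to
#' positives, form the null sample; p = (1 + #null >= score) / (1 + #null)),
#' and the tree selection frequency.
#'
#' @param forest an `epi_forest`.
#' @return data.frame `feature`, `importance_raw`, `importance_corrected`,
#'   `pvalue`, `selection_freq`, `candidate_nodes`; attribute
#'   `pvalue_unstable` is TRUE (with a warning) when fewer than 100
#'   features have non-positive corrected scores.
#' @export
corrected_impurity <- function(forest) {
  stopifnot(inherits(forest, "epi_forest"))
  sc <- forest$importance_corrected
  nonpos <- sc[sc <= 0]
  unstable <- length(nonpos) < 100L
  if (unstable)
    warnf("only %d features with non-positive corrected scores; empirical p-values are unstable",
          length(nonpos))
  null_sample <- c(nonpos, -nonpos[nonpos < 0])
  nn <- length(null_sample)
  pv <- vapply(sc, function(s) (1 + sum(null_sample >= s)) / (1 + nn),
               numeric(1))
  out <- data.frame(feature = forest$feature_names,
                    importance_raw = forest$importance_gini,
                    importance_corrected = sc,
                    pvalue = pv,
                    selection_freq = as.numeric(selection_frequency(forest)),
                    candidate_nodes = forest$candidate_nodes,
                    stringsAsFactors = FALSE)
  attr(out, "pvalue_unstable") <- unstable
  out
}

#' Class-weighted OOB permutation importance
#'
#' Mean over trees (with at least one out-of-bag subject) of the drop in
#' class-weighted OOB accuracy when the feature's out-of-bag values are
#' permuted. Trees not containing the feature contribute exactly zero, so a
#' feature absent from every tree has importance 0.
#'
#' If the forest was trained with `compute_permutation = TRUE` the stored
#' values are returned; otherwise they are recomputed from the saved trees
#' (requires `keep_inbag = TRUE` at training time).
#'
#' @param forest an `epi_forest`.
#' @param gm,pheno the training data (only needed for recomputation).
#' @param seed seed for the permutations on recomputation.
#' @return data.frame `feature`, `importance_permutation`.
#' @export
permutation_importance <- function(forest, gm = NULL, pheno = NULL,
                                   seed = forest$params$seed) {
  stopifnot(inherits(forest, "epi_forest"))
  if (!is.null(forest$importance_permutation)) {
    imp <- forest$importance_permutation
  } else {
    if (is.null(gm) || is.null(pheno))
      stopf("forest lacks stored permutation importance; supply gm and pheno")
    if (is.null(forest$inbag))
      stopf("forest was trained without keep_inbag = TRUE")
    X <- if (inherits(gm, "genotype_matrix")) gm$dosages else gm
    storage.mode(X) <- "integer"
    y <- if (inherits(pheno, "phenotype_table")) pheno$status else
      as.integer(pheno)
    imp <- .rf_perm_cpp(forest$trees, X, y, forest$inbag, as.numeric(seed))
  }
  data.frame(feature = forest$feature_names,
             importance_permutation = imp, stringsAsFactors = FALSE)
}

#' Serialize a forest to the documented JSON tree schema
#'
#' Node arrays per tree: 1-based `feature` index (null for leaves), numeric
#' `split` ("dosage <= split goes left"), `left`/`right` child indices,
#' per-node sample counts. Consumed by the epistasis module and external
#' tools.
#'
#' @param forest an `epi_forest`.
#' @param path output JSON path.
#' @export
write_forest_json <- function(forest, path) {
  obj <- list(
    n_trees = length(forest$trees),
    feature_names = forest$feature_names,
    n_case = forest$n_case, n_ctrl = forest$n_ctrl,
    params = forest$params,
    trees = forest$trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a forest back from the JSON tree schema
#'
#' @param path JSON file written by [write_forest_json()].
#' @return an `epi_forest` (without importance accumulators).
#' @export
read_forest_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  trees <- lapply(obj$trees, function(tr) {
    for (nm in c("feature", "left", "right", "n", "n_case", "n_ctrl", "pred"))
      tr[[nm]] <- as.integer(tr[[nm]])
    tr$split <- as.numeric(tr$split)
    tr
  })
  structure(list(trees = trees, feature_names = obj$feature_names,
                 n_features = length(obj$feature_names),
                 n_case = obj$n_case, n_ctrl = obj$n_ctrl,
                 n_subjects = obj$n_case + obj$n_ctrl,
                 params = obj$params),
            class = "epi_forest")
}
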
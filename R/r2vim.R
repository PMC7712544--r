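#' r2VIM consensus feature selection over repeated forests
#'
#' Trains `n_forests` independent class-weighted forests (sequential seed
#' streams) on the supplied feature subset and computes, per forest, each
#' feature's *relative* permutation importance
#' `r_vf = VIM_vf / |min_f' VIM_f'|` — importance in units of the largest
#' negative importance in that forest, which estimates the null scale.
#' Features whose relative importance is at least `threshold` in *every*
#' forest are selected. The final forest is returned intact for the
#' downstream forest-structure epistasis screen.
#'
#' @param gm a [genotype_matrix()] or dosage matrix, already reduced to the
#'   stage-1 screened features.
#' @param pheno aligned [phenotype_table()] or 0/1 vector.
#' @param n_forests number of replicate forests (reference: 11).
#' @param n_trees trees per forest (reference: 10000).
#' @param mtry_fraction,min_node_fraction forest parameters, see
#'   [train_forest()].
#' @param threshold minimum relative importance required in every forest
#'   (reference: 1).
#' @param seed base seed; forest f uses a derived stream.
#' @return object of class `r2vim_result`: matrices `vim` and
#'   `relative` (features x forests), `min_relative`, logical `selected`,
#'   the `final_forest`, and `denominators` per forest (with a
#'   `fallback` flag when a forest had no negative importance and the
#'   smallest positive magnitude was used instead, which is warned about).
#' @export
run_r2vim <- function(gm, pheno, n_forests = 11, n_trees = 10000,
                      mtry_fraction = 1 / 3, min_node_fraction = 0.1,
                      threshold = 1, seed = 1L) {
  X <- if (inherits(gm, "genotype_matrix")) gm$dosages else gm
  p <- ncol(X)
  if (p < 1L) stopf("no features supplied to r2VIM")
  vim <- matrix(NA_real_, p, n_forests,
                dimnames = list(colnames(X), NULL))
  denom <- numeric(n_forests)
  fallback <- logical(n_forests)
  final_forest <- NULL
  for (f in seq_len(n_forests)) {
    for_f <- train_forest(gm, pheno, n_trees = n_trees,
                          mtry_fraction = mtry_fraction,
                          min_node_fraction = min_node_fraction,
                          seed = derive_seed(seed, f),
                          compute_permutation = TRUE)
    vim[, f] <- for_f$importance_permutation
    mn <- min(vim[, f])
    if (mn < 0) {
      denom[f] <- abs(mn)
    } else {
      pos <- vim[vim[, f] > 0, f]
      fallback[f] <- TRUE
      if (length(pos)) {
        denom[f] <- min(pos)
        warnf("r2VIM forest %d has no negative importance; falling back to smallest positive magnitude", f)
      } else {
        denom[f] <- Inf  # all-zero importances: nothing can be selected
        warnf("r2VIM forest %d has all-zero importances", f)
      }
    }
    if (f == n_forests) final_forest <- for_f
  }
  rel <- relative_importance(vim, denom)
  min_rel <- apply(rel, 1L, min)
  structure(list(vim = vim, relative = rel, min_relative = min_rel,
                 selected = min_rel >= threshold,
                 threshold = threshold,
                 denominators = denom, fallback = fallback,
                 final_forest = final_forest,
                 feature_names = colnames(X) %||% sprintf("f%d", seq_len(p))),
            class = "r2vim_result")
}

#' Relative permutation importance
#'
#' Scales each forest's importances by that forest's null scale: by default
#' the absolute value of its most negative importance, so e.g. VIMs
#' (2.0, -0.5, 1.0) give relative importances (4, -1, 2).
#'
#' @param vim features x forests matrix (or vector, treated as one forest)
#'   of permutation importances.
#' @param denominators optional per-forest denominators; defaults to
#'   `abs(min(vim))` per forest.
#' @return matrix of relative importances with the shape of `vim`.
#' @export
relative_importance <- function(vim, denominators = NULL) {
  vim <- as.matrix(vim)
  if (is.null(denominators))
    denominators <- apply(vim, 2L, function(v) abs(min(v)))
  sweep(vim, 2L, denominators, "/")
}

#' @export
print.r2vim_result <- function(x, ...) {
  cat(sprintf("r2vim_result: %d features x %d forests, %d selected (threshold %g)\n",
              nrow(x$vim), ncol(x$vim), sum(x$selected), x$threshold))
  invisible(x)
}

#' Tabulate r2VIM per-forest importances and selection flags
#'
#' @param x an `r2vim_result`.
#' @return data.frame with one row per feature: per-forest VIM and relative
#'   importance columns, `min_relative`, `selected`.
#' @export
r2vim_table <- function(x) {
  stopifnot(inherits(x, "r2vim_result"))
  out <- data.frame(feature = x$feature_names, stringsAsFactors = FALSE)
  for (f in seq_len(ncol(x$vim))) {
    out[[sprintf("vim_%d", f)]] <- x$vim[, f]
    out[[sprintf("rel_%d", f)]] <- x$relative[, f]
  }
  out$min_relative <- x$min_relative
  out$selected <- x$selected
  out
}
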
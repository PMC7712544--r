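#' Condense interacting pairs into variant networks
#'
#' Networks are the connected components of the pair graph (shared members
#' merge pairs: A-B and A-C condense to the network \{A, B, C\}).
#' Components are ordered deterministically by their smallest member id.
#'
#' @param pairs data.frame with columns `feature_i`, `feature_j` and
#'   optionally `q_ensemble`.
#' @return list of `variant_network` objects, each with `id`, sorted
#'   `members`, and the member `pairs` rows.
#' @export
condense_networks <- function(pairs) {
  if (nrow(pairs) == 0L) return(list())
  members <- sort(unique(c(pairs$feature_i, pairs$feature_j)))
  parent <- seq_along(members)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(match(pairs$feature_i[k], members))
    b <- find(match(pairs$feature_j[k], members))
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(members), find, integer(1))
  comps <- split(members, members[root])
  comps <- comps[order(vapply(comps, min, character(1)))]
  lapply(seq_along(comps), function(k) {
    mem <- sort(comps[[k]])
    rows <- pairs[pairs$feature_i %in% mem & pairs$feature_j %in% mem, ,
                  drop = FALSE]
    structure(list(id = k, members = mem, pairs = rows),
              class = "variant_network")
  })
}

#' @export
print.variant_network <- function(x, ...) {
  cat(sprintf("variant_network %d: %s (%d pairs)\n", x$id,
              paste(x$members, collapse = " | "), nrow(x$pairs)))
  invisible(x)
}

#' Fit a conditional-inference-style decision tree on a variant network
#'
#' Recursive partitioning restricted to the network's features, in the
#' architecture of ctree: at each node every candidate feature's genotype
#' table is tested against the outcome with a chi-square independence test,
#' p-values are Bonferroni-adjusted across the candidates tested, and the
#' node splits on the minimum-p feature only if its adjusted p is below
#' `alpha`. The split partition is the binary grouping of the feature's
#' observed genotype levels (for dosages: \{0\}|\{1,2\}, \{0,1\}|\{2\} or
#' \{0,2\}|\{1\}) that minimizes the 2x2 chi-square p-value, subject to
#' both children holding at least `min_leaf` subjects; if no admissible
#' grouping exists the node becomes a leaf.
#'
#' @param network a `variant_network` (or character vector of feature
#'   ids; `"sex"` resolves to the phenotype covariate).
#' @param gm a [genotype_matrix()].
#' @param pheno aligned [phenotype_table()].
#' @param alpha split significance level after Bonferroni adjustment
#'   (default 0.05).
#' @param min_leaf minimum subjects per child (default 20; keeps the
#'   terminal exact tests meaningful).
#' @return object of class `network_tree`: a node table (`feature`,
#'   `left_levels`, `p_adjusted`, children, per-node case/control counts)
#'   plus the cohort totals. Terminal odds ratios are added by
#'   [terminal_odds_ratios()].
#' @export
fit_network_tree <- function(network, gm, pheno, alpha = 0.05,
                             min_leaf = 20) {
  feats <- if (inherits(network, "variant_network")) network$members
           else as.character(network)
  check_aligned(gm, pheno)
  y <- pheno$status
  cols <- lapply(feats, function(id) {
    if (id %in% colnames(gm$dosages)) gm$dosages[, id]
    else if (id == "sex" && !is.null(pheno$sex)) pheno$sex
    else stopf("network feature '%s' not found", id)
  })
  names(cols) <- feats

  nodes <- new.env()
  nodes$tab <- list()
  add_node <- function(rec) {
    nodes$tab[[length(nodes$tab) + 1L]] <- rec
    length(nodes$tab)
  }

  grow <- function(idx) {
    yy <- y[idx]
    me <- add_node(list(feature = NA_character_, left_levels = NA,
                        p_adjusted = NA_real_, left = NA_integer_,
                        right = NA_integer_, n = length(idx),
                        n_case = sum(yy), n_ctrl = sum(1 - yy)))
    if (length(idx) < 2L * min_leaf || length(unique(yy)) < 2L) return(me)
    # candidate association tests
    pvals <- rep(NA_real_, length(feats))
    for (k in seq_along(feats)) {
      g <- cols[[k]][idx]
      if (length(unique(g)) < 2L) next
      pvals[k] <- suppressWarnings(
        chisq.test(table(g, yy), correct = FALSE)$p.value)
    }
    tested <- which(!is.na(pvals))
    if (!length(tested)) return(me)
    p_adj <- pmin(1, pvals * length(tested))
    best_k <- tested[which.min(pvals[tested])]
    if (p_adj[best_k] >= alpha) return(me)
    # best admissible binary grouping of the winning feature's levels
    g <- cols[[best_k]][idx]
    levs <- sort(unique(g))
    groupings <- if (length(levs) == 2L) list(levs[1L]) else
      list(levs[1L], levs[1:2], levs[c(1L, 3L)])
    best_p <- Inf; best_left <- NULL
    for (gr in groupings) {
      inl <- g %in% gr
      nl <- sum(inl); nr <- sum(!inl)
      if (nl < min_leaf || nr < min_leaf) next
      p2 <- suppressWarnings(
        chisq.test(table(inl, yy), correct = FALSE)$p.value)
      if (!is.na(p2) && p2 < best_p) {
        best_p <- p2
        best_left <- gr
      }
    }
    if (is.null(best_left)) return(me)
    inl <- cols[[best_k]][idx] %in% best_left
    lid <- grow(idx[inl])
    rid <- grow(idx[!inl])
    nodes$tab[[me]]$feature <- feats[best_k]
    nodes$tab[[me]]$left_levels <- list(best_left)
    nodes$tab[[me]]$p_adjusted <- p_adj[best_k]
    nodes$tab[[me]]$left <- lid
    nodes$tab[[me]]$right <- rid
    me
  }
  grow(seq_along(y))
  structure(list(nodes = nodes$tab, features = feats,
                 n_case = sum(y), n_ctrl = sum(1 - y),
                 alpha = alpha, min_leaf = min_leaf),
            class = "network_tree")
}

#' Annotate a network tree's terminal nodes with odds ratios
#'
#' In `overall` mode the leaf odds are normalized to the whole cohort's
#' case odds: `OR = (cases_leaf / controls_leaf) / (cases_total /
#' controls_total)` — a root-only tree then has OR = 1. In `complement`
#' mode (the default) the denominator uses the subjects *outside* the
#' leaf, i.e. the odds relative to subjects not carrying that genotype
#' combination. Each leaf also receives a Fisher exact p-value for the
#' leaf-vs-rest 2x2 table. Zero cells get a Haldane-Anscombe 0.5 continuity
#' correction for the odds ratio (flagged).
#'
#' @param tree a `network_tree`.
#' @param mode `"complement"` or `"overall"`; both columns are emitted,
#'   `odds_ratio` aliases the chosen one.
#' @return data.frame with one row per leaf: `node`, `n`, `n_case`,
#'   `n_ctrl`, `or_overall`, `or_complement`, `odds_ratio`, `p_fisher`,
#'   `corrected` (continuity flag), plus the path description `rule`.
#' @export
terminal_odds_ratios <- function(tree, mode = c("complement", "overall")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "network_tree"))
  leaves <- which(vapply(tree$nodes, function(nd) is.na(nd$feature),
                         logical(1)))
  ct <- tree$n_case; cc <- tree$n_ctrl
  rules <- node_rules(tree)
  out <- lapply(leaves, function(li) {
    nd <- tree$nodes[[li]]
    a <- nd$n_case; b <- nd$n_ctrl
    if (a + b == 0L) stopf("empty leaf")
    corrected <- (a == 0L || b == 0L || (ct - a) == 0L || (cc - b) == 0L)
    h <- if (corrected) 0.5 else 0
    or_overall <- ((a + h) / (b + h)) / ((ct + h) / (cc + h))
    or_comp <- ((a + h) / (b + h)) / ((ct - a + h) / (cc - b + h))
    pf <- fisher.test(matrix(c(a, b, ct - a, cc - b), 2L))$p.value
    data.frame(node = li, n = nd$n, n_case = a, n_ctrl = b,
               or_overall = or_overall, or_complement = or_comp,
               odds_ratio = if (mode == "overall") or_overall else or_comp,
               p_fisher = pf, corrected = corrected,
               rule = rules[[li]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# human-readable root-to-node rule strings
node_rules <- function(tree) {
  n <- length(tree$nodes)
  rules <- rep("(root)", n)
  for (k in seq_len(n)) {
    nd <- tree$nodes[[k]]
    if (is.na(nd$feature)) next
    lv <- nd$left_levels[[1L]]
    rules[nd$left] <- paste0(ifelse(rules[k] == "(root)", "",
                                    paste0(rules[k], " & ")),
                             nd$feature, " in {",
                             paste(lv, collapse = ","), "}")
    rules[nd$right] <- paste0(ifelse(rules[k] == "(root)", "",
                                     paste0(rules[k], " & ")),
                              nd$feature, " not in {",
                              paste(lv, collapse = ","), "}")
  }
  rules
}

#' @export
print.network_tree <- function(x, ...) {
  cat(sprintf("network_tree: %d nodes over features %s\n",
              length(x$nodes), paste(x$features, collapse = ", ")))
  rec <- function(k, depth) {
    nd <- x$nodes[[k]]
    pad <- strrep("  ", depth)
    if (is.na(nd$feature)) {
      cat(sprintf("%s[leaf] %d cases / %d controls\n", pad, nd$n_case,
                  nd$n_ctrl))
    } else {
      cat(sprintf("%s%s in {%s} (p_adj %.3g)\n", pad, nd$feature,
                  paste(nd$left_levels[[1L]], collapse = ","),
                  nd$p_adjusted))
      rec(nd$left, depth + 1L)
      rec(nd$right, depth + 1L)
    }
  }
  rec(1L, 0L)
  invisible(x)
}

#' Render a network tree as a Graphviz dot file
#'
#' @param tree a `network_tree`.
#' @param path output .dot path.
#' @param mode odds-ratio normalization for leaf labels.
#' @export
network_tree_dot <- function(tree, path, mode = "complement") {
  ors <- terminal_odds_ratios(tree, mode)
  lines <- c("digraph network_tree {", "  node [shape=box];")
  for (k in seq_along(tree$nodes)) {
    nd <- tree$nodes[[k]]
    lab <- if (is.na(nd$feature)) {
      orv <- ors$odds_ratio[ors$node == k]
      sprintf("%d case / %d ctrl\\nOR=%.2f", nd$n_case, nd$n_ctrl, orv)
    } else {
      sprintf("%s\\np=%.3g", nd$feature, nd$p_adjusted)
    }
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", k, lab))
    if (!is.na(nd$feature)) {
      lv <- paste(nd$left_levels[[1L]], collapse = ",")
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"in {%s}\"];", k, nd$left, lv),
                 sprintf("  n%d -> n%d [label=\"not in {%s}\"];", k,
                         nd$right, lv))
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
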
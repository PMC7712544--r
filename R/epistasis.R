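#' Pair co-occurrence counts from forest structure
#'
#' For every unordered pair of the given features, counts the number of
#' trees whose split set contains both (a feature counts once per tree no
#' matter how many nodes use it).
#'
#' @param forest an `epi_forest`.
#' @param features integer indices (into the forest's feature space) of the
#'   selected features.
#' @return list with `t_ij` (K x K symmetric count matrix), `p_i` (per
#'   selected feature tree selection frequency) and `N` (tree count).
#' @export
pair_cooccurrence <- function(forest, features) {
  features <- as.integer(features)
  K <- length(features)
  N <- length(forest$trees)
  inc <- matrix(0L, N, K)  # tree x feature membership
  fs <- tree_feature_sets(forest)
  for (t in seq_len(N)) inc[t, ] <- as.integer(features %in% fs[[t]])
  t_ij <- crossprod(inc)
  storage.mode(t_ij) <- "integer"
  dimnames(t_ij) <- list(forest$feature_names[features],
                         forest$feature_names[features])
  list(t_ij = t_ij, p_i = setNames(colSums(inc) / N,
                                   forest$feature_names[features]),
       N = N)
}

#' Paired selection frequency test
#'
#' Exact binomial upper tail for observing `t_ij` or more co-occurrences in
#' `N` trees under independence, where the expected per-tree probability is
#' `p_i * p_j`. Pairs selected together *more* often than expected are
#' epistasis candidates; less often suggests correlation (LD).
#'
#' @param t_ij co-occurrence count(s).
#' @param p_i,p_j per-feature tree selection frequencies.
#' @param N number of trees.
#' @return upper-tail p-value(s), `P(X >= t_ij)`, with p = 1 when
#'   `p_i * p_j = 0`.
#' @export
paired_selection_test <- function(t_ij, p_i, p_j, N) {
  e <- p_i * p_j
  p <- ifelse(e <= 0, 1,
              pbinom(t_ij - 1, size = N, prob = pmin(e, 1),
                     lower.tail = FALSE))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Selection asymmetry counts and structural-null trials
#'
#' For every internal node splitting on feature i, feature j may occur in
#' the left daughter subtree (incrementing `n_L`), the right daughter
#' subtree (`n_R`), both, or neither; both orientations (i over j and j
#' over i) are pooled into one unordered-pair statistic. Tree daughters
#' are not structurally exchangeable — the daughter with more internal
#' nodes, class mixture and depth offers more selection opportunities — so
#' alongside the raw counts every *exclusive* occurrence is recorded as a
#' trial with a node-matched empirical null probability `q`: the fraction
#' of the *other* selected features that landed in the left daughter
#' among their exclusive occurrences at the same node. Co-features at the
#' same node are matched controls for everything structural; the
#' calibrated test in [screen_pairs()] is the Poisson-binomial two-sided
#' test over those trials (nodes with fewer than two exclusive features
#' yield no trial).
#'
#' @param forest an `epi_forest`.
#' @param features integer feature indices.
#' @return list of K x K matrices `n_L`, `n_R` (rows = upstream/splitting
#'   feature, unpooled), the pooled symmetric matrices `n_L_pooled`,
#'   `n_R_pooled`, and a `trials` matrix with columns `i`, `j` (indices
#'   into `features`), `q`, `left`, `m` (control count behind `q`).
#' @export
selection_asymmetry <- function(forest, features) {
  features <- as.integer(features)
  res <- .rf_asymmetry_cpp(forest$trees, features)
  nms <- forest$feature_names[features]
  nL <- res$n_left; nR <- res$n_right
  dimnames(nL) <- dimnames(nR) <- list(nms, nms)
  list(n_L = nL, n_R = nR,
       n_L_pooled = nL + t(nL), n_R_pooled = nR + t(nR),
       trials = res$trials)
}

#' Poisson-binomial two-sided test
#'
#' Distribution of a sum of independent Bernoulli trials with
#' probabilities `q`. Up to 200 trials the distribution is evaluated
#' exactly by direct convolution and the two-sided p-value sums all
#' outcomes no more likely than the observed count (the `binom.test`
#' convention, to which it reduces for constant `q`); beyond that a
#' normal approximation with continuity correction is used, where the
#' exact and approximate tails agree to well within the retention
#' tolerances.
#'
#' @param q vector of per-trial success probabilities.
#' @param x observed success count.
#' @param n_controls optional per-trial count of observations behind an
#'   *estimated* `q`; when supplied, the normal branch inflates each
#'   trial's variance by `(1 + 1/n_controls)` to account for the
#'   estimation error of the null probability.
#' @return p-value; 1 for zero trials.
#' @export
poisson_binomial_test <- function(q, x, n_controls = NULL) {
  m <- length(q)
  if (!m) return(1)
  if (m > 200L) {
    mu <- sum(q)
    infl <- if (is.null(n_controls)) 1 else 1 + 1 / pmax(n_controls, 1)
    sg <- sqrt(sum(q * (1 - q) * infl))
    if (sg == 0) return(1)
    z <- (abs(x - mu) - 0.5) / sg
    return(min(1, 2 * stats::pnorm(-max(z, 0))))
  }
  dp <- 1
  for (qi in q) dp <- c(dp * (1 - qi), 0) + c(0, dp * qi)
  px <- dp[x + 1L]
  min(1, sum(dp[dp <= px * (1 + 1e-7)]))
}

#' Two-sided exact binomial asymmetry p-value
#'
#' At `p0 = 0.5` this is the classic symmetric two-sided test (so e.g.
#' `n_L = 10, n_R = 0` gives `2 * 0.5^10`). Tree daughters are not
#' structurally exchangeable, however — the larger/deeper daughter catches
#' more downstream features for *every* pair — so the pair screen calls
#' this with a null proportion calibrated on the forest (see
#' [screen_pairs()]); at `p0 != 0.5` the minimum-likelihood two-sided
#' binomial test (as in `binom.test`) is used.
#'
#' @param n_L,n_R branch counts (vectors allowed).
#' @param p0 null probability of the left daughter.
#' @return p-value(s); 1 when `n_L + n_R = 0`.
#' @export
asymmetry_test <- function(n_L, n_R, p0 = 0.5) {
  n <- n_L + n_R
  if (length(p0) == 1L) p0 <- rep(p0, length(n))
  out <- numeric(length(n))
  for (k in seq_along(n)) {
    out[k] <- if (n[k] == 0) 1 else
      stats::binom.test(n_L[k], n[k], p0[k])$p.value
  }
  out
}

#' Fisher combination of two p-values
#'
#' `X = -2 (ln p1 + ln p2)` referred to the chi-square distribution with 4
#' degrees of freedom, whose survival function has the closed form
#' `exp(-X/2) (1 + X/2)`. Inputs of exactly 0 are clamped to 1e-300 with a
#' warning.
#'
#' @param p1,p2 p-values in (0, 1].
#' @return combined p-value(s).
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 <= 0) || any(p2 <= 0)) {
    warnf("p-value of 0 clamped to 1e-300 in Fisher combination")
    p1 <- pmax(p1, 1e-300)
    p2 <- pmax(p2, 1e-300)
  }
  X <- -2 * (log(p1) + log(p2))
  exp(-X / 2) * (1 + X / 2)
}

# Calibrated pair asymmetry p-values from the trials table.
#
# A trial is one exclusive daughter-side placement of a downstream feature
# j beneath a split on upstream feature i, with the node-matched control
# probability q (smoothed co-feature left-fraction) and its control count
# m. Each downstream feature has its own placement style (predictive
# features chase the class-mixed daughter under every upstream), so the
# pair statistic is a difference of deviations: j's mean (left - q)
# under splits of i minus j's mean deviation under all other upstream
# features, standardized with variances q(1-q)(1 + 1/m); both
# orientations combine as a chi-square with one df per usable
# orientation, deflated by a median-based genomic-control lambda.
# Pairs with no usable orientation get p = 1.
asymmetry_pair_pvalues <- function(trials, i, j) {
  n_pairs <- length(i)
  if (nrow(trials) == 0L) return(rep(1, n_pairs))
  ti <- trials[, "i"]; tj <- trials[, "j"]
  d <- trials[, "left"] - trials[, "q"]
  v <- trials[, "q"] * (1 - trials[, "q"]) * (1 + 1 / trials[, "m"])
  key <- paste(ti, tj)
  n_uv <- tapply(d, key, length)
  d_uv <- tapply(d, key, sum)
  v_uv <- tapply(v, key, sum)
  n_j <- tapply(d, tj, length)
  d_j <- tapply(d, tj, sum)
  v_j <- tapply(v, tj, sum)
  get0 <- function(tab, k) {
    x <- tab[as.character(k)]
    ifelse(is.na(x), 0, x)
  }
  z2 <- function(up, dn) {
    k <- paste(up, dn)
    n1 <- get0(n_uv, k)
    if (n1 == 0) return(NA_real_)
    no <- get0(n_j, dn) - n1
    if (no == 0) return(NA_real_)
    s1 <- get0(d_uv, k); vv1 <- get0(v_uv, k)
    so <- get0(d_j, dn) - s1; vo <- get0(v_j, dn) - vv1
    S <- s1 / n1 - so / no
    V <- vv1 / n1^2 + vo / no^2
    if (V <= 0) return(NA_real_)
    S^2 / V
  }
  X <- numeric(n_pairs)
  df <- integer(n_pairs)
  for (k in seq_len(n_pairs)) {
    zz <- c(z2(i[k], j[k]), z2(j[k], i[k]))
    zz <- zz[!is.na(zz)]
    X[k] <- sum(zz)
    df[k] <- length(zz)
  }
  # genomic-control deflation: pairs are overwhelmingly null, so residual
  # systematic inflation of the chi-squares (sparse-trial normal
  # approximation, leftover dependence) is removed by the median-based
  # lambda per df group; lambda is floored at 1 so significance is only
  # ever deflated, and groups too small for a stable median are left as is
  p <- rep(1, n_pairs)
  for (d in unique(df[df > 0L])) {
    sel <- df == d
    lambda <- if (sum(sel) >= 10L)
      max(1, median(X[sel]) / qchisq(0.5, d)) else 1
    p[sel] <- pchisq(X[sel] / lambda, df = d, lower.tail = FALSE)
  }
  p
}

#' Screen all feature pairs for epistasis from forest structure
#'
#' Evaluates every unordered pair of the selected features: paired
#' selection frequency (one-sided binomial, alternative "greater"),
#' selection asymmetry (two-sided binomial at 0.5), Fisher combination,
#' and Benjamini-Hochberg adjustment across *all* evaluated pairs
#' (LD-like pairs stay in the multiplicity count but can never be
#' retained). A pair is labelled `LD-like` when its observed co-occurrence
#' is below the independence expectation `N p_i p_j`, else
#' `epistasis-candidate`.
#'
#' @param forest an `epi_forest` (typically the final r2VIM forest).
#' @param features integer indices of the selected features.
#' @param fdr_threshold retention threshold on the BH-adjusted combined
#'   p-value (reference: 0.05).
#' @return data.frame of class `pair_screen` with one row per unordered
#'   pair: `feature_i`, `feature_j`, `t_ij`, `expected`, `p_cooccur`,
#'   `n_L`, `n_R`, `p_asym`, `p_fisher`, `q_ensemble`, `direction`,
#'   `retained`.
#' @export
screen_pairs <- function(forest, features, fdr_threshold = 0.05) {
  features <- as.integer(features)
  nms <- forest$feature_names[features]
  K <- length(features)
  empty <- data.frame(feature_i = character(), feature_j = character(),
                      t_ij = integer(), expected = numeric(),
                      p_cooccur = numeric(), n_L = integer(),
                      n_R = integer(), p_asym = numeric(),
                      p_fisher = numeric(), q_ensemble = numeric(),
                      direction = character(), retained = logical(),
                      stringsAsFactors = FALSE)
  if (K < 2L) return(structure(empty, class = c("pair_screen", "data.frame")))

  co <- pair_cooccurrence(forest, features)
  asym <- selection_asymmetry(forest, features)
  ut <- which(upper.tri(co$t_ij), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  t_ij <- co$t_ij[ut]
  e <- co$p_i[i] * co$p_i[j]
  p_co <- paired_selection_test(t_ij, co$p_i[i], co$p_i[j], co$N)
  nL <- asym$n_L_pooled[ut]
  nR <- asym$n_R_pooled[ut]
  p_as <- asymmetry_pair_pvalues(asym$trials, i, j)
  p_f <- fisher_combine(p_co, p_as)
  q <- p.adjust(p_f, method = "BH")
  # a deficit of less than one whole tree is not observable on the count
  # scale, so "fewer than expected" compares against the floor of the
  # expectation (matters when p_i, p_j -> 1 and the expectation crowds N)
  direction <- ifelse(t_ij < floor(co$N * e), "LD-like",
                      "epistasis-candidate")
  out <- data.frame(feature_i = nms[i], feature_j = nms[j],
                    t_ij = as.integer(t_ij), expected = co$N * e,
                    p_cooccur = p_co, n_L = as.integer(nL),
                    n_R = as.integer(nR), p_asym = p_as, p_fisher = p_f,
                    q_ensemble = q, direction = direction,
                    retained = q < fdr_threshold &
                      direction == "epistasis-candidate",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("pair_screen", "data.frame"))
}
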
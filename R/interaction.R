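#' Minimum dummy-coded pairwise interaction p-value for one feature pair
#'
#' For each genotype-level combination (a, b) with a in the observed levels
#' of feature i and b in the observed levels of feature j, indicators
#' `I_a = [g_i == a]` and `I_b = [g_j == b]` are built and the logistic
#' model `logit P(case) = b0 + b1 I_a + b2 I_b + b3 I_a I_b` is compared
#' with the no-interaction model by likelihood-ratio test of `b3 = 0`.
#' Combinations with any of the four `I_a x I_b` cells below `min_cell`
#' subjects are skipped (sparse cells produce separation artifacts). The
#' pair's statistic is the *minimum* p over non-skipped combinations —
#' deliberately not corrected for the within-pair search — or 1 if every
#' combination was skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param pheno aligned [phenotype_table()].
#' @param pair length-2 character vector of feature ids; the id `"sex"`
#'   refers to the phenotype table's sex covariate if not a variant id.
#' @param min_cell minimum subjects per indicator cell (default 10).
#' @return list of class `interaction_result`: `pair`, `min_p`,
#'   `best_combination` (a, b), and a per-combination data.frame
#'   (`a`, `b`, cell counts, `p`, `skipped`, `ridge` flag for fits that
#'   needed the ridge fallback).
#' @export
min_interaction_p <- function(gm, pheno, pair, min_cell = 10) {
  stopifnot(length(pair) == 2L)
  check_aligned(gm, pheno)
  y <- pheno$status
  get_col <- function(id) {
    if (id %in% colnames(gm$dosages)) return(gm$dosages[, id])
    if (id == "sex" && !is.null(pheno$sex)) return(pheno$sex)
    stopf("feature '%s' not found in genotype matrix or covariates", id)
  }
  gi <- get_col(pair[1L])
  gj <- get_col(pair[2L])
  la <- sort(unique(gi))
  lb <- sort(unique(gj))
  combos <- expand.grid(a = la, b = lb)
  res <- data.frame(a = combos$a, b = combos$b, n11 = NA_integer_,
                    n10 = NA_integer_, n01 = NA_integer_,
                    n00 = NA_integer_, p = NA_real_, skipped = TRUE,
                    ridge = FALSE)
  for (k in seq_len(nrow(combos))) {
    Ia <- as.integer(gi == combos$a[k])
    Ib <- as.integer(gj == combos$b[k])
    n11 <- sum(Ia & Ib); n10 <- sum(Ia & !Ib)
    n01 <- sum(!Ia & Ib); n00 <- sum(!Ia & !Ib)
    res[k, c("n11", "n10", "n01", "n00")] <- c(n11, n10, n01, n00)
    if (min(n11, n10, n01, n00) < min_cell) next
    fit <- interaction_lrt(y, Ia, Ib)
    res$p[k] <- fit$p
    res$skipped[k] <- is.na(fit$p)
    res$ridge[k] <- fit$ridge
  }
  ok <- !res$skipped
  if (any(ok)) {
    min_p <- min(res$p[ok])
    best <- res[ok, ][which.min(res$p[ok]), c("a", "b")]
  } else {
    min_p <- 1
    best <- data.frame(a = NA, b = NA)
  }
  structure(list(pair = pair, min_p = min_p,
                 best_combination = c(a = best$a[[1L]], b = best$b[[1L]]),
                 combinations = res),
            class = "interaction_result")
}

# LRT of the interaction coefficient; glm first, small-ridge IRLS fallback
interaction_lrt <- function(y, Ia, Ib) {
  p <- tryCatch({
    f1 <- suppressWarnings(glm(y ~ Ia * Ib, family = binomial()))
    f0 <- suppressWarnings(glm(y ~ Ia + Ib, family = binomial()))
    if (!f1$converged || !f0$converged) stop("no convergence")
    pchisq(f0$deviance - f1$deviance, df = 1L, lower.tail = FALSE)
  }, error = function(e) NA_real_)
  if (!is.na(p)) return(list(p = p, ridge = FALSE))
  d1 <- ridge_logistic_deviance(cbind(1, Ia, Ib, Ia * Ib), y)
  d0 <- ridge_logistic_deviance(cbind(1, Ia, Ib), y)
  if (is.na(d1) || is.na(d0)) return(list(p = NA_real_, ridge = TRUE))
  list(p = pchisq(max(d0 - d1, 0), df = 1L, lower.tail = FALSE),
       ridge = TRUE)
}

# IRLS with a small ridge penalty (intercept unpenalized); returns the
# unpenalized deviance at the penalized optimum
ridge_logistic_deviance <- function(X, y, lambda = 1e-4, maxit = 50) {
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    beta_new <- tryCatch(solve(H, crossprod(X, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) return(NA_real_)
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- plogis(drop(X %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Confirm a table of screened pairs with interaction regressions
#'
#' Runs [min_interaction_p()] on each row of a pair table and applies the
#' Benjamini-Hochberg adjustment across the pairs' minimum p-values.
#' Following the reference analysis, pairs are *reported* regardless of the
#' second FDR pass; `significant` flags `q_interaction < threshold`.
#'
#' @param gm,pheno data as in [min_interaction_p()].
#' @param pairs data.frame with columns `feature_i`, `feature_j` (e.g. the
#'   retained rows of [screen_pairs()]).
#' @param min_cell cell floor, see [min_interaction_p()].
#' @param threshold FDR flag threshold (default 0.05).
#' @return data.frame: `feature_i`, `feature_j`, `min_p`, `best_a`,
#'   `best_b`, `q_interaction`, `significant`; the per-combination tables
#'   are attached as attribute `details`.
#' @export
interaction_confirm <- function(gm, pheno, pairs, min_cell = 10,
                                threshold = 0.05) {
  if (nrow(pairs) == 0L)
    return(data.frame(feature_i = character(), feature_j = character(),
                      min_p = numeric(), best_a = numeric(),
                      best_b = numeric(), q_interaction = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  details <- vector("list", nrow(pairs))
  out <- data.frame(feature_i = pairs$feature_i,
                    feature_j = pairs$feature_j,
                    min_p = NA_real_, best_a = NA_real_, best_b = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    r <- min_interaction_p(gm, pheno,
                           c(pairs$feature_i[k], pairs$feature_j[k]),
                           min_cell = min_cell)
    details[[k]] <- r$combinations
    out$min_p[k] <- r$min_p
    out$best_a[k] <- as.numeric(r$best_combination[["a"]])
    out$best_b[k] <- as.numeric(r$best_combination[["b"]])
  }
  out <- fdr_pass(out, threshold)
  attr(out, "details") <- details
  out
}

#' Benjamini-Hochberg pass over pair minimum p-values
#'
#' @param results data.frame with a `min_p` column.
#' @param threshold significance flag threshold.
#' @return `results` with `q_interaction` and `significant` columns.
#' @export
fdr_pass <- function(results, threshold = 0.05) {
  results$q_interaction <- if (nrow(results)) p.adjust(results$min_p, "BH")
    else numeric(0)
  results$significant <- results$q_interaction < threshold
  results
}
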
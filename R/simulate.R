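#' Specify a synthetic case-control genotype simulation
#'
#' Describes a cohort of unrelated subjects with independent biallelic
#' autosomal SNPs in Hardy-Weinberg proportions, a logistic disease model
#' with planted per-allele (additive) main effects and planted AND/XOR
#' epistatic pairs, and optional LD blocks emulated as noisy copies of an
#' anchor column. The default dimensions mirror a statin-cohort style
#' case-control imbalance (case fraction ~0.29 of 5890 subjects).
#'
#' @param n_subjects number of subjects.
#' @param n_variants number of base variants (LD-block copies are appended
#'   after these, so planted indices always refer to base columns).
#' @param maf_range length-2 range in [0.01, 0.5] from which each variant's
#'   minor allele frequency is drawn uniformly.
#' @param case_fraction target fraction of cases in (0, 1); the baseline
#'   logit is auto-calibrated by bisection so the realized fraction lands
#'   within +/- 0.02 of this target.
#' @param main_effects data.frame with columns `index`, `beta` (per-allele
#'   log-odds), or NULL.
#' @param interactions data.frame with columns `i`, `j`, `model` ("AND" or
#'   "XOR") and `gamma` (interaction log-odds), or NULL.
#' @param ld_blocks data.frame with columns `anchor`, `n_copies`,
#'   `flip_prob`, or NULL. Each copy equals the anchor column with every
#'   subject's value independently resampled from the anchor's HWE
#'   distribution with probability `flip_prob`.
#' @param baseline_logit fixed intercept; `NA` (default) means calibrate.
#' @param carrier_coding `"dominant"` (carrier = dosage >= 1, default) or
#'   `"recessive"` (carrier = dosage == 2) inside the AND/XOR penetrance
#'   functions.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 5890, n_variants = 1000,
                            maf_range = c(0.05, 0.5),
                            case_fraction = 1718 / 5890,
                            main_effects = NULL, interactions = NULL,
                            ld_blocks = NULL, baseline_logit = NA_real_,
                            carrier_coding = c("dominant", "recessive"),
                            seed = 1L) {
  carrier_coding <- match.arg(carrier_coding)
  stopifnot(n_subjects >= 2, n_variants >= 1, length(maf_range) == 2)
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be within [0.01, 0.5]")
  if (case_fraction <= 0 || case_fraction >= 1)
    stopf("case_fraction must be in (0, 1)")
  planted <- c(main_effects$index, interactions$i, interactions$j)
  if (length(planted)) {
    if (anyDuplicated(planted)) stopf("planted indices must be distinct")
    if (any(planted < 1 | planted > n_variants))
      stopf("planted indices out of range")
  }
  if (!is.null(interactions) &&
      !all(interactions$model %in% c("AND", "XOR")))
    stopf("interaction model must be AND or XOR")
  if (!is.null(ld_blocks) &&
      any(ld_blocks$anchor < 1 | ld_blocks$anchor > n_variants))
    stopf("ld block anchors out of range")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_variants = as.integer(n_variants),
                 maf_range = as.numeric(maf_range),
                 case_fraction = case_fraction,
                 main_effects = main_effects,
                 interactions = interactions,
                 ld_blocks = ld_blocks,
                 baseline_logit = baseline_logit,
                 carrier_coding = carrier_coding,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw genotypes under a simulation spec
#'
#' Each base variant is drawn as Binomial(2, maf) per subject, i.e.
#' Hardy-Weinberg proportions (q^2, 2pq, p^2), at a MAF drawn uniformly
#' from `maf_range`. LD-block copies are appended after the base columns.
#'
#' @param spec a [simulation_spec()].
#' @return a [genotype_matrix()]; variant metadata carries synthetic ids
#'   (`snp<k>` for base variants, `snp<k>_ld<c>` for copies).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(derive_seed(spec$seed, 1L), {
    n <- spec$n_subjects
    p <- spec$n_variants
    maf <- runif(p, spec$maf_range[1], spec$maf_range[2])
    dos <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
    ids <- sprintf("snp%05d", seq_len(p))
    chrom <- as.character(rep_len(1:22, p))
    pos <- stats::ave(seq_len(p), chrom, FUN = seq_along) * 1000L
    if (!is.null(spec$ld_blocks)) {
      for (b in seq_len(nrow(spec$ld_blocks))) {
        a <- spec$ld_blocks$anchor[b]
        for (cc in seq_len(spec$ld_blocks$n_copies[b])) {
          col <- dos[, a]
          flip <- runif(n) < spec$ld_blocks$flip_prob[b]
          if (any(flip))
            col[flip] <- rbinom(sum(flip), 2L, maf[a])
          dos <- cbind(dos, col)
          ids <- c(ids, sprintf("snp%05d_ld%d", a, cc))
          chrom <- c(chrom, chrom[a])
          pos <- c(pos, pos[a] + cc)
        }
      }
    }
    meta <- data.frame(id = ids, chrom = chrom, pos = as.integer(pos),
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
    genotype_matrix(dos, meta, sprintf("subj%05d", seq_len(n)))
  })
}

# penetrance indicator for one planted pair under the spec's carrier coding
interaction_indicator <- function(gi, gj, model, coding) {
  ci <- if (coding == "dominant") gi >= 1L else gi == 2L
  cj <- if (coding == "dominant") gj >= 1L else gj == 2L
  if (model == "AND") as.numeric(ci & cj) else as.numeric(xor(ci, cj))
}

#' Draw a case/control phenotype under a simulation spec
#'
#' The disease model is logistic:
#' `logit P(case) = b0 + sum beta * dosage + sum gamma * f(model, gi, gj)`
#' with `f(AND) = 1` iff both pair members carry the risk genotype and
#' `f(XOR) = 1` iff exactly one does. Unless `baseline_logit` is fixed in
#' the spec, `b0` is calibrated by bisection (against a fixed uniform draw,
#' so the result is deterministic) until the realized case fraction is
#' within +/- 0.02 of the target.
#'
#' @param gm genotype matrix from [simulate_genotypes()] with the same spec.
#' @param spec the [simulation_spec()].
#' @return a [phenotype_table()]; the achieved baseline logit is attached
#'   as attribute `baseline_logit`.
#' @export
simulate_phenotype <- function(gm, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_subjects
  if (nrow(gm$dosages) != n) stopf("genotype matrix does not match spec")
  score <- numeric(n)
  if (!is.null(spec$main_effects))
    for (k in seq_len(nrow(spec$main_effects)))
      score <- score + spec$main_effects$beta[k] *
        gm$dosages[, spec$main_effects$index[k]]
  if (!is.null(spec$interactions))
    for (k in seq_len(nrow(spec$interactions)))
      score <- score + spec$interactions$gamma[k] * interaction_indicator(
        gm$dosages[, spec$interactions$i[k]],
        gm$dosages[, spec$interactions$j[k]],
        spec$interactions$model[k], spec$carrier_coding)
  if (!all(is.finite(score))) stopf("non-finite logit score")
  u <- with_seed(derive_seed(spec$seed, 2L), runif(n))
  frac_at <- function(b0) mean(u < plogis(b0 + score))
  if (is.na(spec$baseline_logit)) {
    lo <- -20; hi <- 20
    b0 <- 0
    for (it in 1:60) {
      b0 <- (lo + hi) / 2
      fr <- frac_at(b0)
      if (abs(fr - spec$case_fraction) <= 0.005) break
      if (fr < spec$case_fraction) lo <- b0 else hi <- b0
    }
  } else {
    b0 <- spec$baseline_logit
  }
  status <- as.integer(u < plogis(b0 + score))
  if (length(unique(status)) < 2L)
    stopf("degenerate phenotype: only one class realized")
  ph <- phenotype_table(gm$subject_ids, status)
  attr(ph, "baseline_logit") <- b0
  ph
}

#' Simulate a complete dataset (genotypes, phenotype, truth set)
#'
#' @param spec a [simulation_spec()].
#' @return list with `genotypes`, `phenotypes` and `truth` (a list holding
#'   the planted main-effect indices/ids and planted pairs with model
#'   labels).
#' @export
simulate_dataset <- function(spec) {
  gm <- simulate_genotypes(spec)
  ph <- simulate_phenotype(gm, spec)
  truth <- list(
    main_effects = if (is.null(spec$main_effects)) NULL else
      cbind(spec$main_effects, id = gm$variants$id[spec$main_effects$index]),
    interactions = if (is.null(spec$interactions)) NULL else
      cbind(spec$interactions,
            id_i = gm$variants$id[spec$interactions$i],
            id_j = gm$variants$id[spec$interactions$j]))
  list(genotypes = gm, phenotypes = ph, truth = truth)
}

#' Write a simulated dataset as .tped/.tfam plus a truth-set TSV
#'
#' @param sim result of [simulate_dataset()].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  write_tped(sim$genotypes, sim$phenotypes, prefix)
  tr <- sim$truth
  rows <- list()
  if (!is.null(tr$main_effects))
    rows[[1L]] <- data.frame(kind = "main", id_i = tr$main_effects$id,
                             id_j = NA, model = "ADD",
                             effect = tr$main_effects$beta)
  if (!is.null(tr$interactions))
    rows[[2L]] <- data.frame(kind = "pair", id_i = tr$interactions$id_i,
                             id_j = tr$interactions$id_j,
                             model = tr$interactions$model,
                             effect = tr$interactions$gamma)
  truth_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), id_i = character(), id_j = character(),
               model = character(), effect = numeric())
  write_tsv(truth_df, paste0(prefix, ".truth.tsv"))
  invisible(prefix)
}
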
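#' Genotype matrix container
#'
#' The central data object of the package: a subjects x variants matrix of
#' minor-allele dosages (0/1/2) together with per-variant metadata. All
#' modelling stages (association scan, forests, interaction tests, network
#' trees) consume this object. Missing dosages are not representable; readers
#' must resolve them (error or mode imputation) before construction.
#'
#' @param dosages integer matrix, subjects in rows, variants in columns,
#'   values in \{0, 1, 2\}.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per variant). A `maf` column is (re)computed from the
#'   dosages.
#' @param subject_ids character vector of unique subject identifiers, one
#'   per row of `dosages`.
#' @return An object of class `genotype_matrix` with fields `dosages`,
#'   `variants` (including recomputed `maf`) and `subject_ids`.
#' @export
genotype_matrix <- function(dosages, variants, subject_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (anyNA(dosages))
    stopf("dosage matrix contains missing values; resolve them on read")
  rng <- range(dosages)
  if (rng[1L] < 0L || rng[2L] > 2L)
    stopf("dosages must all be 0, 1 or 2")
  if (nrow(variants) != ncol(dosages))
    stopf("variant metadata rows (%d) != dosage columns (%d)",
          nrow(variants), ncol(dosages))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(dosages))
    stopf("subject_ids length != number of dosage rows")
  if (anyDuplicated(subject_ids))
    stopf("subject ids must be unique")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stopf("variant metadata missing columns: %s",
                          paste(miss, collapse = ", "))
  variants$chrom <- as.character(variants$chrom)
  variants$maf <- compute_maf(dosages)
  rownames(dosages) <- subject_ids
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants,
                 subject_ids = subject_ids),
            class = "genotype_matrix")
}

# minor allele frequency per column; dosage may be coded on either allele,
# so fold at 0.5
compute_maf <- function(dosages) {
  f <- colMeans(dosages) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range: %.4f - %.4f\n",
              min(x$variants$maf), max(x$variants$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Case/control phenotype table
#'
#' @param subject_ids character ids, aligned 1:1 with the genotype matrix.
#' @param status integer 0/1 (1 = case); `NA` allowed on construction but
#'   rejected by the modelling stages.
#' @param sex optional binary covariate (0/1), `NA` allowed.
#' @export
phenotype_table <- function(subject_ids, status, sex = NULL) {
  subject_ids <- as.character(subject_ids)
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L, NA_integer_)))
    stopf("status must be 0, 1 or NA")
  out <- data.frame(subject_id = subject_ids, status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(sex)) {
    sex <- as.integer(sex)
    if (!all(sex %in% c(0L, 1L, NA_integer_))) stopf("sex must be 0, 1 or NA")
    out$sex <- sex
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}

check_aligned <- function(gm, pheno) {
  if (!identical(gm$subject_ids, pheno$subject_id))
    stopf("genotype and phenotype subject ids are not aligned")
  if (anyNA(pheno$status)) stopf("phenotype contains missing status values")
  if (length(unique(pheno$status)) < 2L)
    stopf("phenotype must contain both cases and controls")
  invisible(TRUE)
}

#' Filter variants by minor allele frequency and chromosome
#'
#' Keeps variants with MAF at or above `maf_min` (boundary inclusive) and,
#' if `autosomes_only`, chromosome in 1..22. Column order is preserved and
#' the operation is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency, default 0.01.
#' @param autosomes_only drop non-autosomal variants, default TRUE.
#' @return filtered `genotype_matrix`.
#' @export
filter_variants <- function(gm, maf_min = 0.01, autosomes_only = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  maf <- compute_maf(gm$dosages)
  keep <- maf >= maf_min
  if (autosomes_only)
    keep <- keep & gm$variants$chrom %in% as.character(1:22)
  if (!any(keep)) stopf("all variants removed by filtering")
  genotype_matrix(gm$dosages[, keep, drop = FALSE],
                  gm$variants[keep, , drop = FALSE],
                  gm$subject_ids)
}
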
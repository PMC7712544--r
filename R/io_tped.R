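#' Read PLINK transposed-text genotypes (.tped/.tfam)
#'
#' Dosages are counted as the number of *minor* alleles, with the minor
#' allele determined per variant from the sample allele frequency (an exact
#' tie is broken towards the alphabetically last allele). Phenotypes are read from
#' tfam column 6 with PLINK coding: 1 = control (0), 2 = case (1), 0/-9 =
#' missing. Sex (tfam column 5) is mapped 1 -> 0 (male), 2 -> 1 (female),
#' 0 -> NA.
#'
#' @param tped_path path to the .tped file (whitespace-delimited; each row
#'   `chrom id cM pos` followed by two allele columns per subject).
#' @param tfam_path path to the matching .tfam file.
#' @param missing how to handle missing genotypes (allele code `0`):
#'   `"error"` (default; the modelling stages require complete dosages) or
#'   `"impute"` (per-variant mode imputation).
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `phenotypes` (a [phenotype_table()]).
#' @export
read_tped <- function(tped_path, tfam_path, missing = c("error", "impute")) {
  missing <- match.arg(missing)
  if (!file.exists(tped_path)) stopf("tped file not found: %s", tped_path)
  if (!file.exists(tfam_path)) stopf("tfam file not found: %s", tfam_path)

  fam <- utils::read.table(tfam_path, header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 6L) stopf("tfam must have 6 columns")
  n_subj <- nrow(fam)
  subject_ids <- fam[[2L]]
  phe_raw <- fam[[6L]]
  if (!all(phe_raw %in% c("1", "2", "0", "-9")))
    stopf("tfam phenotype values outside {1, 2, 0, -9}")
  status <- ifelse(phe_raw == "2", 1L, ifelse(phe_raw == "1", 0L, NA_integer_))
  sex_raw <- fam[[5L]]
  sex <- ifelse(sex_raw == "1", 0L, ifelse(sex_raw == "2", 1L, NA_integer_))
  if (all(is.na(sex))) sex <- NULL

  lines <- readLines(tped_path)
  lines <- lines[nzchar(lines)]
  p <- length(lines)
  if (p == 0L) stopf("tped file is empty")
  dos <- matrix(0L, n_subj, p)
  meta <- data.frame(id = character(p), chrom = character(p),
                     pos = integer(p), ref = character(p),
                     alt = character(p), stringsAsFactors = FALSE)
  valid_alleles <- c("A", "C", "G", "T")
  for (v in seq_len(p)) {
    tok <- strsplit(trimws(lines[v]), "[ \t]+")[[1L]]
    if (length(tok) != 4L + 2L * n_subj)
      stopf("tped line %d: expected %d fields, found %d",
            v, 4L + 2L * n_subj, length(tok))
    al <- tok[-(1:4)]
    bad <- setdiff(unique(al), c(valid_alleles, "0"))
    if (length(bad))
      stopf("tped line %d: unknown allele symbol(s): %s",
            v, paste(bad, collapse = ", "))
    a1 <- al[c(TRUE, FALSE)]
    a2 <- al[c(FALSE, TRUE)]
    miss_g <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss_g], a2[!miss_g])
    if (!length(obs)) stopf("tped line %d: all genotypes missing", v)
    tab <- table(factor(obs, levels = sort(unique(obs))))
    alleles <- names(tab)
    if (length(alleles) > 2L)
      stopf("tped line %d: more than two alleles", v)
    if (length(alleles) == 2L) {
      # minor = least frequent; exact tie -> alphabetically last allele
      minor <- if (tab[[1L]] == tab[[2L]]) alleles[2L] else
        alleles[which.min(tab)]
      major <- setdiff(alleles, minor)
      d <- (a1 == minor) + (a2 == minor)
    } else {
      # monomorphic: zero copies of a (non-existent) minor allele
      major <- alleles
      minor <- alleles
      d <- rep(0L, n_subj)
    }
    if (any(miss_g)) {
      if (missing == "error")
        stopf("tped line %d: missing genotype(s); use missing = \"impute\"", v)
      mode_d <- as.integer(names(which.max(table(d[!miss_g]))))
      d[miss_g] <- mode_d
    }
    dos[, v] <- as.integer(d)
    meta$id[v] <- tok[2L]
    meta$chrom[v] <- sub("^chr", "", tok[1L])
    meta$pos[v] <- as.integer(tok[4L])
    meta$ref[v] <- major
    meta$alt[v] <- minor
  }
  ok_chrom <- c(as.character(1:22), "X", "Y", "XY", "MT")
  if (!all(meta$chrom %in% ok_chrom))
    stopf("tped contains chromosomes outside {1..22, X, Y, XY, MT}")
  gm <- genotype_matrix(dos, meta, subject_ids)
  ph <- phenotype_table(subject_ids, status, sex)
  list(genotypes = gm, phenotypes = ph)
}

#' Write genotypes and phenotypes as PLINK .tped/.tfam
#'
#' Dosage 0 is written as homozygous `ref`, 1 as `ref alt`, 2 as homozygous
#' `alt`, so `read_tped()` on the output reproduces the dosages exactly
#' (provided the alt allele is the sample-minor allele, which holds for all
#' matrices produced by the readers and the simulator away from MAF = 0.5
#' ties).
#'
#' @param gm a [genotype_matrix()].
#' @param pheno a [phenotype_table()] aligned with `gm`.
#' @param prefix output path prefix; writes `<prefix>.tped`, `<prefix>.tfam`.
#' @return the prefix, invisibly.
#' @export
write_tped <- function(gm, pheno, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$subject_ids)
  p <- ncol(gm$dosages)
  con <- file(paste0(prefix, ".tped"), "w")
  on.exit(close(con))
  for (v in seq_len(p)) {
    d <- gm$dosages[, v]
    ref <- gm$variants$ref[v]
    alt <- gm$variants$alt[v]
    a1 <- ifelse(d >= 1L, alt, ref)
    a2 <- ifelse(d == 2L, alt, ref)
    geno <- character(2L * n)
    geno[c(TRUE, FALSE)] <- a1
    geno[c(FALSE, TRUE)] <- a2
    writeLines(paste(c(gm$variants$chrom[v], gm$variants$id[v], "0",
                       gm$variants$pos[v], geno), collapse = " "), con)
  }
  sex <- if (!is.null(pheno$sex))
    ifelse(is.na(pheno$sex), "0", ifelse(pheno$sex == 1L, "2", "1"))
  else rep("0", n)
  phe <- ifelse(is.na(pheno$status), "-9",
                ifelse(pheno$status == 1L, "2", "1"))
  fam <- data.frame(pheno$subject_id, pheno$subject_id, 0, 0, sex, phe)
  utils::write.table(fam, paste0(prefix, ".tfam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}
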
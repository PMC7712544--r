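#' Read genotypes from a multi-sample VCF
#'
#' Backed by the Bioconductor VariantAnnotation parser. Biallelic records
#' with a GT field are converted to dosages of the sample-minor allele: ALT
#' dosage is counted first and the column is flipped to REF counting when
#' the ALT frequency exceeds 0.5, so filtering semantics match the MAF-based
#' contract. Multiallelic records are skipped with a reported count, as are
#' records on chromosomes outside \{1..22, X, Y, XY, MT\}.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF 4.x file.
#' @param missing `"error"` (default) or `"impute"` (per-variant mode) for
#'   missing GT calls; `"skip"` drops records containing any missing call.
#' @return a [genotype_matrix()]. The numbers of skipped multiallelic /
#'   off-chromosome / missing-call records are attached as attribute
#'   `skipped`.
#' @export
read_vcf <- function(vcf_path, missing = c("error", "impute", "skip")) {
  missing <- match.arg(missing)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stopf("read_vcf requires the VariantAnnotation package")
  if (!file.exists(vcf_path)) stopf("VCF file not found: %s", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- sub("^chr", "", as.character(GenomeInfoDb::seqnames(rr)))
  pos <- GenomicRanges::start(rr)
  ids <- names(rr)
  ref <- as.character(rr$REF)
  n_alt <- lengths(rr$ALT)
  alt1 <- vapply(seq_along(rr$ALT), function(i)
    as.character(rr$ALT[[i]][1L]), character(1L))

  ok_chrom <- c(as.character(1:22), "X", "Y", "XY", "MT")
  skip_multi <- sum(n_alt != 1L)
  skip_chrom <- sum(n_alt == 1L & !(chrom %in% ok_chrom))
  keep <- n_alt == 1L & chrom %in% ok_chrom

  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ids <- ids[keep]
  ref <- ref[keep]; alt1 <- alt1[keep]

  # GT string -> ALT dosage (phased or unphased diploid calls)
  to_dos <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  dos <- t(apply(gt, 1L, to_dos))  # variants x subjects
  skip_missing <- 0L
  if (anyNA(dos)) {
    if (missing == "error")
      stopf("VCF contains missing GT calls; use missing = \"impute\" or \"skip\"")
    if (missing == "skip") {
      bad <- apply(dos, 1L, anyNA)
      skip_missing <- sum(bad)
      dos <- dos[!bad, , drop = FALSE]
      chrom <- chrom[!bad]; pos <- pos[!bad]; ids <- ids[!bad]
      ref <- ref[!bad]; alt1 <- alt1[!bad]
    } else {
      for (v in which(apply(dos, 1L, anyNA))) {
        dv <- dos[v, ]
        mode_d <- as.integer(names(which.max(table(dv[!is.na(dv)]))))
        dos[v, is.na(dv)] <- mode_d
      }
    }
  }
  if (nrow(dos) == 0L) stopf("no usable biallelic records in VCF")

  # orient to the minor allele
  f_alt <- rowMeans(dos) / 2
  flip <- f_alt > 0.5
  dos[flip, ] <- 2L - dos[flip, ]
  meta <- data.frame(id = ids, chrom = chrom, pos = pos,
                     ref = ifelse(flip, alt1, ref),
                     alt = ifelse(flip, ref, alt1),
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(dos), meta, colnames(gt))
  attr(gm, "skipped") <- c(multiallelic = skip_multi,
                           off_chromosome = skip_chrom,
                           missing_gt = skip_missing)
  gm
}
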
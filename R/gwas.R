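#' Single-variant additive association scan (Cochran-Armitage trend test)
#'
#' The reference comparison for the forest pipeline: each variant is tested
#' with the Cochran-Armitage trend test on the 2x3 case/control x dosage
#' table with scores (0, 1, 2), which is the score test of an additive
#' logistic model with no covariates. Monomorphic variants receive p = 1
#' and are flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param pheno an aligned [phenotype_table()].
#' @return data.frame with one row per variant: `chrom`, `pos`, `id`,
#'   `stat` (chi-square, 1 df), `p`, `monomorphic`.
#' @export
additive_scan <- function(gm, pheno) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_aligned(gm, pheno)
  X <- gm$dosages
  y <- pheno$status
  N <- nrow(X)
  R <- sum(y)            # total cases
  case <- y == 1L
  n_d <- r_d <- matrix(0, 3L, ncol(X))
  for (d in 0:2) {
    m <- X == d
    n_d[d + 1L, ] <- colSums(m)
    r_d[d + 1L, ] <- colSums(m & case)
  }
  s <- c(0, 1, 2)
  num <- colSums(s * (r_d - R * n_d / N))
  s1 <- colSums(s * n_d)
  s2 <- colSums(s^2 * n_d)
  den <- (R / N) * (1 - R / N) * (s2 - s1^2 / N)
  mono <- den <= 0
  stat <- ifelse(mono, 0, num^2 / den)
  p <- ifelse(mono, 1, pchisq(stat, df = 1L, lower.tail = FALSE))
  data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
             id = gm$variants$id, stat = stat, p = p,
             monomorphic = mono, stringsAsFactors = FALSE)
}

#' Write a scan result as a Manhattan-plotter-compatible TSV
#'
#' Columns CHR, BP, SNP, P. The conventional genome-wide significance line
#' for such plots is 5e-8.
#'
#' @param scan result of [additive_scan()].
#' @param path output file.
#' @export
write_gwas <- function(scan, path) {
  write_tsv(data.frame(CHR = scan$chrom, BP = scan$pos, SNP = scan$id,
                       P = scan$p), path)
}
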
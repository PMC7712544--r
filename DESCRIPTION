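Package: epiforest
Title: Random-Forest Epistasis Screening for Case-Control Genotype Data
Version: 0.1.0
Authors@R:
    person("BioStat", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Iterative random-forest feature reduction and selection for
    genome-wide epistasis screening in case-control cohorts. Trains
    class-weighted random forests on minor-allele dosages with
    Nembrini-style corrected impurity importance, applies r2VIM
    (repeated-forest relative permutation importance) consensus
    selection, screens variant pairs for epistasis from forest
    structure (paired selection frequency and selection asymmetry,
    Fisher-combined and FDR-adjusted), confirms pairs with dummy-coded
    logistic interaction tests, and condenses significant pairs into
    variant networks rendered as conditional-inference-style decision
    trees with terminal-node odds ratios. Includes PLINK tped/tfam and
    VCF readers, a Cochran-Armitage single-variant baseline scan, and a
    synthetic case-control genotype simulator with planted additive and
    AND/XOR epistatic effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
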
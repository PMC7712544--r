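# epiforest

Random-forest epistasis screening for case-control genotype data.

Genome-wide association scans test one variant at a time and are blind to
risk that only materializes when two loci interact — the canonical failure
case being an XOR-style pair whose members have no marginal effect at all.
`epiforest` implements an iterative random-forest feature reduction and
selection pipeline that detects such SNP-SNP interactions from the
*structure* of trained forests and condenses them into interpretable
variant networks:

1. **Input / filters** — PLINK `.tped/.tfam` or VCF genotypes as
   minor-allele dosages (0/1/2); autosomal variants with MAF ≥ 0.01.
2. **GWAS baseline** — Cochran–Armitage additive trend scan
   (the single-variant reference comparison).
3. **Stage-1 screen** — class-weighted random forest (weighted bootstrap,
   expected 50:50 case/control in-bag), Nembrini-style *corrected
   impurity* importance (shadow-copy debiased, so uninformative variants
   score zero in expectation regardless of allele frequency), empirical
   p < 0.01 screen.
4. **r2VIM** — repeated forests; a feature is kept when its permutation
   importance is at least 1× the |most negative importance| in *every*
   forest; the final forest is saved.
5. **Epistasis screen** — per variant pair, *paired selection frequency*
   (exact binomial tail of the tree co-occurrence count `t_ij` against
   `N·p_i·p_j`) and *selection asymmetry* (does variant j preferentially
   follow variant i into one daughter branch?), Fisher-combined
   (χ²₄ survival `e^{-X/2}(1+X/2)`), BH-FDR < 0.05; pairs co-occurring
   *less* than expected are labelled LD-like and never retained. The
   asymmetry null is calibrated on the forest itself (node-matched
   co-feature placements), see the methods vignette.
6. **Interaction regressions** — dummy-coded logistic models over all
   genotype-level combinations of each retained pair; LRT of the
   interaction coefficient; minimum p per pair; second BH pass.
7. **Networks** — retained pairs condensed by shared members
   (A|B + A|C → A|B|C); per network a conditional-inference-style decision
   tree with chi-square/Bonferroni splits; terminal nodes report odds
   ratios normalized to the overall case odds (and to the leaf's
   complement) with Fisher exact p-values.

A synthetic-data module simulates the whole stated world — HWE genotypes,
case:control imbalance (default 1718:4172), planted additive effects,
planted AND/XOR pairs with dominant carrier coding, optional LD blocks —
so the full pipeline is testable without controlled-access data.

## Worked example

```r
library(epiforest)

spec <- simulation_spec(
  n_subjects = 4000, n_variants = 1000, maf_range = c(0.3, 0.3),
  case_fraction = 0.3,
  interactions = data.frame(i = 21L, j = 22L, model = "AND", gamma = 1.5),
  seed = 101)

cfg <- pipeline_config(
  simulation = spec, seed = 501, out_dir = "run1",
  stage1 = list(n_trees = 300),            # desk profile; reference: 1000
  r2vim  = list(n_forests = 5, n_trees = 1000))  # reference: 11 x 10000

res <- run_pipeline(cfg)$results
res$pairs[res$pairs$retained, c("feature_i", "feature_j", "t_ij",
                                "expected", "p_asym", "q_ensemble")]
```

On this run the planted AND pair tops the retained set:

```
   feature_i feature_j t_ij expected     p_asym q_ensemble
3   snp00021  snp00022  977    977.1 5.261e-120 1.562e-115
```

977 of the 1000 final-forest trees contain both members, and their
selection asymmetry — the partner is informative only in the carrier
daughter of a split — is what carries the signal. The network stage then
fits a decision tree over the pair's network; its terminal-leaf table
includes, e.g.,

```
     n n_case n_ctrl or_overall or_complement  p_fisher
7  994    563    431     3.0552        4.8774 9.119e-94
```

i.e. subjects with that genotype combination have 4.88 times the odds of
being a case relative to subjects outside the leaf (3.06 times the
overall cohort odds).

Every stage writes a TSV into `out_dir` plus a deterministic
`manifest.json` (stage seeds, counts in/out); the same seed reproduces all
artifacts byte-for-byte.

### Command line

```sh
exec/epiforest simulate --spec spec.json --out sim1
exec/epiforest run-all  --config config.json --out run1 --seed 5
exec/epiforest gwas     --config config.json --out run1   # prefix stages
```

## Notes

The reference-scale configuration (stage-1 forest of 1000 trees; r2VIM
with 11 forests × 10,000 trees; mtry 1/3; 10% node-size limit) is the
package default; tests and examples use a documented smaller "desk
profile". See `vignettes/epiforest-methods.Rmd` for the model, the
debiasing construction, the calibrated asymmetry null, and known
limitations — including why a *pure* XOR pair cannot pass a marginal
stage-1 screen, which bounds end-to-end XOR recovery for any pipeline of
this design.
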
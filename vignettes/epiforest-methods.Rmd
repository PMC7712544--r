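---
title: "Forest-based epistasis screening: models, parameters and design notes"
author: "epiforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest-based epistasis screening: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-variant association scans test each SNP's marginal effect on a binary
outcome and therefore cannot, by construction, find variants whose effect
exists only in combination with another locus. A pure XOR pair — risk raised
when *exactly one* of two loci carries a risk genotype — can have exactly
zero marginal signal while strongly shifting joint penetrance. `epiforest`
implements an iterative random-forest feature reduction and selection
pipeline for case-control genotype data that (1) reduces a genome-scale
variant panel with a fast debiased impurity screen, (2) confirms a small
consensus set with repeated-forest relative permutation importance (r2VIM),
(3) reads candidate SNP-SNP interactions directly out of the final forest's
tree structure, (4) confirms them with dummy-coded logistic interaction
regressions, and (5) condenses the surviving pairs into variant networks
rendered as decision trees whose terminal nodes carry clinically
interpretable odds ratios.

## The disease model of the simulator

The synthetic-data module draws biallelic autosomal SNPs independently in
Hardy-Weinberg proportions, `g ~ Binomial(2, maf)` with the MAF uniform on
a configurable range, and an optional LD block device that appends noisy
copies of an anchor column (each subject's value re-drawn from the anchor's
HWE distribution with probability `flip_prob`). The phenotype follows a
logistic model

logit P(case) = b0 + Σ β·g + Σ γ·f(model, g_i, g_j)

with dominant carrier coding inside the penetrance function: `f(AND) = 1`
iff both members carry at least one minor allele, `f(XOR) = 1` iff exactly
one does (a recessive switch is exposed). `b0` is calibrated by bisection
against a fixed uniform draw until the realized case fraction is within
±0.02 of the target, so the whole dataset is a deterministic function of
the seed. Default dimensions mirror a statin-cohort style imbalance
(case fraction 1718/5890 ≈ 0.29).

What the generator does *not* emulate: population structure, genotyping
error, missingness, realistic LD beyond noisy duplication, and allele
frequency spectra. A green pipeline test therefore establishes that the
statistical machinery behaves as designed on clean, exchangeable genotypes
— not that the pipeline is robust to confounding or cryptic relatedness.

One point where the simulator's arithmetic matters for interpretation:
with dominant coding the carrier frequency is `1-(1-maf)^2`, so a pure XOR
pair is *marginally* invisible when the carrier frequency is 1/2, i.e. at
MAF `1 - sqrt(1/2) ≈ 0.293` — essentially the MAF 0.3 used throughout the
power settings. At MAF 0.5 carriers are 75% of subjects and a pure XOR
pair shows a strong marginal trend; the "marginally invisible" property is
asserted at MAF 0.293 for that reason.

## The forest engine

Forests are grown in compiled code with an own-rolled, fully specified
RNG (splitmix64-seeded xoshiro256++), so a seed determines the forest
byte-for-byte on any platform.

* **Class weighting.** Each bootstrap draw first picks a class with
  probability 1/2, then a subject uniformly within the class — a weighted
  bootstrap in which the expected in-bag class balance is 50:50 regardless
  of cohort imbalance. This matches "equal probability of selecting either
  class from the bootstrapped population" and is verified by the per-tree
  case-draw fractions the engine records.
* **Splits.** Dosages are ordered numeric, so the only candidate
  thresholds are 0.5 and 1.5. At each node `ceil(mtry_fraction · p)`
  candidate features are drawn without replacement in shuffled order; the
  best Gini decrease wins and ties resolve to the first maximum in that
  shuffled order — deterministic under the tree's RNG stream.
* **Depth limit.** `min_node_fraction` (default 0.10) stops splitting at
  nodes at or below that fraction of the cohort. The reference wording
  ("nodes limited to a maximum of 10% of the population to limit tree
  depth") is ambiguous between a minimum-size stop and a maximum terminal
  size; the implemented stop rule yields terminal nodes at or below ~10%
  except where no improving split exists, which satisfies both readings in
  practice, and the parameter is exposed.

### Corrected impurity importance

Raw Gini importance is biased toward common variants: a high-MAF noise SNP
offers more balanced splits and wins more ties, so its accumulated impurity
decrease grows with MAF. The debiased score pairs every candidate
evaluation with a *shadow copy* of the same feature — the feature indexed
through a per-tree permutation of subjects — and accumulates

corrected(f) = Σ over candidate evaluations [ best split decrease of f −
best split decrease of shadow f ]

Because the shadow is attached to subjects (not to bootstrap positions),
the duplication structure of the weighted bootstrap is preserved and the
two terms are exchangeable under the null: the corrected score of an
uninformative feature has exactly zero mean at every MAF. Two realizations
were tried; drawing the shadow's contingency table from the node-margin
hypergeometric (a position-level permutation) is *not* exchangeable under
bootstrap duplication and showed measurable positive bias on pure noise,
which is why the subject-level shadow copy is the one implemented. Note
the symmetric accounting: the actual term accrues at every candidate
evaluation, not only where the feature wins the split — the winner-only
variant is not zero-mean under the null.

Empirical p-values use the mirrored-null heuristic: all non-positive
corrected scores, mirrored to positives, form the null sample, and
p(f) = (1 + #{null ≥ score}) / (1 + #null). With fewer than 100
non-positive scores the p-values are flagged unstable. At desk scale the
heuristic is anti-conservative (roughly 5-10% of null features pass
p < 0.01 rather than 1%); the screen is a funnel stage, so this costs
r2VIM work rather than final false positives, and it is left as specified.

### Permutation importance

Class-weighted OOB permutation importance: per tree, the drop in
class-weighted OOB accuracy after permuting a feature's out-of-bag values,
averaged over trees with OOB subjects; features absent from a tree
contribute exactly zero there. r2VIM divides each forest's importances by
|most negative importance| — the natural null scale, since a feature can
only obtain negative importance by chance — and keeps features whose
relative importance is at least 1 in *every* replicate forest. A forest
with no negative importance falls back to the smallest positive magnitude
with a warning. The r2VIM literature's observed behavior reproduces here:
with few features and many trees the denominator shrinks faster than the
sampling noise of in-sample-correlated features, so r2VIM retains some
noise features that the sample genuinely correlates with the outcome; the
downstream pair screen is what controls final error.

## The epistasis screen

All statistics are functions of the saved final forest's structure only.

* **Paired selection frequency.** `t_ij` counts trees containing both
  features (once per tree); the test is the exact binomial upper tail of
  `t_ij` against `N · p_i p_j`. Pairs observed *below* expectation are
  labelled LD-like and can never be retained — correlated variants split
  interchangeably, not jointly. The label compares `t_ij` against
  `floor(N·e)`: when the strongest features sit in essentially every tree,
  the expectation crowds the maximum attainable count and a literal
  `t < N·e` comparison would label true interacting pairs LD-like on a
  deficit smaller than one tree, which is not an observable deficit on the
  count scale.
* **Selection asymmetry.** For each split on `i`, feature `j` may appear
  in the left or right daughter subtree. Calibrating this statistic was
  the hardest design problem in the package, because daughters are not
  exchangeable at several levels, and each level was diagnosed on
  no-effect simulations before the next refinement:
  (1) a fixed fair-coin null is catastrophically anti-conservative — the
  larger/deeper daughter catches more downstream features for *every*
  pair; (2) a per-node structural share (left daughter's fraction of
  internal nodes, saturating at the feature's forest-level selection
  rate) removes the size effect but not the *purity* effect: every
  outcome-correlated feature preferentially follows any other into the
  class-mixed daughter; (3) node-matched controls — comparing `j`'s side
  choice with the side choices of the other selected features at the very
  same node — absorb size, depth and purity, but confound `j`'s own
  placement style with the pair; so the final statistic is a
  *difference of deviations*: `j`'s mean node-matched deviation beneath
  splits of `i` minus its mean deviation beneath all other upstream
  features (Jeffreys-smoothed leave-one-out control fractions, variances
  `q(1-q)(1+1/m)`), squared and summed over both orientations as a
  chi-square, and finally deflated by a median-based genomic-control
  lambda (floored at 1, applied when at least 10 pairs are available) to
  absorb the sparse-trial normal approximation. Under no-effect
  simulations the resulting p-values are near-uniform while a planted
  AND pair keeps p below 1e-30. `asymmetry_test()` additionally exposes
  the classic fixed-null two-sided binomial (n_L = 10, n_R = 0 gives
  2·0.5¹⁰) for reference and for hand-built examples.
* **Combination and retention.** Fisher's method on the two p-values with
  the closed-form chi-square(4) survival `exp(-X/2)(1+X/2)`;
  Benjamini-Hochberg across *all* evaluated pairs (LD-like pairs stay in
  the multiplicity count); retained = `q < 0.05` and epistasis-candidate.

AND interactions surface mainly through asymmetry (the partner is
informative only in the carrier daughter); XOR pairs surface mainly
through elevated co-occurrence (the partner is informative in both
daughters). The screen therefore detects both planted-pair types when the
members reach the final forest.

### What the funnel can and cannot recover

A planted AND pair (γ = 1.5, MAF 0.3, n = 4000) carries marginal signal,
passes the stage-1 screen and r2VIM essentially always, and its pair is
retained by the screen and used along one root-to-leaf path of its network
tree in virtually every replicate. A *pure* XOR pair at the same settings
carries no marginal signal at all, and the stage-1 corrected-impurity
screen — a marginal method, as the reference analysis itself notes — ranks
its members among noise; the probability that both members survive to the
final forest is below 1%. End-to-end XOR recovery through the full funnel
is therefore structurally near zero in this stated world, and the
corresponding acceptance expectation is left red rather than weakened: the
screen's own XOR power is demonstrated separately by feeding it a forest
in which the pair survived selection (where it is retained reliably).

## Interaction regressions

For each genotype-level combination (a, b) of a retained pair, indicator
variables `I_a = [g_i = a]`, `I_b = [g_j = b]` enter
`logit P(case) = b0 + b1 I_a + b2 I_b + b3 I_a I_b`, and the
likelihood-ratio test of `b3 = 0` gives the combination's p-value.
Combinations with any indicator cell under `min_cell = 10` subjects are
skipped — the reference gives no floor, but without one sparse cells
produce separation artifacts. Non-converging fits retry with a small-ridge
(1e-4) IRLS and are flagged. The pair statistic is the *minimum* p over
combinations, deliberately uncorrected for the 9-way search (the reference
retains the raw minimum); the second BH pass runs across pairs, and —
following the reference tables, which report pairs with interaction FDR
above 0.05 — pairs are reported with a significance flag rather than
filtered.

## Network trees

Retained pairs are condensed into connected components (A|B + A|C →
A|B|C). Per network, a conditional-inference-style tree is fitted over the
network's features only: at each node every candidate feature's genotype
table is chi-square-tested against the outcome, p-values are
Bonferroni-adjusted across candidates tested, and the node splits on the
minimum-p feature when its adjusted p is below `alpha = 0.05`, using the
binary genotype grouping ({0}|{1,2}, {0,1}|{2} or {0,2}|{1} over observed
levels) that minimizes the 2×2 chi-square p, subject to children of at
least `min_leaf = 20` subjects. This reproduces the architecture of
ctree — association-test-driven splits with multiplicity-adjusted stopping
— as a documented surrogate for the permutation-test framework of the
named tool, which is not available here. Terminal nodes report both
normalizations: odds against the whole cohort (`overall`, root-only tree
= 1 exactly) and odds against subjects outside the leaf (`complement`,
the default, matching "relative to those who did not carry those
variants"), plus a Fisher exact leaf-vs-rest p-value; zero cells get a
flagged Haldane-Anscombe 0.5 correction. The reference does not state the
fitting cohort or stopping parameters; all subjects and the defaults above
are explicit stand-ins.

## Numerical and engineering choices

* Seeds: one global seed fans out per stage via a fixed affine map (kept
  below 2^31); every stage can be re-run in isolation and the end-to-end
  manifest is byte-identical under a repeated seed.
* p-value floors: Fisher inputs of exactly 0 clamp to 1e-300 with a
  warning; binomial tails floor at the smallest positive double.
* Degenerate inputs: single-class phenotypes, all-filtered variant sets,
  monomorphic pair members, empty pair lists and zero-split forests all
  have defined, tested behavior (error or empty result, never silence).
* The "desk profile" used by the test-suite pipelines — stage-1 forest of
  300 trees, r2VIM 5 forests × 1000 trees on the screened subset — scales
  the reference configuration (1000 trees; 11 × 10,000) down for a
  single-CPU budget. The r2VIM tree count is kept high relative to the
  other stages because the |most negative importance| denominator is an
  extreme order statistic and destabilizes below ~1000 trees.
* Missing genotypes are a hard error by default (forests do not tolerate
  missing values); per-variant mode imputation is opt-in at read time.

## Known limitations

* The corrected-impurity empirical p-values are anti-conservative at
  moderate feature counts; they gate a funnel stage only.
* r2VIM inherits its literature's in-sample character: features that
  correlate with the outcome by chance in *this* dataset can be selected
  repeatedly; the pair screen, not r2VIM, controls final error.
* The asymmetry statistic conditions on forest structure; its structural
  null (internal-node share) is an approximation to the unknowable
  candidate-sampling process, exact only on average.
* Pure XOR pairs with no marginal signal do not survive marginal
  screening stages; this is a property of the method being reproduced,
  not of this implementation.
* No population-structure correction, covariate adjustment (beyond sex as
  a feature), or higher-order interaction statistics.
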
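---
title: "Methods: pooled-sequencing screen design, decoding and association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-sequencing screen design, decoding and association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
library(dplyr)
```

poolscreen re-implements the computational design of a large case-control
screen for monogenic diabetes mutations in which DNA from 20-24 individuals
was sequenced per pool rather than per person. This document explains the
models and procedures the package implements, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The screening design

The screen sequences a cohort in three stages. Stages 1 and 2 are
*discovery*: individuals are partitioned into phenotype-homogeneous pools
(all-case or all-control, pools of 20 in Stage 1 and 24 in Stage 2), and
variants are detected from pooled read counts. Stage 3 is *validation and
carrier identification*: a subset of cases is re-pooled *orthogonally* —
any Stage-3 pool shares at most 1-2 individuals with any discovery pool —
so that a rare variant seen in one discovery pool and one validation pool
is pinned, by intersection of their member lists, to very few candidate
carriers. This is group testing applied to sequencing.

`design_stratified_pools()` shuffles each stratum under a seed (after
canonical sorting, so input order is irrelevant) and chunks it;
`design_orthogonal_pools()` constructs the re-pooling transversal-first: a
new pool repeatedly takes up to `max_overlap` members from the base pool
with the most unplaced members. Taking from the *largest* remaining group
first preserves the feasibility invariant (no base pool may hold more
unplaced members than `max_overlap` times the remaining new-pool slots);
should a pass fail verification anyway it is restarted reshuffled, and the
certificate — `max_pairwise_overlap()` over all pool pairs — is always
recomputed exhaustively rather than trusted from the construction. Ragged
final pools are allowed; the per-pool chromosome count 2N is always taken
from the design, never assumed global. Stage-3 pools are not forced to be
onset-homogeneous (the design only pools cases there); a strata argument is
available where homogeneity is wanted.

## Pooled allele-count calling

In a pool of N individuals, a site where c of the 2N chromosomes carry the
alt allele yields alt-supporting reads at rate

p_c = (c/2N)(1 - e) + (1 - c/2N) e/3,

where e is the per-base miscall rate; miscalls are spread evenly over the
three non-reference bases, the standard substitution-error convention. The
alt-read count at total depth d is Binomial(d, p_c).
`estimate_pool_allele_count()` maximises this likelihood over c in 0..2N
(a uniform prior makes the MAP equal this MLE), breaking ties toward
smaller c — conservative for rare variants — and reports a quality equal to
the log10 likelihood ratio of the best count against c = 0.

A site becomes a variant (`discover_variants()`) when at least one pool
calls c >= 1 with quality >= `min_quality` in a pool covered at
`min_depth_per_individual` (default 10x per pooled individual, i.e. 200x
for pools of 20). The cohort allele count AC sums per-pool estimates over
depth-passing pools and AF = AC/AN.

**Threshold calibration.** The quality default was calibrated on
simulation against the screen's validation bounds — a false-negative rate
at or below 7% and a per-pool false-positive fraction at or below 3%
(medians over 20 replicate pools of 20 individuals at median depth 600x,
error rate 0.005). On a grid of thresholds, log10-LR 2 gives median FN
5.2-5.7% and median FP 0-2.2% across independent seed streams; higher
thresholds push FN above the bound (a threshold of 5 alone loses ~5% of
true singletons at 600x because a singleton's expected signal is only ~16
reads). The calibrated default is `min_quality = 2`. Simulated false
negatives are dominated, as in the real screen, by low-coverage targets:
the suppressed exons contribute ~3.3 percentage points, threshold losses
the rest.

## Coverage model and QC

Each pool draws a median depth uniformly from 600-970x; per-site depth is
that median times a mean-1 Gamma multiplier with shape 10. Sites belong to
exons (default 215, matching the RefSeq exon count of the 22 genes the
screen analyses — ABCC8 alone has 39), and a configurable set of exons
(default 7) has all pools' depth scaled by 0.05, emulating the handful of
GC-rich, hard-to-capture exons with poor depth in every pool.
`coverage_qc()` reports the per-pool fraction of bases at or above the
per-individual threshold and flags exons whose median depth is low in at
least 90% of pools; on the generator the flagged set is exactly the
suppressed set.

## Parsimonious carrier decoding

For one rare variant, `decode_carriers()` finds every minimal explanation
of the variant-positive pools: an assignment of 1 or 2 alleles to
individuals such that each confidently-called pool's member sum matches its
call. "Parsimonious" is operationalised as minimum number of carriers
first, then minimum total allele count; this reading is enforced against an
exhaustive-enumeration oracle in the tests. The search is exact:
depth-first over the union of positive pools' members with residual
pruning, iteratively deepened over the carrier count (rare variants need
very few carriers, so the search is effectively instantaneous even with
~50 candidates).

Three numerical choices matter:

* **Confidence gating.** Only pools covered at
  `min_depth_per_individual` constrain the solution. Confident *negative*
  pools exclude their members outright; low-coverage negatives are
  ignored, mirroring the real screen where apparent cross-stage
  discrepancies were explained by low Stage-1/2 coverage.
* **Count intervals.** At 600x a pool with c = 1 occasionally draws enough
  alt reads that c = 2 is the likelihood maximum; demanding exact equality
  to the point estimate would brand the truth "discrepant". When raw read
  counts are available the constraint is therefore the *plausible count
  interval* — every count within `count_margin` (default 2) log10 units of
  the maximum-likelihood count; the binomial likelihood is unimodal in c,
  so this set is an interval, and with decisive data it collapses to the
  point estimate. Calls without read-level data are matched exactly.
* **Homozygote ties.** One carrier with two alleles is more parsimonious
  than two carriers with one each, but when both explain the data the
  choice is biological, not combinatorial: both are reported and the call
  is flagged ambiguous (this is how a homozygous rare-variant carrier —
  the Wolfram-syndrome-like case — surfaces rather than being silently
  resolved).

`check_stage_consistency()` decodes from the discovery stages alone,
computes the set of validation-stage totals compatible with any
discovery-consistent assignment restricted to the resequenced individuals,
and classifies the observed total as consistent, discrepant, or
unresolvable (when the only discovery evidence sits in low-coverage
pools). `summarize_partial_attributes()` reports phenotype values over all
candidate carriers: even an ambiguous carrier set often has a single age
at diagnosis, which is the clinically useful quantity.

## Variant classification and registries

`classify_functional()` collapses consequence strings into synonymous,
missense, missense-group (in-frame indels, analysed with missense) and PTV
(nonsense, canonical splice, frameshift); unknown strings become
"unclassified", never dropped. `apply_rare_filter()` is a strict < filter
(default 0.2% MAF) treating missing population frequencies as "not
observed", matching reference-panel absence. `flag_candidate_deleterious()`
keeps variants called damaging by both PolyPhen2 (not benign) and SIFT
(deleterious) below 0.05% population MAF, and verifies — reporting rather
than filtering — the side condition that MutationTaster and CADD (> 20)
agree. ACMG 5-tier classification is an *input* field: re-implementing the
28 ACMG criteria is out of scope, as the original analysis delegates it to
external tooling.

Three registry fixtures transcribe the screen's published variant tables:
protein-truncating variants, all GCK missense variants with per-carrier
ages, and previously reported pathogenic missense variants in
HNF1A/HNF4A/ABCC8/INS with carrier counts by onset subgroup. Carrier
counts are distinct individuals, not alleles, because the screen reports
carrier frequencies. From these fixtures the package reproduces the
headline numbers: 26 case vs 3 control carriers (OR 6.24, Woolf 95% CI
1.9-20.6, Fisher P = 4e-4), 13 early vs 13 late carriers (OR 1.99), 1.8%
early-onset carrier frequency (24/1346), and a 0.5% GCK missense carrier
frequency in cases vs 0.035% in controls.

## Association statistics

Carrier-level tests use the 2x2 table with non-carriers = group size minus
carriers. The odds ratio is the cross-product; the confidence interval is
Woolf's logit interval exp(ln OR ± z sqrt(1/a + 1/b + 1/c + 1/d)) — chosen
because it exactly reproduces the published 1.9-20.6 from the published
counts, which the tests verify; zero cells fall back to the Haldane
correction with a flag. The two-sided Fisher p value uses the
point-probability convention (the sum of hypergeometric probabilities no
larger than the observed table's), cross-checked against full enumeration.

`gene_burden_test()` aggregates rare-variant allele counts per pool and
tests whether case pools carry more rare alleles per chromosome than
control pools. The statistic is the rate difference; the p value is a
one-sided permutation test over pool labels — the pool, not the
individual, is the exchangeable unit, because pooling and library
preparation act on pools — with the (r+1)/(n_perm+1) convention and
within-stage permutation when stages are mixed. The published test's exact
form is not available; this operationalisation is the package's own and is
labelled as such. With tied permutation statistics the convention is
conservative, never anticonservative; the type-I-error simulation
therefore uses dense per-pool counts (Poisson with mean 20 over 60 pools,
1000 null genes, 199 permutations) where ties are rare, yielding rejection
rates within 0.05 ± 0.02 and p values indistinguishable from uniform.
Bonferroni across genes is left to the caller; the original analysis
reports nominal p values.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` reproduces the statistical structure the pipeline
consumes:

* **Cohort layout** — 4016 cases (1346 diagnosed before 40; ties at the
  cutoff are late-onset) and 2872 controls by default; ages are uniform
  within onset groups, controls carry no age.
* **Site frequency spectrum** — true AFs drawn with density proportional
  to f^-1.57 truncated to [1e-6, 0.05]. The exponent and bounds were fixed
  once by numerical integration so that, among variants discovered in a
  Stage-1-sized cohort, ~54% are singletons; the same parameters put
  ~84% at AF <= 0.001 (a single power law cannot match both published
  fractions exactly; 84% sits within the tested tolerance band, and the
  singleton fraction was prioritised because decoding and burden testing
  are driven by singletons).
* **Pathogenic effects** — with cohort sizes fixed by design,
  carrier status is drawn *conditional on* case/control status
  (retrospective sampling): controls carry with the population probability
  q = 1 - (1 - AF)^2 and cases with odds multiplied by the configured OR.
  The population carrier odds ratio then equals the configured effect in
  expectation, which a 500-replicate simulation verifies for OR 6 at the
  screen's sample sizes.
* **Read counts** — the binomial error model above, with the Gamma
  coverage model and suppressed exons.

It does **not** emulate: read-level artefacts (FASTQ, alignment, indel
realignment), capture bias beyond the low-coverage-exon scalar,
batch/lane effects, relatedness or population structure, linkage between
sites, or copy-number variation. Passing tests therefore demonstrate the
pipeline's correctness under its stated error model, not robustness to
alignment artefacts or cryptic structure in real data.

All randomness flows from explicit seed arguments (`withr`-scoped, so the
caller's RNG state is untouched); identical configurations are
bit-identical, which the pipeline's output manifest (file hashes plus
seeds) makes checkable.

## Problem sizes used in the shipped checks

The packaged tests run at deliberately reduced scale, chosen to keep the
whole suite under a few minutes while leaving the measured quantities
stable: 20 replicate pools of 20 individuals over 11,000 candidate sites
for detection-error rates (~50 true variants per pool); a 480-case cohort
with 24 + 20 orthogonal pools for end-to-end singleton recovery; the full
3720-individual Stage-1 layout (186 pools) for discovery sensitivity and
AF recovery; 1000 null genes for burden-test calibration; and 10^4
simulated tables for Woolf coverage. The acceptance script
(`scripts/acceptance.R`) recomputes the detection false-negative rate from
scratch at the same conditions.

## Known limitations

* The binomial caller is a deliberate simplification of joint cross-pool
  calling; it estimates each pool independently and will not match a joint
  caller's behaviour at sites with systematic artefacts shared across
  pools.
* Decoding is combinatorial, not probabilistic: count uncertainty enters
  only through the plausible-count interval, not as a posterior over
  carrier sets.
* The burden test conditions on called allele counts; calling error
  propagates into it unmodelled.
* Registry-based tallies assume one registry variant per carrier (true in
  the packaged fixtures, asserted nowhere else).
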
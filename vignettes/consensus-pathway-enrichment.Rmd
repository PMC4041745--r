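---
title: "Consensus pathway enrichment of GWAS summary statistics"
author: "gwasora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus pathway enrichment of GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasora)
```

## The problem

A genome-wide association scan yields one allelic p-value per SNP.  Single
hits rarely survive genome-wide correction in modestly sized cohorts, so a
common strategy is to ask a coarser question: do the genes tagged by the
scan's *moderately* associated SNPs cluster in known functional categories
(GO terms, KEGG pathways)?  Over-representation analysis (ORA) answers this
by comparing the category composition of a thresholded gene list to a
reference background.

Two nuisances make the naive approach unreliable.  First, the answer depends
on analysis choices that have no canonical value: the p-value cutoff that
defines "associated", and whether a SNP is assigned to a gene only when it
falls inside the transcript or also when it lands in a flanking window that
may contain regulatory sequence.  Second, enrichment tools differ wildly in
statistic, multiple-testing correction and effective stringency, and their
outputs can disagree by an order of magnitude on identical input.

`gwasora` operationalizes a consensus strategy: build **four gene lists**
(two allelic p-value cutoffs, 0.01 and 0.005, each under two annotation
schemes, gene body only and gene body ± 20 kb), enrich every list under
**several method profiles**, and report only the categories enriched in
**all four lists by at least two profiles** as *consistently enriched*.
Requiring agreement across both analysis axes discards categories that owe
their significance to one particular cutoff, window, or statistic.

## SNP-to-gene annotation

Gene models are kept in the BED convention (0-based, half-open); SNP
positions in the PLINK/VCF convention (1-based).  The two meet at exactly
one place: a SNP `s` maps to gene `g` under window width `w` kb iff, on the
same chromosome (after stripping an optional `chr` prefix on either side),

```
start(g) - 1000 w  <=  pos(s) - 1   <  end(g) + 1000 w .
```

The flank is strand-symmetric, so strand never affects mapping.  Both
boundaries are half-open on the right: a SNP exactly `1000 w` bp past the
gene end is *not* mapped.  A SNP inside the overlap of two genes' windows
counts for both genes; the later best-SNP collapse makes this harmless.
The 20 kb default follows the usual reasoning from haplotype-block length
in European-ancestry panels (block averages of roughly 6--16 kb), so a
flanking window of that order captures variants in linkage disequilibrium
with the gene.

Each mapped gene is then collapsed to its single best SNP — the minimum
allelic p-value — which limits the advantage of long genes that harbor many
SNPs.  Ties are broken by smaller position, then lexicographic SNP id, so
output is deterministic.  Gene lists use a **strict** inequality
(`best_p < cutoff`) and are ordered by ascending best p.

Interval queries go through `GenomicRanges::findOverlaps()`; the test suite
checks the mapping against an exhaustive O(n·m) interval scan.

## The enrichment model

For a query list with `n` genes in the background (size `N`) and a category
with `K` background members, of which `k` are in the query, the canonical
ORA statistic is the upper hypergeometric tail

$$p = \sum_{i=k}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

identical to a one-sided Fisher exact test on the 2×2 table.  The tail is
accumulated in log space from the smallest term; this matters because the
strictest profile flags categories at adjusted p below 1e-6 and naive
summation underflows long before the answers stop being meaningful.
Binomial (`P(Bin(n, K/N) >= k)`) and one-sided Pearson chi-square variants
are provided as alternative statistics; the chi-square returns p = 1 for
categories at or below their expected representation (one-sidedness) and
for categories with a zero expected cell (untestable).

The background is the full gene universe of the supplied gene-model file —
the pipeline's certifiable proxy for "whole genome" — and every count
(`k`, `K`, `n`) is taken after intersection with it.  Corrections
(Benjamini–Hochberg, Holm, Bonferroni via `stats::p.adjust`) are applied
across all categories of one collection; GO-like and KEGG-like collections
supplied as separate GMT files are therefore corrected independently, as
the annotation databases are treated by the tools this emulates.  A
category is flagged enriched when its adjusted p falls below the profile's
`alpha` **and** at least `min_genes = 2` query genes are in it; records
failing the gene filter remain in the table for inspection.

### Method profiles

Six heterogeneous web tools cannot be wrapped reproducibly or offline, and
their internal statistics are not published in enough detail to
reconstruct.  What the consensus logic actually needs is a set of
*independent verdicts* spanning the observed behavioral spread.  Four named
profiles provide that:

| profile        | statistic      | correction | alpha  |
|----------------|----------------|------------|--------|
| `strict-1e6`   | hypergeometric | BH         | 1e-6   |
| `strict-1e4`   | binomial       | BH         | 1e-4   |
| `mid-0.01`     | chi-square     | BH         | 0.01   |
| `default-0.05` | hypergeometric | BH         | 0.05   |

The strict thresholds mirror the practice of demoting tools that report
hundreds of categories at nominal 0.05 to a much harsher cutoff, while
permissive exact tests keep their conventional threshold.  Two profiles
share statistic and correction and differ only in alpha, which makes the
subset relationship between their enriched sets a testable invariant.

## The consensus rule

For each profile, the categories enriched in *every* required list are
intersected (an empty enriched set in any list empties the result).  A
category is **consistent** when at least `min_methods = 2` profiles support
it.  Both knobs are configurable; raising either is provably
anti-monotone — it can only shrink the consistent set — and the test suite
enforces this on randomized inputs.  Intersections operate on category ids
only, never on overlap gene content, and ids are never merged across
namespaces.

Consistent categories are then cross-tabulated: a symmetric matrix of
shared-member counts over full category membership, and again restricted to
a query gene list.  Pairwise overlaps are reported as percentages of
*both* categories, since "x% overlap" is ambiguous when the categories
differ in size (685 vs 958 members sharing 185 genes is 27.0% of one and
19.3% of the other).

A separate comparison mode enriches two gene lists simultaneously under one
configuration, keeps categories covered by both (at `min_genes` each),
ranks by the better of the two adjusted p-values, and flags categories
significant in both at an FDR threshold (default 0.05).

## The synthetic scan generator

Every downstream stage is testable offline against a generator with
recorded ground truth.  It emulates a balanced case-control allelic scan —
369 cases vs 369 controls by default, matching the size of the
survival-contrast design this pipeline is aimed at — over a toy genome.

* **Genome**: `n_genes = 2000` genes with geometric lengths (mean 2 kb) and
  geometric intergenic gaps (mean 30 kb), at most 1,000 genes per
  chromosome.  The gap mean is chosen so that a ±20 kb window inflates gene
  lists by roughly a factor of two relative to body-only annotation —
  the order observed when real scans are annotated both ways — rather than
  fusing the whole chromosome into one window.
* **Gene sets**: 200 sets of mean size 25, sampled uniformly with
  replacement and de-duplicated, so sets overlap by chance as GO/KEGG
  categories do (expected pairwise overlap ≈ 25²/2000 ≈ 0.3 genes).
* **SNPs**: Poisson(3) SNPs per gene body plus 30% intergenic SNPs placed
  uniformly in gaps; minor allele frequency uniform on [0.05, 0.5] (the
  lower bound mirrors the conventional MAF < 5% QC exclusion).
* **Null model**: case and control alternate-allele counts are independent
  Binomial(2N, f) draws — alleles are independent, so Hardy–Weinberg holds
  by construction and genotype-level QC has nothing to act on.
* **Signal**: each gene in a chosen fraction (default 0.5) of a causal
  set's members receives one extra causal SNP, placed uniformly inside the
  gene body (never only in the flank, keeping window-scheme comparisons
  interpretable), whose case allele frequency is shifted to
  `f' = θf/(1−f+θf)` for a per-allele odds ratio θ.
* **Test**: the 1-df Pearson chi-square on the 2×2 allele-count table,
  without continuity correction (the standard "allelic" p-value; a Yates
  variant is available behind a flag).  Monomorphic SNPs get p = 1.

Everything is deterministic given the seed: the genome uses `seed`, the
scan `seed + 1`, and the pipeline gives the gene-set draw `seed + 2`.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: linkage disequilibrium between SNPs (each
SNP is independent, so there is no correlation structure for the best-SNP
rule to untangle), genotype-level artifacts (call-rate, batch effects,
HWE violations), population stratification, covariates, and the biological
correlation between functionally related genes.  Real GO/KEGG collections
are also far more nested than uniformly sampled sets.

One calibration subtlety: allele counts are integers, so the allelic test's
p-values live on a lattice.  In a balanced 369 vs 369 design the event
"case and control alternate counts equal" has probability ≈ 2.5% and maps
to p = 1 exactly, which keeps the Kolmogorov–Smirnov distance of null
p-values from uniformity at around 0.025 even though the rejection rate at
any conventional α is nominal.  This is a property of discrete 2×2 tests,
not an artifact of the implementation.

## Numerical and degenerate-input choices

* Hypergeometric tails: `dhyper(log = TRUE)` terms, logsumexp from the
  smallest term; `k = 0` short-circuits to 1.
* The binomial tail uses `pbinom`'s exact summation.
* Unparseable association rows (missing/non-numeric P) are dropped with a
  reported count rather than aborting — real GWAS exports contain NA
  p-values — but out-of-range p, duplicate SNP ids, and inverted BED
  intervals abort with the offending record named.
* Ties everywhere break deterministically (position, then id); all writers
  emit byte-identical output for identical input, with non-integer numerics
  in scientific notation at seven significant digits.
* A category emptied by background intersection is not tested; one emptied
  by gene-list restriction in the overlap stage reports `NA` percentages
  (undefined, not 0%).
* Which association-test column supplies the p-value is left to the caller:
  the reader accepts any single `P` column, making no assumption about the
  model (allelic, trend, genotypic) that produced it.

## Problem sizes used in the automated checks

The statistical checks run at deliberately modest scale: exact-statistic
enumeration up to N = 12 plus 1,000 random tables against Fisher's test;
correction oracles on 1,000 random vectors; calibration on a 20,000-SNP
null scan; and planted-signal recovery on 20 independent scans of the
default 2,000-gene genome at θ = 1.8 (with 20 matched null scans, where
the consistent set is expected to be empty).  These sizes give stable
verdicts in minutes on one core; all of them are re-derived from scratch at
run time by `scripts/acceptance.R`.

## Known limitations

* Gene-score-rank methods (GSEA-style), permutation nulls, and
  topology-aware pathway statistics are out of scope; the consensus is
  over ORA variants only.
* The method profiles emulate the *spread* of independent tools, not any
  specific tool's internals; consensus counts are comparable in spirit, not
  numerically, to a multi-tool study.
* The background is the supplied gene-model universe; if a category's
  members are mostly absent from it, the category is effectively
  untestable.
* With very permissive cutoffs on dense genomes, the windowed gene lists
  can cover a large fraction of the background, and all enrichment
  statistics lose power; the count-summary table (`summarize_counts`) is
  the diagnostic to consult before trusting a run.
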
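---
title: "Delineating cryptic lineages from codominant markers and mtDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating cryptic lineages from codominant markers and mtDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladelim)
```

## The problem and the protocol

Codominant multi-locus data — classically allozymes, where each enzyme locus
is scored as two observable alleles per diploid individual — remain one of
the most decisive sources of evidence for cryptic species: two lineages that
share no alleles at several nuclear loci while living in the same drainage
cannot be exchanging genes. The protocol implemented here works on
individuals, deliberately blind to locality and to mitochondrial haplotype,
so that the groups it finds are discovered rather than presupposed:

1. ordinate all individuals by principal coordinates analysis (PCoA) of
   their genotypes;
2. if the scatter shows discrete clusters, split and re-ordinate each
   cluster separately; recurse until no further split is convincing;
3. flag individuals intermediate between two clusters that carry alleles of
   both — putative F1 hybrids — and leave them out of the lineages;
4. with lineages fixed, quantify diagnosability (fixed allelic differences
   under a shared-allele tolerance, allele-frequency differentials),
   between-group divergence (Nei's unbiased D, with a neighbour-joining
   tree over sites), and mitochondrial divergence (p-distance ranges among
   and within clades).

Steps 1–3 are `stepwise_delineate()`; step 4 is the diagnosability, trees
and sequence-divergence function families, orchestrated by `run_full()`.

## Genotype encoding and missing data

`encode_genotypes()` expands a genotype table into per-(locus, allele)
dosages: a homozygote contributes 1 to its allele's column, a heterozygote
0.5 to each of its two alleles, so the non-missing dosages of a locus sum
to 1 per individual. Inter-individual distance is Euclidean on this
encoding, under which PCoA is exactly PCA of the dosage matrix — a choice
made for transparency (an independent double-centering oracle verifies it in
the test suite) and because no published metric is canonical for this
protocol; the distance is an explicit extension point.

Missing genotypes are mean-imputed **per column within the current analysis
subset**. Re-encoding inside every recursion step matters: imputing from the
full dataset would leak between-group frequency differences into a subset
analysis and manufacture apparent structure. The consumers of allele
frequencies handle missingness differently and explicitly: frequency
denominators count only scored gene copies; Nei's D drops loci scoreable
(2n ≥ 2) in only one group of a pair, pairwise; the p-distance excludes
sites with `N` or `-` in either sequence of a pair (gaps in these
protein-coding alignments denote missing flanks, not indels).

## The split-acceptance rule

The original protocol delimited clusters by eye. The automated rule is
single-linkage clustering on the first two PCoA axes, with the smallest
number of clusters `k >= 2` accepted such that:

* the between-cluster gap (the next single-linkage merge height) exceeds
  `gap_factor` (default 3) times the median within-cluster
  nearest-neighbour distance;
* the same gap exceeds `spread_factor` (default 1.5) times the pooled
  within-cluster RMS deviation from the cluster centroids;
* every cluster has at least `min_cluster` (default 4) members — the
  smallest group size we consider interpretable as a candidate taxon.

The first condition is the classical density-gap criterion. The second was
added after simulation showed the gap criterion alone over-splits
structureless groups: among ~25 points on two noise axes, a local gap just
over 3x the nearest-neighbour spacing arises in several percent of
replicates, yet such a gap is a small fraction of the cloud's own scatter
and no analyst would read it as discrete clusters. Requiring the corridor
between clusters to also exceed ~1.5 within-cluster RMS deviations (about
two within-cluster standard deviations for a 2-D Gaussian cluster) encodes
that visual judgement; on labelled synthetic splits the two regimes are
separated by a wide margin (genuine splits score above ~1.8, spurious local
gaps below ~1.2), so the default sits between them and is not sensitive to
its exact value. The scale is within-cluster — not total — scatter, because
admixed individuals sitting mid-gap inflate the total spread and would
otherwise veto genuine splits.

Three-way structure may resolve as one 3-way split or two nested 2-way
splits depending on relative gap sizes; the leaf partition is identical.
Determinism is guaranteed throughout: rows are processed in lexicographic
id order, eigenvector signs are canonicalised (largest-magnitude coordinate
positive), and re-running on the same input is bit-identical.

## Admixture flagging

At each accepted split, an individual is flagged as putatively admixed
between the two largest children when (a) its projection on the axis
joining the cluster centroids lies strictly between the clusters' convex
ranges, and (b) it carries alleles from both clusters at >= 50% of its
scoreable diagnostic loci. Both criteria are computed against cluster
*cores*: each child is trimmed of small satellite components (single
linkage cut at 3x the child's median nearest-neighbour distance) before
ranges, centroids and allele frequencies are taken. This is essential, not
cosmetic — a hybrid is always a member of one child, so untrimmed convex
ranges cover it by construction, and its introgressed alleles would make
the shared-allele sum of the donor group ~1 and erase the diagnostic-locus
set. An intermediate individual with no scoreable diagnostic locus is
reported with a warning but never flagged: the evidence standard is
allelic, not positional. Only F1-like admixture is modelled (and
simulated); backcrosses dilute the mixed-carriage signal and are out of
scope.

## Diagnosability and Nei's D

A locus is diagnostic between groups A and B at tolerance `tau` when
`max(S_A, S_B) <= tau`, with `S_A` the summed frequency within A of alleles
shared with B. The tolerance phrase "shared alleles summed together for a
locus" admits a second reading — a pooled budget `S_A + S_B <= tau` — which
is available as `mode = "sum"`; the default `max` reading gives each taxon
its own 10% budget, which matches how "fully diagnosable" is used in
practice (a taxon fixed for an allele that is rare in the other taxon is
*not* diagnosable, because most individuals of the second taxon would be
misassigned). Rare alleles are never pooled: the tolerance already absorbs
low-frequency sharing, and a hygiene test verifies that pooling could only
raise the diagnostic count.

Nei's distance uses the small-sample unbiased within-group identities
`(2n Σx² − 1)/(2n − 1)`, clamped to [0, 1] per locus, averaged
arithmetically over the loci scoreable in both groups, with
`I = mean(Jxy)/sqrt(mean(Jx) mean(Jy))` and `D = −ln I`. At small n the
correction can push I above 1 (the worked case x = y = (0.5, 0.5) at
2n = 20 gives I = 19/18); I is then clamped to 1 and D reported as 0 with a
note, so D is never negative. Disjoint fixation gives D = +Inf, which the
NJ builder rejects explicitly rather than propagating.

Whether site-level D matrices should use lineage-pooled frequencies or
per-site frequencies is the caller's choice of grouping vector;
`run_full()` computes lineage-level matrices for the diagnosability table
and site-level matrices for the NJ tree.

## Trees and sequences

`neighbor_joining()` is the standard Q-criterion agglomeration with two
conventions fixed for reproducibility: ties in Q break toward the
lexicographically smallest pair of subtree labels, and a negative branch
length at a join is clamped to zero with the deficit moved to its sibling,
preserving the joined pair's path length (raw pre-clamp lengths are kept as
an attribute). Neither convention fires on additive matrices, on which the
generating tree is recovered exactly — property-tested against random trees
and cross-checked against an independent NJ implementation. Trees are left
unrooted; outgroup rooting is presentation.

p-distances are delegated to `ape::dist.dna(model = "raw",
pairwise.deletion = TRUE)` behind a surface that flags zero-overlap pairs
as undefined instead of erroring, and a brute-force double loop verifies
the matrix in the tests. Clade summaries report min–max ranges among
(lower triangle) and within (diagonal) clades, to 3 decimals as
proportions or 2 as percentages; `prune_alignment()` reproduces
short-window analyses (the 400-bp amplicon case), with the window an
explicit argument because amplicon coordinates are alignment-specific.

## What the generator emulates — and what it does not

`simulate_genotypes()` draws two independent alleles per individual per
locus (Hardy-Weinberg proportions within lineages), then masks genotypes to
missing at the configured rate. The default scenario — three lineages of
25 individuals over two sites each, 40 loci of which 4/6/8 are diagnostic
for the three pairs and 22 carry shared polymorphism at 0.9/0.1, 5%
missing data — mirrors the scale of a serious allozyme study of a cryptic
complex: modest per-lineage samples, a minority of diagnostic loci, most
loci nearly monomorphic. Planted diagnostic loci fix allele *a* in one
lineage of the pair and *b* in the other, with off-pair lineages
polymorphic at 0.7/0.3 so the locus stays diagnostic for the named pair
only (and both alleles are common enough that finite samples essentially
never lose one). `simulate_sequences()` evolves sites independently under
Jukes-Cantor along a supplied tree from a uniform root, with optional
contiguous terminal masking emulating partial amplicons.

The generator deliberately omits inbreeding and Hardy-Weinberg departures,
linkage, null alleles and scoring error, migration and backcrossing, and
among-site rate variation in sequences. Passing tests therefore show that
the statistics and the delineation logic are implemented correctly and
behave as designed under clean population-genetic assumptions — not that
the protocol is robust to those real-data complications; on real data the
provenance log and the pinning mechanism (`pin =`) exist precisely so an
analyst can inspect and override individual decisions.

## Numerical choices and problem sizes

Eigenvalues are retained as positive above a relative threshold of 1e-8 of
the largest; percent contributions are relative to the sum of positive
eigenvalues. Degenerate ordinations (all individuals identical) return
zero axes rather than an error. Single-linkage ties resolve by
lexicographic id order. The test suite and the acceptance script validate
at deliberately modest sizes — oracle comparisons on <= 10-point
configurations and 100 random frequency tables, NJ recovery on 100 random
5–8-leaf trees, and 100 seeded replicates of the default scenario (plus
100 of a two-lineage hybrid scenario) — chosen so the whole validation runs
in about a minute while every statistic is still exercised end to end at
the study's own scale (75 x 40 genotypes, ~1.1-kb alignments).

## Known limitations

* The split rule reads only the first two axes, as the visual protocol
  does; structure expressed purely on axis 3+ of some subset is found only
  after an earlier split isolates it, or not at all.
* Admixture detection is F1-specific by design.
* Nei's D of +Inf (disjoint fixation across all loci) cannot enter an NJ
  tree; such pairs need either more loci or a different distance.
* The genotype parser accepts single-character allele tokens in compact
  form ("ab") and arbitrary tokens in slash form ("a/b"); it does not
  attempt to repair inconsistent allele labelling across files.
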
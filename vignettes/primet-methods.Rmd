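---
title: "Methods: matched primary/metastasis tumor concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched primary/metastasis tumor concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primet)
```

`primet` implements an integrative analysis of matched primary and
metastatic tumor samples, of the kind used to study upper tract urothelial
carcinoma (UTUC) cohorts: consensus somatic variant filtering from
multi-caller whole-exome calls, read-depth copy-number analysis, matched-pair
mutation concordance, transcriptomic subtype and immune-contexture
classification, and single-cell phenotyping of imaging mass cytometry (IMC)
cell tables. This vignette documents the models, the parameters that matter,
the numerical choices, and what the synthetic-data layer does and does not
emulate.

## Consensus somatic variant filtering

Somatic SNVs are accepted when called by at least two of four callers
(MuTect2, Strelka, VarScan, SomaticSniper); indels when called by both
Strelka and VarScan. Variant identity is the `(chrom, pos, ref, alt)` key
after trimming redundant shared bases from indel alleles (callers pad
inconsistently; without normalization the same event fails the two-caller
rule). When callers disagree on read counts we take the caller with the
highest tumor depth, with a fixed caller-name order breaking exact ties, so
the merge is deterministic.

Support-passing candidates then pass through three filters, in order:

* **Depth** — tumor and matched normal depth both ≥ 30 reads.
* **Tumor VAF** — variant allele frequency ≥ 10% *and* more than 5 reads
  carrying the alternate allele.
* **Normal contamination** — normal VAF ≤ 1% *or* at most one mutated read.
  The single-read escape clause is read disjunctively: a deep normal with
  one stray read is not evidence of a germline variant.

Finally, variants present in dbSNP are removed *unless* also present in
COSMIC (a known hotspot is somatic evidence, not a polymorphism), and keys
on a platform artifact blocklist are removed. Every record carries exactly
one `filter_status`, so the PASS set is re-derivable and the filter order
between the database and quality stages cannot change it — a property the
test suite asserts.

Tumor mutational burden is PASS mutations divided by the covered bases, per
million. The TMB-high threshold is deliberately a required argument with no
default: published cutoffs are platform- and disease-calibrated, and
supplying a silent default would invite misuse. The microsatellite
instability score is the percentage of evaluated microsatellite sites
called unstable; samples are MSI-high when the score is strictly greater
than 3.5 (a score of exactly 3.5 is called MSS).

## Copy-number analysis

Capture regions with fewer than 100 reads in *both* tumor and normal are
discarded — the literal both-samples reading; a region adequately covered
in one sample still carries ratio information. Counts are normalized by
each sample's total aligned reads and the per-region
`log2(tumor/normal)` ratio is segmented per chromosome (karyotypic order
1–22, X, Y).

Segmentation is circular binary segmentation: the two-sample pooled-t
statistic between a circular arc and its complement is maximized over all
arcs (an O(n²) scan, implemented in C++ as the field's segmentation
packages do), and the split is accepted when its permutation p-value —
within-chromosome value shuffles — falls below `alpha` (default 0.01,
1000 permutations, minimum segment width 2). Accepted sub-segments are
searched recursively. The permutation loop stops early once the exceedance
count guarantees p ≥ alpha; this is decision-equivalent to the full run.
We deliberately omit the reference implementations' post-hoc
segment-merging ("undo") pass: it is heuristic, and leaving it out keeps
the algorithm fully specified. The practical consequence is a tendency to
split long noisy segments slightly more often at permissive alpha; at the
default alpha this did not occur in any of our benchmark profiles.

Segments with mean log2 ratio strictly above 1 are amplified, strictly
below −0.5 deleted, otherwise neutral. Genes (transcription start/end
intervals, BED or GFF3) are annotated against non-neutral segments by
coordinate overlap; a gene spanning two conflicting non-neutral segments
receives both calls with a conflict flag, since no principled single-call
rule exists without allele-specific data. Group frequency contrasts use
the two-sided Fisher exact test.

## Matched-pair concordance

For each patient, the PASS nonsynonymous variant keys of the primary and a
metastasis are intersected; shared and private counts are expressed as
percentages of the union of the two sets, which is the only denominator
under which the three percentages sum to 100. Patients with several
metastases contribute the mean over their primary–metastasis pairs, so no
patient is weighted by metastasis count. Pathogenic-alteration overlap
restricts both samples' alterations to those labeled oncogenic or likely
oncogenic in a static, file-based oncogenicity lookup — a live database
query would make results irreproducible.

## Transcriptomic classification

**Molecular subtype.** Nearest-centroid classification against six
consensus urothelial classes (LumP, LumNS, LumU, Stroma-rich, Ba/Sq,
NE-like): Pearson correlation between the sample's `log2(FPKM + 1)`
profile and each centroid over the shared genes, label = argmax, and
`unclassified` when the best correlation is below `min_cor` (default
0.15). Pearson correlation is invariant to positive affine transforms of
the log expression, so library-size rescaling cannot change a call. The
centroid matrix is an input file; the synthetic generator emits a matched
centroid set so no external download is ever needed for testing.

**T-cell inflammation.** Expression of an immune signature gene list is
log-transformed (`log2(FPKM + 1)`; the base-2 convention is used
everywhere a log transform is unspecified), median-centered per gene, and
the samples are split into two groups by partitioning around medoids
(k = 2, Euclidean distance on the centered matrix). PAM is our own
BUILD + SWAP implementation with all ties broken toward the lowest index,
so clustering is deterministic without a seed; the reference
implementation in the `cluster` package is used in the test suite as an
independent check of the optimized objective. The cluster with the higher
mean signature expression is labeled *T-cell inflamed*, the other
*T-cell depleted* — labels attach to expression, never to cluster
indices, so sample order is irrelevant. A reference cohort (for example a
large bladder-carcinoma series) can be co-clustered via
`reference_expr`; calls are returned for the query samples only.

**ssGSEA.** Per sample, genes are ranked by expression in decreasing
order; in-set genes add their rank weight (bottom-up rank raised to
`alpha`, default 0.25, normalized to the in-set total) and out-of-set
genes subtract `1/(N − |S|)`. The enrichment score is the integrated
(summed) running sum. Scores depend on ranks only, and each set's scores
are z-standardized across samples. Group comparison defaults to the
unpaired two-sided Mann-Whitney test with a `paired` option for the
signed-rank variant: primary and metastatic groups of unequal size cannot
be paired, so the unpaired test is the sound default; both are provided
because practice varies. Benjamini-Hochberg q ≤ 0.25 flags significance,
the conventional exploratory GSEA threshold.

## Single-cell phenotyping

The interface is the quantified cell table (sample, image, batch, marker
intensities, morphology); mask generation and per-cell quantification
from raw images depend on externally trained segmentation models and are
out of scope. Processing follows the standard IMC recipe:

1. **Filter** — drop cells with solidity exactly 1: perfectly convex
   objects are almost always segmentation artifacts.
2. **Standardize** — `log(1 + x)`, z-score per marker *within each
   image* (absorbing acquisition drift), cap at ±3 (IMC intensity tails
   are heavy), then center and scale each marker globally. A marker
   constant within an image — including single-cell images — gets z = 0
   there, with a warning.
3. **Batch-correct** — parametric empirical-Bayes location/scale
   adjustment (ComBat, via the `sva` package), followed by restoring each
   feature's pre-correction global mean; features are then rescaled, so
   correction happens between the two scaling passes. Single-batch input
   is returned unchanged.
4. **Cluster** — PCA (default 30 components, truncated to the feature
   count with a warning), a batch-balanced kNN graph taking each cell's
   3 nearest neighbors *from every batch* (forcing batches to mix), and
   Leiden community detection at resolution 0.5 under the modularity
   objective. The four functional markers (Ki67, PD-1, PD-L1,
   Granzyme B) are excluded from clustering but kept in the cluster
   profiles. Neighbor search is an exact compiled brute-force scan —
   at the cell counts this package targets (tens of thousands),
   approximate-NN indexes buy nothing.
5. **Metaclusters** — clusters are aggregated by an ordered marker-rule
   table (first match wins; a rule requires its high markers above and
   its low markers at or below a mean-standardized-intensity threshold,
   default 0.5). The shipped table reconstructs a typical urothelial
   panel ontogeny (luminal/basal tumor, T-cell subsets, macrophage,
   immunosuppressive myeloid, fibroblast, endothelial) and is meant to be
   edited per panel — ontogeny mappings are partly qualitative and no
   fixed table can be authoritative.

The basal/luminal plasticity ratio is `log2((KRT5 + ε)/(GATA3 + ε))` per
cell on raw intensities (ε = 0.01 intensity units guards against zeros);
0 means equal expression. Infiltration statistics count cells per image
and metacluster (zeros included), average per sample, and compare
immune-inflamed versus immune-depleted groups with the Mann-Whitney test.

A note on a limit behavior: as the Leiden resolution approaches 0 a
*connected* graph collapses to one community, but the batch-balanced kNN
graph of well-separated populations is disconnected, and modularity never
merges disconnected components — so the cluster count is bounded below by
the number of graph components, not by 1.

## Statistical core

The two-sided Fisher exact test uses the probability-mass rule (sum of
hypergeometric probabilities ≤ the observed table's, with a 1e-7 relative
guard against floating-point ties). The Mann-Whitney test is exact by full
enumeration of the null U distribution (Gaussian-binomial recurrence) for
tie-free samples up to 8 per group, otherwise a normal approximation with
tie and continuity corrections; the signed-rank test enumerates sign
assignments up to n = 12. All of these are verified in the test suite
against base R's independent implementations — exhaustively over every
2×2 table with N ≤ 30 for the Fisher test — and the Mann-Whitney test's
empirical size under the null is checked at 0.05 ± 0.01 over 10,000
seeded replicates.

## The synthetic-data layer

Every input format has a generator with recorded ground truth, which is
what makes the pipeline testable end to end without controlled-access
data:

* **Variant calls** — true variants (shared / primary-private /
  met-private, drawn without replacement from a 10,000-site toy exome so
  keys are unique) plus decoys each violating exactly one retention rule.
  Depths are Poisson with mean 100; tumor VAFs uniform on [0.15, 0.6].
  The tumor depth is floored at 40 reads — at the minimum VAF of 0.15 the
  more-than-5-alt-reads rule needs depth ≥ 40 to hold with certainty, and
  Poisson(100) makes the floor essentially never bind.
* **Capture counts** — regions over 22 toy chromosomes with planted
  multiplicative segments; with noise off the generator returns
  expectations directly so planted ratios are exact. The per-sample
  totals are returned as fixed library-size constants: normalizing by
  on-target column sums would mean-center the copy-number profile and
  bias every planted ratio, whereas real pipelines normalize by total
  aligned reads, which the planted segments barely perturb.
* **Expression** — sample log-expression = subtype centroid + Gaussian
  noise (default sd 0.5, a realistic bulk RNA-seq log-noise scale);
  immune-inflamed samples get a configurable shift (+2 by default in the
  benchmarks) on a dedicated signature gene block; values return to FPKM
  via `2^x − 1`.
* **Cells** — log-normal marker models per population (expressed markers
  ~7 log-sd above background, mirroring the strong separation of IMC
  lineage channels), direct morphology simulation, per-batch
  multiplicative marker factors, and a configurable rate of solidity-1
  artifacts.

What the generators do *not* emulate: mutational signatures and
caller-specific error profiles (callers are exchangeable beyond the
planted artifact classes); GC and mappability waves in coverage;
correlated gene-gene expression structure beyond the centroid blocks;
spatial structure, marker spillover and cell-segmentation errors other
than the solidity artifact. Passing the recovery benchmarks therefore
demonstrates that the *algorithms* are implemented correctly, not that
real data of these kinds will be this clean.

## Benchmark problem sizes

The shipped test suite and acceptance script use: 1000 planted variant
records (30% artifacts), 100-variant concordance pairs, 1000 capture
regions with 1000 CBS permutations, 120-sample expression cohorts,
40-sample immune cohorts, 10,000 Mann-Whitney null replicates, and a
30,000-cell three-population imaging cohort in two batches. These sizes
were chosen to match the scale of a single-patient exome track, a
mid-size expression cohort, and a multi-image IMC experiment while
keeping every benchmark reproducible on one CPU.
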
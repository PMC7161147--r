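---
title: "Methods: selecting and analysing regulatory regions with modern-human-specific changes"
author: "sncRegulome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selecting and analysing regulatory regions with modern-human-specific changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncRegulome)
```

## The analysis this package implements

Comparative paleogenomics yields catalogs of single-nucleotide changes
(SNCs) that separate modern humans from Neanderthals/Denisovans: *modern*
SNCs are derived alleles at fixed or nearly fixed (≥ 90%) frequency in
present-day humans where the archaic genomes carry the ancestral allele,
and *archaic* SNCs are the converse. Crossing such a catalog with maps of
enhancers and promoters active in the developing human cortex, and with
region-to-gene linkage derived from chromatin-conformation (Hi-C) data,
identifies the genes whose regulation may have changed specifically on our
lineage. This package implements that selection procedure and its
downstream statistics as a reusable, testable pipeline:

1. **Selection** (`annotateRegions()`, `selectCandidates()`,
   `adultEnhancerFilter()`, `resolveGeneList()`, `classifyFixedGenes()`):
   a regulatory region is a *candidate* iff it harbors ≥ 1 modern SNC and
   zero archaic SNCs; adult-cortex enhancers additionally must be fully
   contained in an active-enhancer (H3K27ac) peak free of promoter
   (H3K4me3) signal; candidate genes are the union of genes linked to
   candidate regions.
2. **Mutation-density ranking** (`mutationDensity()`, `topFraction()`):
   SNCs per bp for regions ≥ 1000 bp, with the top 5% flagged per class.
3. **Region-set enrichment** (`randomizeRegions()`,
   `permutationOverlapTest()`): a permutation test of overlap between the
   candidate regions and feature sets such as putative selective-sweep
   regions or disease-associated loci.
4. **Gene-set and motif enrichment** (`hypergeomGeneTest()`, `scanPWM()`,
   `motifEnrichment()`).
5. **Co-expression networks** (`qcFilter()` … `detectModules()`,
   `intersectModules()`): a weighted gene co-expression analysis of
   single-cell counts from cortical progenitors, used to place candidate
   genes inside modules of co-expressed genes.

Every input has a synthetic counterpart with planted ground truth
(`simulateRegions()`, `simulateSncs()`, `simulateFeatures()`,
`simulateMotifSequences()`, `simulateCounts()`), so each stage is
validated by exact recovery, calibration, and power experiments rather
than by inspection.

## Coordinates and data model

Region files use the BED convention (0-based, half-open); SNC catalogs and
the worked examples use 1-based positions. Internally everything lives in
`GRanges` (1-based, closed); `bedInterval()` and `pointToInterval()`
perform the conversions, and I/O goes through `rtracklayer`. The two
conventions are observationally identical under this mapping: adjacent
half-open intervals do not overlap, and a 1-based point `pos` is the BED
interval `[pos - 1, pos)`. Zero-length BED records are rejected on read
because their overlap semantics are undefined. Chromosome names are
compared as exact strings after optional `chr`-prefix normalization
(`normalizeChromNames()`), since public region and variant files mix both
conventions.

## The selection procedure

**Frequency classes.** A modern SNC is *fixed* when its derived-allele
frequency is ≥ 1 − ε with ε = 10⁻⁶ (configurable), and *nearly fixed* when
it lies in [0.90, 1 − ε). Source catalogs that report classes rather than
frequencies can carry an explicit `fixed` flag, which overrides the
numeric rule.

**Depletion.** Candidate status requires *zero* archaic SNCs of any
frequency in the region — the filter is a depletion filter, not a
threshold, because the archaic genomes are too few to estimate archaic
allele frequencies reliably.

**The containment filter.** For adult-cortex enhancers the
H3K4me3 disqualification is applied at the level of the containing
H3K27ac peak: an enhancer passes iff it is completely inside ≥ 1 H3K27ac
peak that itself overlaps no H3K4me3 peak. A `mode = "enhancer"` flag
implements the alternative reading (the enhancer itself must be free of
H3K4me3 overlap); the two differ exactly when a peak is H3K4me3-touched
outside the enhancer's own footprint.

**Gene resolution.** Union semantics: a gene enters the candidate list as
soon as one linked region is a candidate. A gene is classed as carrying
fixed enhancer (promoter) changes iff ≥ 1 linked candidate region of that
class contains ≥ 1 fixed modern SNC; the `both` class is the
intersection.

## Density ranking

Density is the exact rational `hits / length`, computed only for regions
≥ 1000 bp (shorter regions make per-bp rates unstable). "Top 5%" is read
as the `ceiling(0.05 · n)` highest densities *within each region class*,
so a small class still yields at least one top candidate. Boundary ties
are broken deterministically — longer region first, then lexicographic
id — because reproducibility requires a total order.

## The permutation overlap test

The observed statistic is the number of query regions overlapping ≥ 1
feature (the conventional region-overlap count; total overlap events
would double-count long features). The null is built by re-placing each
query region uniformly at random, preserving its length: a chromosome is
chosen with probability proportional to its length among chromosomes the
region fits on, and the start is uniform over the
`chromosome length − region length + 1` valid positions. No masking or
gap handling is applied — the toy genomes have none. The empirical
p-value is `(b + 1) / (n + 1)`, which is never zero and has minimum
`1 / (n + 1)` at 10,000 permutations by default.

**Calibration geometry.** An exact permutation p with a discrete
statistic is conservative: `P(p ≤ α) ≤ α`, with the gap governed by the
point masses of the overlap-count distribution. The calibration
experiment shipped with the package therefore uses a feature geometry
under which the count has wide support — 80 features of 30–50 kb on the
8 Mb toy genome against ~200 candidate query regions, giving a null count
with a standard deviation of ~6–7 and per-integer masses below 2%. Under
those conditions the measured type-I error at α = 0.05 over 500 null
datasets is ≈ 0.046 and the p-value distribution is indistinguishable
from uniform (Kolmogorov–Smirnov p ≈ 0.8). With sparse feature sets
(e.g. 50 features of a few kb) the same test is unavoidably conservative
— that is a property of exact permutation tests, not an implementation
artifact.

## Gene-set and motif enrichment

Gene-set over-representation is the upper-tail hypergeometric test
(`stats::phyper`) against a stated universe, adjusted across terms with
Benjamini–Hochberg (`stats::p.adjust`). The graph-aware multiple-testing
correction of g:Profiler ("gSCS") is deliberately not reproduced: it is
tied to a specific ontology-graph structure, whereas BH is transparent and
testable; output columns are named `adj_p` accordingly. At `k = 0` the
upper tail is 1 by definition.

Motif enrichment reduces each region to a binary hit indicator. A hit is
a window (either strand) whose log2-odds score
`Σ log2(p_base / bg_base)` meets the motif threshold (default: 80% of the
maximum achievable score). Profile columns are smoothed with a 10⁻⁴
pseudocount before log-odds so zero entries cannot produce −∞; positions
containing `N` contribute 0 (background-level evidence). Enrichment of
target hits against the pooled target + background totals is one-sided
hypergeometric with BH q-values across motifs; q < 0.05 is the
conventional reporting threshold. The background set is user-supplied —
no GC-matched background is auto-generated; the synthetic generator
controls composition instead.

## Single-cell preprocessing

The QC thresholds mirror the cortical progenitor analysis and are applied
in this order: cells with < 500 detected genes are removed; genes
detected in < 10% of the remaining cells are removed; then cells with
total counts outside [2000, 9000] (inclusive) or mitochondrial fraction
> 5% are removed, with totals recomputed after the gene filter. The
phrase "gene counts per cell" admits two readings — total transcripts or
detected genes — and the neighbouring mitochondrial threshold speaks of
"total gene counts", so total transcripts is the default and
`byDetected = TRUE` switches to the detected-gene reading.

Normalization is `ln(1 + count / total × 10⁶)` (log1p of counts per
million). Cell-cycle scores use expression-matched controls: set genes
are binned by average expression (25 bins), 100 control genes are drawn
per set gene from the same bin, and the score is the difference of set
and control means per cell — centred near zero for unstructured sets.
Covariates (mitochondrial content, cell-cycle scores) are removed by
per-gene ordinary least squares with intercept; residuals are exactly
orthogonal to the covariates, and collinear designs are an error naming
the offending columns. Highly variable genes are those with mean in
[0.5, 8] and variance-to-mean ratio in [0.5, 5], bounds inclusive.

## The co-expression network stage

Gene–gene similarity is the biweight midcorrelation (bicor) with the
standard tuning constant 9 × (raw median absolute deviation); a gene
whose MAD is zero falls back to Pearson centring, and no outlier-cap
(`maxPOutliers`-style) handling is applied. The signed adjacency is
`a_ij = ((1 + r_ij) / 2)^β`; the cortical networks used β = 12–14, and
β = 12 is the default in the package's benchmarks. `pickSoftPower()`
assesses the scale-free fit by binning `log10 k` into 10 equal-occupancy
bins, regressing log-density on log-connectivity, and signing R² against
the slope; the smallest β reaching the target (default 0.8) is chosen,
otherwise the maximizer is returned flagged. Equal-occupancy binning
keeps every fit point supported even when connectivities concentrate.

The topological overlap matrix is
`TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`
with unit diagonal, computed by a single matrix product and verified
against an O(n³) loop in the tests.

**Module detection** is average-linkage hierarchical clustering of
`1 − TOM` with a *static* cut (default height 0.99) followed by merging
clusters smaller than the minimum module size (default 200 genes, as in
the cortical networks) into `"unassigned"`. This deliberately simplifies
the dynamic hybrid tree cut of the reference implementation: on planted
modular structure a static cut is sufficient and exactly reproducible,
and the cut height is exposed for harder trees. Merge heights from
average linkage on non-ultrametric dissimilarities can be locally
non-monotone; heights are made monotone (cumulative maximum) before
cutting, which leaves separable trees unchanged. Labels `M1, M2, …` are
ordered by decreasing module size.

## The synthetic-data generators

The generators emulate the statistical structure the analysis assumes,
not the biology of any real genome:

* **Genome**: two chromosomes of 5 Mb and 3 Mb — room for several
  hundred disjoint regions while keeping brute-force oracles cheap.
* **Regions** (default 300 enhancers + 200 promoters): log-normal lengths
  around 1.5 kb clipped to [200, 5000] bp (straddling the 1000 bp
  density-eligibility bound on purpose), placed disjointly with ≥ 100 bp
  gaps by an exact stick-breaking construction; each region links to 1–3
  genes from a 400-gene catalog so that genes are shared between regions.
* **SNCs**: each region is modern-only (probability 0.3 — these are the
  planted candidates), archaic-contaminated (0.2 — exercising the
  depletion filter), or empty; modern frequencies are 1.0 with
  probability 0.5, otherwise uniform on [0.90, 1 − ε); background SNCs
  (10⁻⁴ per bp) fall strictly outside regions. The manifest records the
  planted truth from the planting decisions themselves, never by
  re-running the filter.
* **Features**: `round(rho · n)` features forced to overlap a random
  candidate, the rest uniform; feature lengths default to 2–8 kb
  (disease-locus scale), with 30–50 kb (sweep-region scale) used in the
  calibration study.
* **Sequences**: i.i.d. background at a given base composition with one
  PWM-sampled motif instance inserted at a uniform position and strand in
  the planted fraction of regions.
* **Counts**: negative binomial (size 2 — single-cell overdispersion is
  needed for the QC and variable-gene thresholds to have bite) around
  log-normal library sizes (median 5000, matching the [2000, 9000] QC
  window); log-rates are `baseline + cluster markers + module loading ×
  per-cell latent factor + phase shifts`. One latent factor per module is
  the simplest generative model whose bicor-based recovery is well-posed.
  Baselines are N(0.8, 0.6) and loadings uniform on [0.8, 1.8]: modules
  are planted on genes expressed well enough that their co-variation is
  observable at the simulated depth (co-expression among genes with ~0
  counts is unrecoverable by construction, which is a fact about
  sequencing depth, not about the network method). Designated `MT-*`
  genes carry ~3% of counts, ~12% in a 10% subset of cells built to fail
  the 5% mitochondrial filter; designated G1/S / G2/M sets have
  phase-dependent means.

What the generators do *not* emulate: real base composition, linkage
disequilibrium, Hi-C contact decay, empty droplets/doublets, or
batch effects. Passing the recovery benchmarks therefore demonstrates the
correctness and calibration of the statistics under their stated
assumptions — not robustness to every artifact of real data.

## Validation experiment sizes

The shipped experiments use: exact filter recovery on 500-region datasets
over 10 seeds; permutation calibration on 500 null datasets (1000
permutations each, sweep-scale features as described above); power at
rho = 0.5 with 50 features over 100 replicates (measured rejection 100%);
density ranking against a sort-and-slice oracle on 1000-region datasets
over 20 seeds; hypergeometric agreement with exhaustive enumeration for
every (N ≤ 15, K, n, k); TOM against the cubic oracle at n = 50–100;
module recovery (4 × 250 genes, 120 cells, β = 12) over 10 seeds with
adjusted Rand index ≥ 0.8 (measured ≈ 1.0); motif detection at planted
fraction 0.5 (100 targets / 500 background) and specificity at fraction 0
over 100 seeds each. These sizes were chosen so the full suite runs
comfortably on a laptop while keeping every Monte-Carlo margin several
standard errors wide.

## Known limitations

* The dynamic hybrid tree cut and the gSCS correction of the reference
  tools are intentionally replaced by simpler, testable procedures
  (static cut + merge; BH). Results on real data will differ in detail.
* Cell clustering is consumed as labels (synthetic truth or any external
  clustering); the package does not reimplement graph clustering, PCA
  significance, or t-SNE.
* The permutation null has no masking/gap model, so applying it to a real
  genome would require adding one.
* `pickSoftPower()` presumes a decaying degree distribution; on networks
  of equally sized, equally loaded modules the signed fit is legitimately
  poor and the chosen β is flagged rather than trusted.
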
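---
title: "Methods: integrative analysis of light-responsive expression, small RNAs and DNA methylation"
author: "lightomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of light-responsive expression, small RNAs and DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`lightomics` implements an integrative desk-scale analysis of how far-red
(FR) versus red (R) light reprograms gene expression, small-RNA (sRNA)
accumulation, and cytosine methylation in *Cuscuta campestris* shoots
during early haustorium development. The package chains eight stages —
synthetic data generation, differential expression, soft clustering,
co-expression networks, functional enrichment, sRNA profiling, DMR
calling, and RdDM-consistency integration — behind `runPipeline()`, and
exposes each stage as plain functions over Bioconductor containers
(`SummarizedExperiment`, `GRanges`, `DNAStringSet`).

Raw sequencing is out of scope: the package consumes gene-level counts,
per-cytosine bisulfite reports, and locus-level sRNA count tables, the
outputs of standard upstream aligners and callers.

# Differential expression

Counts are modeled per gene as negative binomial. Samples are normalized
by median-of-ratios size factors (the ratio of each sample's counts to
the gene-wise geometric mean over genes with all-positive counts, median
over genes). Size factors are defined only up to a common scale; we
normalize them to geometric mean 1, under which rescaling one sample's
library rescales its factor relative to every other sample one-to-one.

The test statistic is a Wald ratio of the log2 fold change of group means
of normalized counts to its delta-method standard error, with a per-gene
method-of-moments dispersion pooled across the two groups and floored at
$10^{-8}$. Two numerical choices matter:

* **t quantiles, not normal.** With four replicates per group the
  moment-based dispersion is noisy; against normal quantiles the raw
  type-I error at $\alpha = 0.05$ runs near 0.10. Referring the statistic
  to a t distribution with $n_A + n_B - 2$ degrees of freedom restores
  calibration (0.044–0.053 across dispersions 0.01–0.3 in the test
  suite's null simulations).
* **Zero-mean floor.** A group mean of zero carries no ratio information;
  means are floored at 1/8 normalized count inside the statistic, and a
  gene with zero counts in both groups is reported with $p = 1$.

A gene is called differentially expressed only when the BH-adjusted
p-value is at most 0.05 **and** $|\log_2 \mathrm{FC}| \ge 1.5$. The
fold-change gate is deliberately part of the decision rule, not a
post-filter. There is no shrinkage and no independent filtering; the
engine is validated by calibration and planted-effect recovery rather
than by equality with any external tool.

# Soft clustering and the FR-DEG set

Genes eligible for clustering must (i) be differentially expressed in at
least one pairwise light-treatment contrast and (ii) show at least five
normalized counts in at least three samples. Profiles are
$\log_2(\mathrm{TPM}+1)$ — the pseudocount makes the transform total —
z-scored per gene.

Fuzzy c-means is implemented in-package: memberships proportional to
inverse squared distance to the power $1/(m-1)$, centroids as
membership$^m$-weighted means, iterated to a $10^{-6}$ centroid-shift
tolerance. The objective $\sum_{ij} u_{ij}^m \lVert x_i - v_j \rVert^2$
is asserted non-increasing at every iteration. A point coincident with a
centroid takes membership 1 there (the continuity limit). Initialization
is k-means++-style seeding from the pipeline seed with ten restarts,
keeping the lowest objective; rows are processed in sorted-id order so
permuting the input permutes the output. The fuzzifier defaults to the
Schwämmle–Jensen empirical rule in (N, D), as the clustering literature
does not fix it; it is overridable.

Genes are retained only where the maximum membership reaches 0.7 and are
hard-assigned by argmax (ties to the lowest cluster index). A cluster is
labeled FR-up (FR-down) when its centroid's FR-minus-R mean exceeds
+0.5 z (falls below −0.5 z) at day 1, day 3, or both; conflicting or flat
centroids are `other`. The margin δ = 0.5 z is a configurable default
standing in for by-eye cluster curation. The FR-DEG set is the union of
retained members of FR-labeled clusters. Redundant clusters are grouped
by single-linkage over centroid Pearson correlation ≥ 0.8 with test
p < 0.05.

# Co-expression networks

Pairwise Pearson correlations of replicate-level $\log_2(\mathrm{TPM}+1)$
profiles are computed separately for the up- and down-regulated FR-DEG
sets, Fisher-Z transformed ($z = \operatorname{atanh} r$), standardized
over all pairs, and thresholded at the 0.945 normal quantile. A raw-PCC
floor (0.98 up / 0.97 down) is applied conjunctively; the two filters are
independently configurable and the PCC implied by the quantile step is
logged, because their interplay is a genuine design freedom. Only
positive correlations form edges by default. Hub queries (first/second
neighborhood, shortest paths) are BFS on the resulting igraph graph, with
lexicographic tie-breaking so reported paths are deterministic. Under
independent Gaussian expression the standardized-Z step retains ≈ 5.5 %
of pairs by construction, which the test suite verifies over 20 seeds.

# Enrichment

Functional-bin enrichment is the hypergeometric upper tail
$P(X \ge k)$ against a universe of annotated genes, BH-corrected jointly
across all tested bins of one query set, with FDR ≤ 0.05 as the
enrichment gate. Over-representation only; genes may carry several bins.
One caveat surfaced by the property tests: BH is *not* idempotent —
re-adjusting an adjusted vector inflates small q-values — so the suite
asserts dominance ($q \ge p$), monotonicity, and equality with a naive
step-up reference instead.

# Small RNAs

Counts are locus × size-class (18–28 nt, fixed) × sample. RPM uses
per-sample totals of genome-matching 18–28 nt reads. Read categorization
follows a priority order (genes, miRNAs, TEs, rRNA, tRNA, then `other`),
counting each read once; an `independent` mode reproduces overlapping
per-index totals since the upstream convention ("sequentially and
individually") is ambiguous. miRNA-family differential accumulation and
sRNA accumulation at arbitrary regions (e.g. DMRs, by ≥ 1 bp overlap)
reuse the NB engine with library-total size factors — the region-level
test is a package choice, as no standard exists — with BH within each
size class.

# Methylome

Cytosine context is read 5′→3′ on the cytosine's own strand: CG, CHG,
CHH (H ≠ G); within 2 bp of a contig end CG remains decidable from one
base and anything else defaults to CHH flagged ambiguous. Methylation
level is methylated/(methylated+unmethylated); zero-coverage sites are
retained in reports but excluded from aggregates. Global levels pool
counts (coverage-weighted) rather than averaging per-site levels.
Metagene profiles bin a strand-aware relative coordinate over
upstream-2kb / body / downstream-2kb; binning the coordinate (rather
than flipping bin indices) makes strand reversal an exact symmetry,
which is asserted on mirrored synthetic genes.

DMR calling substitutes a transparent procedure for binary-segmentation
callers: candidate regions are maximal runs of same-context cytosines
covered in both conditions with inter-cytosine gaps ≤ 300 bp; replicates
are pooled per condition per site; per-region Mann–Whitney U compares
the per-site levels of the two conditions; BH runs across candidates per
context. A reported DMR must pass all three filters — more than 5
cytosines, absolute pooled-level difference above 0.1, and q below
0.05 — and is `hyper` when methylation is higher under FR than R.
Validation is planted-DMR recovery (sensitivity ≥ 0.9, empirical
FDR ≤ 0.10 at the default effect 0.4 and 20× coverage), not equality
with any particular caller. The promoter is defined as the strand-aware
2-kb window upstream of the TSS, clipped at contig ends; upstream tools
leave "promoter" undefined, so this is an explicit, configurable choice.

# RdDM-consistency integration

Every (FR-DEG gene, DMR) pair in which the DMR overlaps the gene's
promoter, an exon, or an intron by ≥ 1 bp becomes a record carrying the
methylation direction, the per-size-class (21/22/24 nt) sRNA direction at
that DMR, and the gene's expression direction (taken from its cluster
label, not re-tested). The verdict is the RdDM expectation: consistent
iff hypermethylation with sRNA accumulation in at least one of the three
classes and expression down, or hypomethylation with sRNA depletion and
expression up; a non-significant sRNA class never supports consistency.
A gene with several DMRs is consistent if any record is; sRNA-silent
DMRs of consistent genes are still reported, flagged, because they are
the signature of non-RdDM methylation turnover. Sankey tallies stratify
(methylation → sRNA → expression) paths per size class and conserve
record counts exactly.

# The synthetic experiment

The generator plants machine-readable ground truth for every stage. Each
of the four generators (annotation, counts, methylome, sRNA) draws from
its own RNG stream derived from the master seed by a fixed offset, so
adding one never perturbs another and all outputs are bit-reproducible.

* **Annotation/genome** — 300 non-overlapping genes (1–4 exons, introns
  derived), 80 TEs that may overlap gene bodies (to exercise the "both"
  feature class), strand-aware 2-kb promoters, 1.6 Mb of uniform random
  DNA.
* **Counts** — NB with dispersion 0.05 (a typical biological-replicate
  value for plant RNA-seq), 5 groups (Ctrl 0 h; R/FR at 23 h and 71 h) ×
  4 replicates. 30 % of genes are planted DEGs following one of ten
  temporal archetypes (FR-specific up/down at day 1, day 3 or both;
  R-specific; shared), with |log2 FC| drawn from [2, 3] — above the 1.5
  gate so planted effects are recoverable by construction.
* **Methylome** — cytosine reports are emitted inside 2 200 discrete
  windows (200 planted DMRs + 2 000 nulls) separated by more than the
  caller's gap, because a genome-wide dense CHH track would merge into a
  single gap-bounded candidate run; discrete windows are the only
  construction under which a defined candidate-region population exists.
  Baselines CG 0.7 / CHG 0.5 / CHH 0.1 are arbitrary configuration
  defaults, documented as not derived from any real genome. Planted
  windows use a 0.5 baseline in their target context (an
  RdDM-target-like locus) so the ±0.4 effect fits in [0, 1] in both
  directions; clipping, if configured to occur, is recorded as the
  realized effect. Coverage is Poisson(20), replicate-pooled.
* **sRNA** — per-locus per-size NB counts peaking at 24 nt with 21/22-nt
  secondary modes; loci at planted RdDM DMRs shift ×4 in the 21/22/24-nt
  classes, with activity floors making those shifts detectable at
  n = 4 after BH across 2 200 loci. A 15-family miRNA table with five
  planted differential families and a family→target map biased toward
  FR-DEGs exercises the family-level operations.
* **RdDM genes** — 12 genes combine a day-3 expression archetype, a
  planted DMR in the promoter or gene body with the opposite methylation
  direction, and a matching sRNA shift, so their triples satisfy the
  consistency rule by construction.

What the generator does **not** emulate: read-level noise and mapping
artifacts, pooling variance across the pooled shoot segments (a single
dispersion stands in), linkage disequilibrium of methylation between
neighboring cytosines, sequence-realistic miRNA hairpins, and genome-wide
methylation outside the windows. Passing tests therefore demonstrate
correctness of the statistical machinery and of signal recovery under the
stated noise model — not performance on real libraries.

# Problem sizes and reproducibility

The test suite and the acceptance script use the default synthetic scale
(300 genes, 2 200 methylation windows, 10 000-gene null simulations, 20
network-null seeds), which gives stable Monte-Carlo margins while keeping
a full run in minutes on one CPU; the pipeline-level determinism check
runs a reduced configuration (80 genes, 200 windows) twice and compares
bytes. Every random draw in the package descends from a single
configuration seed, and two runs with the same configuration produce
byte-identical outputs (provenance files record inputs, parameters and
seed, and contain no timestamps).

# Known limitations

* The DE engine is intentionally minimal: no dispersion shrinkage, no
  outlier handling; with very low counts it is conservative.
* The DMR caller's gap-bounded candidates are not a segmentation; on
  dense genome-wide methylomes candidate regions must be supplied or the
  gap reduced.
* Expression direction in the integration comes from cluster labels, so
  genes excluded by the 0.7-membership filter cannot be flagged even if
  their DMR and sRNA evidence is strong.
* The false-flag rate of the RdDM verdict is governed by the sRNA FDR
  gate at the DMR level; at noisy seeds an occasional null DMR on an
  FR-DEG can pass, which is expected behavior of the 0.05 gate, not a
  defect.
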
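---
title: "Reconstructing a co-binding gene regulatory network from limb bud multi-omics"
author: "limbGRN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a co-binding gene regulatory network from limb bud multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbGRN)
```

## The scientific problem

Transcription factors such as PBX1/2 are expressed almost everywhere in the
vertebrate embryo, yet they drive sharply tissue-specific programs. One
resolution of this paradox is cofactor selection: a broadly bound, promiscuous
factor acquires context-specific function where a domain-restricted cofactor
(HAND2 in the posterior limb bud mesenchyme) co-occupies a subset of its
binding sites. Establishing this requires stitching together several
genome-scale measurements: TF ChIP-seq cistromes from replicated experiments,
chromatin state (H3K27ac, H3K27me3, ATAC, CTCF), differential expression in
two mutant genotypes, single-cell co-expression, enhancer evidence inside the
target gene's TAD, and cross-tissue comparisons of the promiscuous factor's
binding.

`limbGRN` implements that integration as a tested, reusable pipeline. Every
stage is exposed as an ordinary function; `run_pipeline()` chains them on
synthetic input with planted ground truth, so each statistical claim the
pipeline makes can be checked against a known answer.

## Replicate-consensus peak combination

Peaks from k replicates are combined with Fisher's method. A peak only
participates if its own p-value passes a *weak* per-peak threshold
(default `1e-6`); a group of overlapping peaks is kept if it is supported by
at least `min_replicates` distinct replicates (default 2) and its combined
statistic

$$X = -2 \sum_{i=1}^{k} \ln p_i \sim \chi^2_{2k}$$

yields a tail probability at or below a *stringent* threshold (default
`1e-10`). The consensus region is the union span of the group and its score
the combined $-\log_{10} p$. For a single member the combined p equals the
member's p exactly, which anchors the unit tests.

Replicated-cistrome workflows of this kind commonly use MSPC with
`-s 1E-10 -W 1E-6`; MSPC's internal confirmation iteration is not available
in closed form, so this package implements the plain Fisher combination with
the weak/stringent thresholds mapped onto `-W`/`-s`. We treat this as an
approximation of the same evidential logic rather than a re-implementation
of MSPC, and all downstream behaviour is validated against planted truth,
not against MSPC output. Peaks reported with p = 0 (an infinite $-\log_{10} p$) are clamped to
a configurable ceiling (default 300) and the clamp is warned about, so a
handful of saturated peaks cannot dominate a combined score silently.

All intervals live in `GRanges`, the canonical R container, which is 1-based
and closed. BED-family files are 0-based half-open; the conversion happens
in exactly one place — `read_peaks()`/`write_peaks()` and the BED exporters —
so no other code ever adjusts coordinates. This is a deliberate departure
from keeping BED convention in memory: in R, fighting the container's native
convention is the likelier source of off-by-one drift.

## Cistrome partitioning and chromatin overlay

`partition_cobinding()` reduces the union of two consensus cistromes to
merged regions and labels each `A_only`, `B_only` or `both` by ≥ 1 bp overlap
(configurable). The three counts always sum to the merged total — the
bookkeeping identity behind every co-binding Venn diagram.

Genomic context uses the precedence promoter > intragenic > intergenic.
The promoter is TSS ± 2 kb: the convention is common in cistrome work, and
the width is a parameter (`promoter_halfwidth_bp`) because published analyses
rarely state theirs. Chromatin marks are overlaid as boolean flags plus a
per-region signal equal to the *maximum* $-\log_{10} p$ of overlapping mark
peaks; the maximum rather than the mean makes the attributed signal robust to
a mark peak being fragmented into several calls.

Class-wise comparisons use rank tests with midrank ties
(`stats::kruskal.test`, `stats::wilcox.test` without continuity correction,
exact where group sizes permit and no ties are present). p-values are floored
at the smallest positive double, so "p < 2.2e-16"-style statements remain
reproducible and no comparison ever reports exactly zero. When every
observation is tied the rank statistic has zero variance; we report p = 1
(no evidence) rather than NaN.

## DEG concordance across two genotypes

A gene is differentially expressed when its linear fold change is at least
1.2 in either direction — applied as $|\log_2 FC| \ge \log_2 1.2 \approx
0.263$, boundary inclusive — at FDR ≤ 0.05. The intersection of two
mutant-versus-control contrasts is restricted *first* to the universe of
genes detected in all replicates of both experiments, then classified by
sign pair: up/up (repressed by both factors), down/down (activated by both),
opposite (discordant), or single-contrast. Restricting before classification
is the reading most consistent with intersecting "only genes that were
detected in all replicates"; the alternative (restrict after) would only
shrink the single-contrast sets, never the shared classes, because a shared
gene must be significant — hence detected — in both contrasts either way.
The five output sets are pairwise disjoint by construction and tested as
such.

## Single-cell co-expression

Cells pass QC with 3000–25,000 total transcripts (inclusive), at least 1000
expressed genes, and a mitochondrial fraction strictly below 10%.
Normalization is `log1p(1e4 * count / total)` per cell. This stands in for
variance-stabilizing NB regression deliberately: that transformation is a
package internal of its implementation, not a defined computation, whereas
log-normalization is exactly reproducible and sufficient for the rank-based
statistics used downstream (which are invariant to monotone transforms).

Clustering resolution is selected on a grid (0.2–2.0, step 0.1) by the mean
silhouette width over cells, computed with Euclidean distance in the PCA
embedding; ties break toward the lowest resolution, and a grid that never
produces two clusters is an error, not a silent answer. The clusterer itself
is a contract — any function `(embedding, resolution, seed) -> labels` — with
a reference implementation (`snn_cluster()`) that builds a shared-nearest-
neighbor graph with Jaccard weights and applies seeded Louvain modularity
optimization. Mean-over-cells (rather than medoid) silhouette is used; both
are defensible, one had to be chosen.

Co-expression is scored as the AUROC of a gene's expression classifying
*double-positive* cells against other mesenchymal cells, computed as the
Mann–Whitney U statistic over $n_1 n_2$. Genes pass at AUC ≥ 0.55.
"Double-positive" — a notion upstream toolchains leave informal — is
formalized here as nonzero raw count of *Hand2* and nonzero raw count of
*Pbx1* or *Pbx2*, with a configurable expression floor. Module scores follow the
standard construction: per-cell mean expression of the gene set minus the
mean of control genes sampled (seeded) from the same average-expression
bins; a set whose genes can only draw themselves as controls scores exactly
zero, which the tests exploit.

## Enhancer prioritization and TAD scores

Within a TAD, every consensus TF peak becomes a candidate carrying six
flags: replicated binding, fold enrichment ≥ 15 (inclusive), no overlap with
any promoter window, H3K27ac overlap, ATAC overlap, and conservation
overlap, each by ≥ 1 bp. `passes` is the conjunction, checked exhaustively
in tests. The reporter-assay ledger is input, not inference: previously
known enhancers and newly reproducible limb-domain activities are tallied
into a validated total.

A TAD's regulatory score is the pair (count, summed $-\log_{10} p$) of the
distal (non-promoter) consensus sites inside it. There is no standard
closed form combining site count with site strength, so both components are
reported and the DEG-versus-other comparison (one-sided Mann–Whitney, DEG
TADs greater) is run on each.

## Cross-tissue binding specificity

The merged-region universe across tissues yields Venn counts and, per
tissue, the fraction of peaks in the common core. The cofactor selection
fraction is (cofactor peaks overlapping ≥ 1 promiscuous-factor peak) /
(cofactor peaks); selection percentages reported in this field rarely pin
down the denominator, so the numerator and both set sizes are reported
alongside the fraction to keep the alternative auditable. Signal
comparisons between tissues use $\log_2((a + 1)/(b + 1))$ per region (the
pseudocount guards zeros and is configurable) with a two-sided Mann–Whitney
between region subsets.

## Mutagenesis planning

Binding-site cores are disrupted by the fixed substitution map T→C, A→C,
C→A, G→A. The map has no fixed points, so the number of altered bases equals
the number of core bases, making altered-base counts directly comparable
across designs (`compare_designs()` checks the equality rather than
enforcing it). Printed 1-based site positions are taken as core starts
(offset 0) by default; per-site core length and offset are inputs because
the authors' exact site boundaries are not derivable from the published
position lists. `apply_plan()` verifies every reference base before
substituting, so a stale plan fails loudly instead of silently mutating the
wrong bases.

## The synthetic-data generator

Every pipeline input can be generated at desk scale with planted truth:

* **Peaks** — disjoint A-only/co-bound/B-only regions (defaults 700/300/220)
  with true $-\log_{10} p$ drawn from U(8, 30); replicates are jittered
  copies (centers N(0, 20 bp), scores N(0, 0.5)) so the consensus stage has
  real work; ATAC/H3K27ac cover every region with a +3 score shift at
  co-bound regions, mirroring the finding that co-bound sites sit in more
  accessible, more active chromatin.
* **DEG tables** — classes are dealt to genes deterministically in id order
  (46 concordant-up, 37 concordant-down, 31 discordant by default, matching
  the reported shared-target classes, plus single-contrast, undetected and
  null genes); statistics are drawn so planted classes pass the thresholds
  and null genes fail at least one.
* **Single-cell counts** — negative-binomial UMI counts (size 2) over three
  clusters (two mesenchymal, one epithelial; 800/800/400 cells by default),
  cluster-specific markers, a pan-mesenchymal marker, a double-positive
  subpopulation (half the posterior cluster) in which seven planted target
  genes are elevated by 1.5 log-units, and a few cells planted to fail each
  QC rule. The cell count is a desk-scale stand-in for the ~10,000-cell
  experiments this emulates; it is chosen large enough that the null AUROC
  sampling noise (sd $\approx \sqrt{(n_1+n_2+1)/(12 n_1 n_2)}$) keeps pure
  noise genes clearly below the 0.55 threshold.
* **Enhancer landscape** — one TAD with 5 candidates passing every filter
  and 10 candidates each violating exactly one, cycling through the five
  failure modes, so precision and recall are 1 by construction.
* **Cross-tissue** — three tissue cistromes sharing a planted common core
  (60%); cofactor peaks are planted at *exact counts* of the stated rates
  (48%/18% for the HAND2-like cofactor against HL/MF, 70%/43% for the
  HOXA2-like cofactor against BA2/HL) rather than Bernoulli draws, so the
  planted rate is realized exactly on every seed; a signal table carries a
  +1 planted median log2FC at cofactor-co-bound regions.

Every generator is a pure function of its configuration: it derives a fixed
RNG stream from the master seed and restores the caller's stream, and
`write_sim()` emits byte-identical files per seed. Truth labels go to
sidecar TSVs, never into the standard-format files.

What the generator does *not* emulate: read-level noise and peak-calling
artifacts (inputs begin at peak calls), mapping biases, doublets and
ambient RNA in the single-cell counts, correlated gene-gene structure beyond
the planted clusters and programs, and real TAD boundaries. Passing tests
therefore demonstrate that the pipeline's logic recovers known structure
under its stated statistical assumptions — not that those assumptions hold
in any particular real data set.

## Problem sizes and numerical choices

Default problem sizes — ~1200 planted regions, 400 genes, 40 TADs,
2000 cells × 1500 genes, 1000 peaks per tissue — were chosen so a full
`run_pipeline()` completes in about 1–2 minutes on a single CPU while
keeping every statistical property comfortably powered. Other conventions:
overlap thresholds default to ≥ 1 bp; silhouette ties break to the lowest
resolution; p-values are floored at `.Machine$double.xmin`; all-tie rank
tests report p = 1; Fisher combination is computed on the $-\log_{10}$
scale throughout to avoid underflow; the run report contains no timestamps
so identical configurations produce identical reports.

## Known limitations

* The Fisher-based consensus is an approximation of MSPC's combined-evidence
  procedure; numerical agreement with MSPC on real data is not claimed.
* The AUC positive-class definition and the promoter window are formalized
  choices where the source analyses are silent; both are parameters.
* The TAD regulatory score reports count and summed strength separately
  because the original scoring formula is unpublished.
* GO/motif enrichment (GREAT, HOMER) and scTransform-style normalization are
  intentionally out of scope; the pipeline starts from peak calls and count
  matrices and ends at the statistics described above.
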
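---
title: "Quantifying and classifying promoter chromatin states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying promoter chromatin states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromstate)
```

## The problem

During early post-implantation development, many developmental genes sit in
a *bivalent* chromatin state: their promoters carry the activating mark
H3K4me3 and the repressive mark H3K27me3 at the same time, and may or may
not be engaged by RNA polymerase II (Pol II). Whether a bivalent promoter
is Pol II-bound, whether engaged Pol II actually elongates (detected as
Ser2-phosphorylated Pol II, Ser2p, over the gene body), and whether
elongation produces stable mRNA are three separate questions, and their
answers change as epiblast cells commit to germ layers. This package turns
that question set into a reproducible pipeline: background-corrected
signal quantification, fixed-threshold state classification, chromatin
clustering, stage dynamics, and a synthetic-data harness that validates
every classifier against planted ground truth.

## Signal model and normalization

For each sample the pipeline computes RPKM (reads per kilobase per million
mapped reads) over three windows per gene:

* **promoter** — a 1-kb window centered on the TSS (`tx_start` on the `+`
  strand, `tx_end − 1` on the `−` strand; coordinates are 0-based
  half-open everywhere, the native convention of refFlat and BED);
* **background** — the upstream −4 to −3 kb region, strand-mirrored for
  `−` strand genes as `[TSS + 3001, TSS + 4001)` so that the two strands
  are exact mirror images under the `TSS = tx_end − 1` convention (a
  symmetry covered by a dedicated test);
* **gene body** — the transcript span, used for Ser2p.

A read counts toward a window when it overlaps it by at least 1 bp, and at
most once per window; RPKM is `C / (L_kb · M)` with `M` the library size
in millions. The *background coefficient* of a sample is the arithmetic
mean of the per-gene background RPKMs across all collapsed genes, floored
at `1e-6` so a sparse simulation can never divide by zero, and the
*normalized RPKM* of a gene is its window RPKM divided by that
coefficient — a dimensionless fold-over-background. Two algebraic
identities follow directly and are enforced by tests: duplicating every
read (and the library size) changes nothing, and scaling all backgrounds
by `c` scales every normalized value by `1/c`.

Windows are clipped at chromosome ends; a background window clipped away
entirely contributes an RPKM of 0 to the mean rather than poisoning it.
Multi-isoform genes are collapsed to their longest transcript (ties:
smaller start, then lexicographic transcript name) before any window is
computed — the classification is gene-level, and refFlat gives no other
canonical choice.

## Classification thresholds

All cutoffs live in `default_thresholds()` and every comparison is
*strict* — a value exactly at a threshold fails, a convention fixed once
and covered by boundary tests:

| rule | cutoff |
|---|---|
| bivalent | H3K4me3 > 2 **and** H3K27me3 > 2 (normalized, promoter) |
| Pol II(+) among bivalent; activated among the rest | Pol II > 3 |
| germ-layer-specific (Ser2p) | > 3 in the top layer, < 2 in the others, one extra > 3 layer tolerated |
| germ-layer-specific (RNA) | FPKM > 5 in one layer, < 5 in the others |
| transcriptionally decoupled | gene-body Ser2p > 2, FPKM < 1, no other gene within 10 kb |

Interpretation choices the threshold text leaves open, decided here once:

* *Neighbor exclusion* — "within 10 kb of the genomic region" is measured
  as the gap between collapsed transcript spans (overlap = gap 0), on
  either strand; computed with `GenomicRanges::distanceToNearest` and
  cross-checked in tests against a brute-force all-pairs scan.
* *Lineage tolerance* — the tolerated second `> 3` layer must be the
  second-highest, the remaining layers must still be `< 2`, and the gene
  is assigned to the argmax layer (the only order-independent reading;
  assignment is tested to be invariant under layer permutation). Ties at
  the maximum leave the gene unassigned.
* Genes missing from the expression table are an error by default;
  `missing_as_zero = TRUE` opts into treating them as FPKM 0, because
  silent zeros hide joins gone wrong.

## Chromatin clusters, fold changes, dynamics

Bivalent promoters are stratified into C1 (strong H3K4me3 / weak
H3K27me3), C2 (strong/strong), C3 (weak/strong) and C4 (weak/weak). No
published strong/weak cutoff exists, so the default is a per-mark median
split across the bivalent set (exactly at the median = weak, so the
partition is total), with a k-means alternative (k = 4) whose clusters
are relabeled by matching centroid strong/weak patterns against the grand
medians. The k-means path uses Euclidean distance: the strata are
magnitude-defined, and a correlation-type distance cannot distinguish
"both strong" from "both weak" in two dimensions.

General-purpose `kmeans_cluster()` offers the uncentered-correlation
distance `1 − Σxy / (√Σx² √Σy²)` used by Cluster 3.0-style expression
clustering, with a seeded farthest-point initialization and ties broken
to the lowest center index, making runs bit-reproducible. Because mean
centroids do not exactly minimize a cosine-type objective, the iteration
additionally stops (reverting the last step) if the objective would
increase — the objective trace is therefore monotone non-increasing by
construction, not by hope.

Knockout responses are summarized as per-gene
`log2((ko + 0.1) / (ctrl + 0.1))` on normalized RPKM — the pseudocount
keeps zeros finite without dominating typical signals of 2–10 — and as
quadrant fractions over the (Pol II fc, H3K27me3 fc) plane, with fc = 0
assigned to the "not reduced"/"not increased" side.

Stage dynamics reuse the classification cutoffs verbatim: a promoter is
Pol II(+) at a stage when it is bivalent there and Pol II > 3, so
gained/lost/retained transition counts are consistent with the state
table. Mark onset is the *first* strict threshold crossing along the
stage order, with no persistence requirement — the biology being modeled
is monotone accumulation, so transient dips are a synthetic edge case
handled deterministically. The cascade summary counts genes per onset
ordering pattern (e.g. `K27<K4<PolII`), with ties joined by `=` and genes
whose marks never cross filed under `incomplete`.

## The synthetic study generator

`generate_study()` emits a complete, seeded study: refFlat annotation,
BED reads per (mark, layer, stage, condition), FPKM tables and a planted
truth manifest, in exactly the formats the pipeline reads. Reads are
Poisson: a uniform background of `depth` expected reads per kb, plus
enough extra reads inside each gene's target window to bring its total
expected coverage to `multiplier ×` background (so a multiplier of 1
means *no* enrichment and a mean normalized signal of ≈ 1). Multipliers
below 1 — knockout losses — saturate at background, which preserves the
*direction* of fold changes, the only property the quadrant statistics
use.

Reference conditions (the defaults): 500 genes on one chromosome, depth
50 reads/kb, read length 50 bp, enrichment 8× for active Pol II / Ser2p /
H3K4me3, strong/weak histone strata at 10×/3× (both above the bivalency
cutoff), three germ layers, four stages, lognormal FPKM noise with
σ = 0.3. Planted classes: 20% housekeeping-activated (15 of the 100
percentage points carrying a germ-layer-specific Ser2p/FPKM profile),
15% + 15% bivalent Pol II(±), 10% decoupled, remainder silenced. These
problem sizes keep a full generate-plus-pipeline cycle under a minute on
one CPU while leaving every classifier's error probability per gene far
below the 5% recovery budget. Choices worth flagging:

* Decoupled genes are planted only on genes isolated by ≥ 10 kb, and 5%
  of genes are deliberately placed in close pairs (5-kb gaps) so the
  exclusion rule is actually exercised.
* Chromatin clusters are planted in *balanced* counts across C1–C4: the
  planted label is defined by strong/weak status relative to the
  bivalent-set median, and only a balanced allocation keeps the per-mark
  strong fraction at one half, i.e. keeps the planted label equal to the
  quantity a median split estimates.
* Cascade genes (the Pol II(+) bivalent class) switch marks on at stages
  2 / 3 / 4 of the four-stage series for H3K27me3 / H3K4me3 / Pol II;
  every other class is stage-constant.
* The knockout scenario is PRC2-loss-like: H3K27me3 × 0.05 at bivalent
  promoters, Pol II × 2 on clusters C2/C3.

What the generator does *not* model — fragment-size distributions,
GC/mappability bias, duplicate reads, batch effects, strand-specific
signal — bounds what passing recovery tests show: they validate the
arithmetic and the decision rules under the stated noise model, not
robustness to artifacts of real ChIP-seq libraries.

## Numerical and degenerate-input conventions

RPKM of a zero-width (fully clipped) window is 0; the background
coefficient floor is 1e-6; k-means requires at least k distinct rows
(distinct *directions* under the correlation distance) and errors on
all-zero rows; assignment ties go to the lowest center index; empty
clusters keep their previous centroid. `quadrant_fractions` and the
activity partition are exact partitions by construction and are
property-tested over hundreds of random instances. Pipeline outputs are
plain TSV/BED written deterministically, so identical inputs reproduce
identical bytes — also a tested contract.

## A worked run

```{r, eval = FALSE}
cfg <- simulation_config(seed = 1)
study <- generate_study(cfg, "study")
res <- run_pipeline("study", "all", seed = 1)
head(res$states)
res$clusters$quadrants
```

## Known limitations

Single-chromosome simulations; one knockout scenario per study; the
one-extra-layer lineage allowance is one defensible reading of an
ambiguous rule (the conjunction with "< 2 in the remaining layers" is
kept); RPKM counts whole read intervals, not fragment-extended or 5'-end
positions; and no peak calling is performed anywhere — promoter state is
defined by windows, not peaks, throughout.
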
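---
title: "Calling high-confidence TF binding sites from cleavage doublets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling high-confidence TF binding sites from cleavage doublets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublechec)
```

## The problem

Chromatin endogenous cleavage (ChEC) maps protein-DNA contacts by fusing
micrococcal nuclease (MNase) to a factor of interest: calcium triggers
cleavage next to wherever the fusion protein sits, and sequencing from the
repaired cut end yields a single-base map of cleavage frequency. The method's
weakness is abundant off-target signal — a tethered nuclease also cuts
accessible chromatin it merely diffuses past, so most raw cleavage peaks are
accessibility artifacts rather than binding sites.

Two observations rescue specificity. First, a free ("soluble") nuclear MNase
control cleaves the same accessible regions with the same sequence bias, so
true binding produces cleavage *significantly above* that control. Second, a
DNA-bound factor protects its recognition sequence: real sites appear as a
**doublet** — two sharp cleavage peaks flanking a protected footprint of
roughly 8-12 bp, with peak-to-peak spacings concentrated between 15 and
50 bp. This package implements that filtering cascade and everything needed
to validate it.

## The pipeline

Given coordinate-sorted alignments for one or more TF-MNase replicates and
soluble-MNase control replicates:

1. **Cleavage extraction** (`extract_cleavage`). Each retained read (MAPQ >=
   10; primary alignments only; read 1 for paired input) contributes one
   event at its 5'-most sequenced base — the base adjacent to the cut.
   Counts per base are CPM-normalized (`cpm_normalize`) and averaged across
   replicates (`mean_track`).
2. **Smoothing** (`smooth_track`). A 3-bp sliding window every 2 bp; window
   means of the averaged CPM track, and integer window *sums* of the raw
   per-replicate counts (the differential test needs counts, and a sum of
   three integers is an integer proportional to the mean).
3. **Baseline filter and local maxima** (`genome_baseline`,
   `find_local_maxima`). Windows below 3x the genome-average per-base CPM
   are discarded; surviving windows strictly greater than their genomic
   neighbor windows are candidate peaks.
4. **Enrichment over the control** (`nb_wald_test`). At candidate windows,
   raw window sums for all samples form a count matrix tested with a
   negative-binomial GLM per window (log link, condition coefficient,
   median-of-ratios size factors as offsets). Windows are retained when the
   log2 fold change exceeds 1.7 **and** the BH-adjusted p-value is below
   1e-4.
5. **Doublet pairing** (`call_doublets`). Consecutive retained peaks 15-50 bp
   apart (inclusive) are paired; chains sharing a peak merge transitively
   into one site spanning the extreme centers, with the site midpoint at the
   chain's center.

`run_pipeline()` orchestrates all stages and reports the funnel
(windows -> maxima -> enriched -> sites), which is monotone by construction.

## The negative-binomial stage

The published pipeline delegates this step to DESeq2; this package
reimplements the core so it is self-contained, and validates the agreement
distributionally rather than claiming numerical parity.

* **Size factors**: median-of-ratios over rows with all-positive counts,
  rescaled to geometric mean 1; library-size ratios as a warned fallback.
  Note that because the tested rows are selected as maxima of the *TF*
  track, the TF columns are upward-biased at background windows and the
  median-of-ratios absorbs that bias; this makes the test conservative, and
  it is shared by the published approach, which feeds the same selected
  windows to DESeq2.
* **Dispersion**: per-row method-of-moments on normalized counts with
  within-condition centering (so genuine enrichment does not masquerade as
  dispersion), using per-condition fitted means in both the shot-noise term
  and the squared-mean denominator. Row estimates are shrunk toward a
  robustly fitted `a0 + a1/mean` trend by a log-scale weighted average
  (weight 1/4 on the row estimate, floored at trend/10; weight 3/4 on the
  trend). The weights reflect the large sampling variance of a variance
  estimate with ~4 degrees of freedom; with this choice the null
  type-I-error rate at p < 0.05 sits near 0.05 (see the acceptance tests).
  Rows with exactly zero within-condition variance fall to the floor
  (1e-8).
* **Wald test, with a boundary fallback**: the condition coefficient is
  tested against a normal reference. When either condition totals at most
  one count, the Wald statistic degenerates — as the fitted mean approaches
  the zero boundary the standard error diverges (the Hauck-Donner effect)
  and the p-value tends to 1 for rows with overwhelming enrichment. Such
  rows instead use the likelihood-ratio test against the intercept-only
  model (chi-square, 1 df), which is finite and well-behaved at the
  boundary. Reference implementations retain these rows through moderated
  fits that stop short of the boundary; the LRT achieves the same outcome
  by textbook means. Reported fold changes for all-zero conditions are
  moderated with a 0.5 pseudocount on normalized means so output stays
  finite; the retained flag uses the reported log2 fold change.

## Numerical choices

* **Coordinates** are 0-based half-open internally; BED/bedGraph follow
  their standards and GFF/GTF inputs are converted on read. Contig order is
  always the chrom.sizes order.
* **Window grid**: centers start at the first full window; partial edge
  windows are dropped. "Genome average" means the per-base mean computed
  from the actual track sum (exact even when averaging replicates of
  unequal depth).
* **Plateaus**: the default keeps the *left* window of an exact tie
  (`plateau = "keep-left"`). Single-base cleavage tracks are sparse, so a
  spike falling midway between two window centers regularly produces two
  windows with exactly equal means — both flanked by zeros — and a strict
  greater-than rule silently drops the peak; in simulations this lost
  several true sites per run. Strict mode is available as
  `plateau = "none"`.
* **Doublet bounds** are inclusive (`[15, 50]`), chains merge transitively
  (the only order-independent rule), and the site score is the minimum
  member adjusted p-value (reported as -log10, capped at 1000, in BED
  output) — the method itself defines no site score, but downstream tools
  expect one.
* **Degenerate inputs**: empty libraries, all-zero count matrices, contigs
  shorter than the window, and unplaceable simulation sites raise immediate
  errors naming the problem; out-of-bounds metaplot sites and unknown
  annotation contigs are dropped with warnings.

## Footprint and target-gene readouts

`scan_iupac` finds degenerate-motif instances on both strands;
`metaplot` averages a CPM track over site-anchored windows, orienting
minus-strand sites by reversal, with offset 0 at the motif's 5' end.
`protection_width` reports the maximal run of body offsets below 50% of the
mean flanking signal — a reporting convenience for reading a footprint width
off a metaplot, not a published definition (the flanking reference distance
must be chosen outside the doublet spikes).

`assign_targets` marks a gene as a target when a site midpoint (or, with
`mode = "interval"`, any overlap of the merged site) falls within the
strand-aware 700 bp window upstream of its start-codon anchor.
`fisher_overlap` then tests the target set against each entry of a curated
TF-target catalog with a one-sided Fisher exact test (hypergeometric upper
tail), Bonferroni-corrected across catalog entries; the universe defaults
to all annotated genes, the standard and configurable choice.

## What the simulator emulates

`simulate_tracks` generates the world the pipeline assumes:

* a **shared accessibility landscape**: a lognormal field (sigma = 0.5)
  obtained by moving-average smoothing of white noise over 200 bp, the
  correlation length of nucleosome-scale accessibility;
* **planted sites**: spike pairs `d ~ U{15..50}` bp apart with a protected
  gap `g ~ U{8..12}` centered between them where accessibility drops to
  10%; placement keeps sites more than (max spacing + 10) bp apart so two
  planted sites can never chain into a single called site;
* **counts**: control replicates draw NB counts (dispersion 0.1) with mean
  `depth x accessibility` (0.5 reads/bp); TF replicates add an NB spike of
  mean `occupancy` (60 expected reads, comfortably above the 50-read
  regime the recovery criterion assumes) at each flanking base; 3+3
  replicates; all randomness derives from one seed.

What it does **not** model: MNase sequence bias, nucleosome positioning,
fragment-length effects, read-level errors, asymmetric doublets (one weak
shoulder), and closely spaced composite binding sites. A green recovery test
therefore establishes that the pipeline's statistics and geometry are
implemented correctly under its own assumptions — not that those assumptions
hold for any particular real data set. The quantization of window centers to
a 2-bp grid also means sites planted at the extreme spacings (15 or 50 bp)
can drift 1 bp out of the inclusive band and be lost; this bounds attainable
sensitivity slightly below 1 and is inherent to the stated parameters.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_tracks(sim_config(seed = 7))
res <- run_pipeline(sim$tf, sim$control)
res
#> doublechec run
#>   windows:  99998
#>   maxima:   1037
#>   enriched: 80
#>   sites:    38
score_recovery(res$sites, sim$truth, tolerance = 10)[c("sensitivity", "fdp")]
#> $sensitivity
#> [1] 0.95
#> $fdp
#> [1] 0
```

## Known limitations

* The NB stage matches its reference tool distributionally, not
  numerically; exact re-analysis of published counts will differ in the
  tail digits.
* Single-peak (asymmetric) sites are invisible by design — the doublet
  requirement is the method's specificity mechanism and its acknowledged
  false-negative source.
* The Wald/LRT switch at a 1-count condition total is a discontinuity;
  rows on either side of it are both strongly enriched in practice, but the
  p-values are not continuous across the threshold.
* Target assignment uses a fixed upstream window; it does not model UTRs,
  divergent promoters (one site can target two genes — by design), or
  enhancer-like action at a distance.
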
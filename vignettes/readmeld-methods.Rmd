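---
title: "Read-level methylation deconvolution: models and design choices"
author: "readmeld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-level methylation deconvolution: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tumor DNA is a small minority of the DNA recovered from body fluids such as
urine. Region-level methylation averages dilute that minority signal: a
region that is 95% normal reads looks almost normal on average even when
every tumor-derived read in it is strikingly aberrant. `readmeld` works at
the resolution where the signal actually lives — the individual sequencing
read. Because methylation states are spatially pervasive (neighbouring CpGs
on the same DNA molecule tend to agree), a single read covering a few CpGs
is already a strong witness of its molecule's epigenetic state.

The pipeline has four stages:

1. **Read-level region statistics.** For each read covering at least
   `min_cpgs` CpGs we compute its alpha value, the fraction of its CpGs
   that are methylated. For each (region, sample) pair we summarise the
   proportion of hypomethylated reads (`P_hypo`, alpha <= `alpha_lo`), of
   hypermethylated reads (`P_hyper`, alpha >= `alpha_hi`), and the
   CpG-weighted mean methylation `M`.
2. **DMR calling.** A two-sided Wilcoxon rank-sum test per region compares
   case and control samples on one of those statistics, with
   Benjamini–Hochberg correction and an effect-size gate
   (`|delta| >= min_abs_delta`). Calls on `M` are mDMRs; calls on the read
   proportions are pDMRs — the read-resolution feature. A region is
   *cancer-specific* only if it is called, in the same direction, against
   both control tissue and control urine.
3. **Per-read classification.** Reads inside the selected top-N regions are
   encoded as an `L x 5` matrix (one-hot DNA sequence + a signed
   methylation channel) and a small convolutional network outputs the
   probability `d` that the read is tumor-derived.
4. **Sample scoring.** A sample's score `S` is the fraction of its scored
   reads with `d > tau` — the estimated ratio of tumor-derived reads.
   Classification cutoffs on `S` are chosen by the Youden index on the
   training cohort and frozen for validation cohorts.

The same pipeline serves diagnosis (cancer vs noncancer urine) and grading
(high-grade vs low-grade disease): only the group labels change.

## The synthetic-data generator

Every stage is testable without controlled-access human data through a
bisulfite-read simulator that emulates the regime the method targets:

- **Regions.** 240 bp candidate regions with 16 CpGs each (one per 15 bp, a
  CpG-island-like density; DMR catalogues are strongly enriched for
  CpG-dense regulatory regions, and an 80 bp read must be able to cover the
  3+ CpGs the read filter demands).
- **Within-read concordance.** Each read draws a latent methylation level
  `mu ~ Beta(p * kappa, (1 - p) * kappa)` where `p` is the methylation
  probability of the read's origin (tumor or normal) and `kappa = 5`
  controls concordance; covered CpGs are then independent `Bernoulli(mu)`.
  This Beta–Bernoulli construction is the simplest generative model with
  the pervasiveness property that motivates read-level analysis: as
  `kappa` decreases, reads become internally concordant but heterogeneous
  across molecules.
- **Mixtures.** A urine-like sample with tumor fraction `theta` draws each
  read's origin independently: tumor with probability `theta`, normal
  otherwise. `theta` is retained as ground truth so parameter recovery is
  directly measurable. The default grid {0, 0.02, 0.05, 0.1, 0.2, 0.3}
  covers the fractions a urine assay must resolve, and coverage defaults
  (3–5X equivalents, scalable to 0.3X by downsampling) match the data
  regime of urinary whole-genome bisulfite sequencing.
- **Cohorts.** The default end-to-end configuration uses 10 tumor + 10
  normal tissue samples and 25 case + 20 control urine samples for
  training, plus an independent 25 + 20 urine validation cohort — five
  samples per positive theta level per cohort, so rank statistics across
  the grid are well defined. These are desk-scale analogs of the
  tissue-pair + urine training design the method is meant for, not a
  reproduction of any specific cohort.

What the generator deliberately does **not** model: sequencer errors,
fragment-length distributions, strand asymmetries, copy-number effects,
tissue heterogeneity beyond the two-origin mixture, and urine background
composition (the two-origin mixture is an assumption). Bisulfite
non-conversion exists only as a single uniform flip rate, default 0.
Passing tests therefore demonstrate that the machinery is correct and
recovers planted truth under its stated model — not that real urine
cohorts will reach any particular AUC.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha_lo`, `alpha_hi` | 0.2, 0.8 | read-level hypo/hyper cutoffs |
| `min_cpgs_per_read` | 3 | minimum CpGs for an informative read |
| `min_reads_per_region` | 5 | floor below which region stats are missing |
| `q_threshold`, `min_abs_delta` | 0.05, 0.2 | DMR significance and effect gates |
| `top_n` | 2000 (pipeline default 20 at desk scale) | selected marker regions |
| `L` | 66 | encoding window, bp |
| `tau` | 0.5 | read-level tumor call inside `S` |
| `min_reads_for_score` | 30 | floor below which `S` is missing |

The alpha cutoffs and count floors are documented defaults, not values
asserted from any external source; they are required configuration in the
sense that every analysis states them explicitly in its resolved config.
`top_n = 2000` mirrors the marker-count regime of genome-wide catalogues;
the synthetic pipeline defaults to 20 because its universe is 60 regions.
The `threshold_sweep()` helper reproduces the marker-count-vs-accuracy
analysis that motivates such a choice on real data.

## The classifier

The per-read model is a deliberately small convolutional network written in
vectorized base R (no external deep-learning runtime): a 1-D convolution
(32 filters, width 8) over the `L x 5` encoding, ReLU, max-pool (width 2),
a position-preserving flatten, a dense ReLU layer (16 units), and a sigmoid
output; trained with minibatch Adam (learning rate 1e-3, batch 128, 15
epochs) on binary cross-entropy with a stratified 20% held-out read split.
The architectural contract is: sequence-local feature extraction, then
order-aware aggregation, then a probabilistic output. We chose the
flatten-plus-dense aggregation over a recurrent layer: it preserves window
order (so it is order-aware), trains in seconds on one CPU, and is exactly
reproducible under a single seed — properties a recurrent implementation
would complicate without changing what the tests can observe. Everything
downstream depends only on the contract, so the network can be swapped
without touching the rest of the pipeline.

Training labels follow the aberrant-read rule: in a hypomethylated marker
region, only tumor-sample reads with `alpha <= alpha_lo` become positives,
because not every read from a tumor sample is a tumor-pattern read;
negatives are all qualifying reads from the control groups in the same
regions. Classes are balanced by downsampling the majority class under the
seed (simpler to reproduce exactly than loss weighting).

## Numerical choices and degenerate inputs

- ROC thresholds are the sorted unique scores plus a low sentinel; a sample
  is positive when `score > threshold`. The trapezoid AUC then equals the
  Mann–Whitney statistic with ties counting 1/2 (property-tested against
  exhaustive pair counting).
- Youden ties are broken toward the lowest cutoff (maximal sensitivity at
  equal J), and J values within 1e-9 are treated as tied so float noise on
  sums of fractions cannot flip the choice.
- Cutoffs are learned on the training cohort and frozen for validation —
  the only leakage-free reading of train/validate evaluation.
- Wilcoxon tests with fewer than two non-missing samples per group leave
  the region untested (excluded from BH) rather than producing a fake p.
- Hierarchical clustering (Euclidean distance, Ward linkage) canonicalizes
  sample order first, because ties in the distance matrix would otherwise
  make the agglomeration order depend on input order.
- Reads failing filters at scoring time are counted and reported, never
  silently dropped; a sample with no qualifying reads gets a missing score
  with reason `no_informative_reads`.
- Seeds: one master seed derives per-stage seeds by hashing the stage name,
  with all arithmetic kept below 2^53 so it is exact in doubles. Two runs
  of the same config produce byte-identical score tables in a single R
  process (R's own BLAS thread count is fixed per platform; cross-platform
  bit identity of the trained weights is not promised).

## Problem sizes

The packaged configurations are sized for a laptop-class single CPU: the
end-to-end synthetic benchmark uses 60 regions x 90 urine samples (about
120k simulated reads, ~11k training reads), the DMR-recovery study 200
regions x 20 samples (72k reads) with 20 null replicates, and the
downsampling study 40 samples x ~21k reads. These sizes are the package's
own desk-scale choices; all of them scale linearly if increased.

## Known limitations

- Matched tumor/normal tissue pairs are treated as independent groups
  (rank-sum, not signed-rank), because urine contrasts are unpaired and one
  code path serves all contrasts. On real matched designs this sacrifices
  some power.
- The "estimated ratio of tumor-derived reads" is the thresholded read
  fraction by default (`S = #{d > tau}/n`); a mean-probability variant is
  available (`method = "mean"`). With a well-calibrated classifier the two
  are close; with a poorly calibrated one neither is a consistent estimator
  of theta without a background correction, which is visible in the
  synthetic benchmark as a small positive offset of `S` at `theta = 0`.
- Reads spanning two regions are counted in both; with sparse,
  non-overlapping candidate regions this is rare and unbiased.
- BAM ingest (Bismark XM tags) is provided but the TSV read-record path is
  the reference implementation; alignment, deduplication, and conversion
  QC are upstream of this package.
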
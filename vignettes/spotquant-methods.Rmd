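---
title: "spotquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotquant)
```

This vignette describes the models and algorithms behind `spotquant`, the
assumptions they make, the parameters that matter, and the design choices
taken where the problem admitted more than one reasonable answer.

## The measurement model

A spatially barcoded array captures polyadenylated transcripts on spots
whose probes all share one spot barcode and carry individually randomized
UMIs. After library preparation and paired-end sequencing, each original
captured molecule is represented by one or more PCR-duplicate read pairs.
The quantity of scientific interest is the number of *unique molecules*
per (spot, gene) — not the number of reads, which confounds expression
with amplification. The pipeline's estimator is exact-string UMI
collapse:

$$ n_{sg} \;=\; \bigl|\{\, u : (s, g, u) \text{ observed} \,\}\bigr| $$

This assumes (i) UMIs are read without error on the forward read, (ii)
the UMI space is large enough that two distinct molecules of the same
gene in the same spot rarely draw the same UMI, and (iii) PCR duplicates
preserve the UMI. Error-tolerant (directional-network) UMI collapse is a
deliberate non-feature: exact matching is the minimal faithful reading of
"duplicates removed using the UMI sequence", and the collapse routine is
isolated (`dedup_umis()`) so a network method could be slotted in. With
the default 9-nt `WSNNWSNNV` pattern the UMI space is 12,288 sequences;
at the simulated occupancies (~10–15 molecules per spot × gene) collision
pressure is negligible.

## Read-level processing

**Quality trimming.** The reverse read is trimmed with the BWA `-q` rule:
scanning from the 3′ end, cut at the position $c$ maximizing
$\sum_{j \ge c} (q_{thr} - q_j)$, retaining the prefix; if the maximum is
not positive the read is untouched. Ties are resolved toward the longest
retained prefix, matching the strict-inequality update of the original
implementation. Default $q_{thr} = 20$ (Phred), minimum retained length
25 nt — conventional values; both configurable. The implementation is
verified in the tests against an exhaustive cut-point maximizer on random
quality strings.

**Ribosomal screen.** A read is flagged ribosomal when it shares at least
`min_shared = 2` distinct 15-mers with any single rRNA reference sequence
(both strands checked). Two shared 15-mers correspond to one exact match
of ≥ 16 bp, so the screen can — correctly, by its definition — flag a
transcript read whose source region happens to share such a stretch with
an rRNA sequence. For this reason analyses of simulations with no
ribosomal contamination simply omit the ribosomal reference rather than
rely on the screen being vacuous.

**Mapping.** In place of a genome aligner the package uses a
transcriptome k-mer seed-and-extend mapper: transcripts sharing
`min_seed = 2` seed 15-mers with the read are candidates, each scored by
the ungapped match count along its most-seeded diagonal (ties between
diagonals resolved toward the smaller offset, deterministically).
Candidates tied at the top score make the read *ambiguous* and it is
discarded, mirroring union-mode handling of multi-gene hits; a unique top
hit not flagged polyadenylated in the annotation is *not_polyA* and also
discarded, since an oligo-dT-captured library is quantified against a
polyadenylated-only annotation. The mapper assumes an intron-free
reference (true of the synthetic transcriptome) and substitution-type
errors only; it is deliberately pluggable — `read_sam_assignments()`
accepts the output of an external aligner whose reference names are gene
identifiers.

**Barcode demultiplexing.** Spot barcodes are matched exactly by default
(`max_mismatch = 0`), on the reading that demultiplexing against a known
whitelist is a membership filter. A Hamming tolerance of up to 2 is
available; the unique nearest barcode wins and distance ties discard the
read. The matcher is verified against a brute-force minimum-Hamming scan.

Every read pair receives exactly one of six statuses, and the status
counts partition the input. This accounting identity is asserted across
the test suite and recomputed by the acceptance script on a maximally
noisy simulation (errors, low-quality tails, rRNA, junk reads,
forward-read errors, background priming).

## Saturation curves

Library complexity is profiled by downsampling the annotated-read
multiset to depths $d$ and counting distinct (spot, gene, UMI) triples.
Sampling is without replacement; within a replicate the samples are
*nested* — one random permutation is drawn and the depth-$d$ sample is
its first $d$ elements — so each depth is a uniform sample and every
per-replicate curve is monotone non-decreasing by construction rather
than only in expectation. Replicate means converge on the closed form

$$ \mathbb{E}[U(d)] \;=\; \sum_m \left[ 1 - \binom{N - c_m}{d}
   \middle/ \binom{N}{d} \right], $$

where molecule $m$ has $c_m$ duplicate reads out of $N$ total; the
package computes this (`saturation_expected()`) from the simulator's
ground truth and the tests require agreement within three standard errors
at 200 replicates. Default depth grid: ten evenly spaced points from 10%
to 100% of the total, since no canonical grid exists. Raw-FASTQ
downsampling (`downsample_fastq()`) is provided separately for bringing
libraries to a common input depth while preserving read pairing;
extrapolation beyond the observed depth is out of scope.

## Replicate concordance

Samples are per-gene vectors: *bulk* sums over all spots of a section, or
*region* averages — the arithmetic mean over a selected set of spots
(zeros included in the denominator), emulating the comparison of one
tissue region (e.g. an inflamed area identifiable in consecutive
sections) across replicates. Normalization is the median-of-ratios size
factor

$$ s_j \;=\; \operatorname*{median}_{g \,:\, \forall v,\; k_{gv} > 0}
   \; \frac{k_{gj}}{\bigl(\prod_v k_{gv}\bigr)^{1/m}}, $$

implemented from the definition with the all-nonzero gene restriction
stated explicitly (and cross-checked in the tests against an independent
implementation of the same estimator). Normalized counts get a
pseudo-count of one and a log2 transform, then pairwise Pearson
correlation over the full shared gene universe — no detected-gene
filtering, since none is assumed — with the group summary being the mean
off-diagonal r. Dispersion between replicates is summarized as the
coefficient of variation, $100 \cdot \mathrm{sd}/\mathrm{mean}$ with the
$n-1$ denominator. For region-level comparison the declared order is:
average over the region, then normalize, then transform, then correlate;
averaging first makes the region vector a pseudo-sample whose depth is
normalized like any other sample's.

Two distributional properties are exercised by the tests: a pure global
depth factor between replicates is removed exactly (size-factor ratio
equal to the factor, identical normalized vectors, r = 1), and
correlations computed on 10-spot region averages vary more across
simulated section pairs than bulk correlations of the same sections — the
expected small-sample/dropout effect.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

- **Array**: 1007 spots by default (a typical printed subarray), on a
  grid filled row by row; 18-nt barcodes, 9-nt `WSNNWSNNV` UMIs; layout
  36-bp forward / 121-bp reverse reads. Barcode and UMI lengths are
  package defaults chosen to fit the 36-bp forward read, not measured
  constants, and are configurable.
- **Expression**: per-gene means drawn from a Gamma(shape 2) with mean
  `baseline_mean` (molecules/spot/gene), shared across spots; a
  contiguous block of `region_size = 10` spots has a random subset
  (default 20%) of polyadenylated genes scaled by `region_effect`. The
  same profile object generates all replicate sections, so the region is
  shared across replicates as consecutive sections of one block would be.
- **Reads**: molecule counts are Poisson; each molecule draws a UMI from
  the IUPAC pattern, unique within its (spot, gene) so that ground truth
  and ideal recovery coincide; PCR copies are 1 + Geometric with mean
  `dup_mean − 1` (the simplest one-parameter duplication model); the
  reverse read is a 3′-biased window (exponential offset from the 3′ end,
  mean 20 nt — oligo-dT priming), padded from the poly-A tail when the
  transcript is shorter than the read; substitution errors at
  `error_rate`; low-quality 3′ tails with probability `tail_lowq_prob`
  (contiguous runs with qualities below the trim threshold, giving the
  trimmer deterministic work); rRNA and unalignable junk reads at given
  fractions of the total; forward reads are barcode + UMI + oligo-dT
  filler, with an independent (default zero) error rate. By default only
  polyadenylated genes emit molecules (oligo-dT capture);
  `non_polyA_capture` adds background priming to exercise the annotation
  filter.

What the generator does **not** emulate: spot-to-spot diffusion, tissue
images, indels, instrument-specific quality profiles, UMI errors, or
duplication rates calibrated to any real dataset. Passing tests therefore
demonstrate algorithmic correctness under a controlled model, not
performance on real tissue libraries.

## Numerical and scale choices

All sequence intervals are 0-based half-open; spot labels serialize as
`"x_y"`. Degenerate inputs fail loudly: ragged or non-ACGT barcodes,
duplicate barcodes or coordinates, mismatched sequence/quality lengths,
depths beyond the read total, normalization with no gene nonzero
everywhere, correlation of zero-variance vectors, CV of zero-mean or
length-1 vectors. Desk-scale problem sizes were chosen so the whole suite
runs in well under a minute of simulation per scenario: the validation
experiment is 50 spots × 100 genes at ~50,000 molecules with 3×
duplication (~150,000 read pairs), oracle comparisons use 10,000 random
inputs, saturation uses 200 replicates at 5 depths, and concordance
contrasts use 3 sections per group with lognormal per-gene technical
noise at sdlog 0.05 (tight, automation-like) vs 0.4 (variable,
manual-like). Exact identities (ground-truth equality, accounting
partitions) are asserted with no tolerance; stochastic comparisons use
standard-error-scaled bounds.
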
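# spotquant

Processing and replicate-concordance analysis for spatially barcoded
RNA-seq libraries, from raw paired reads to a spot × gene matrix of unique
molecule counts.

In spatially barcoded ("spatial transcriptomics") experiments, a tissue
section is placed on a glass array of ~100 μm spots. Every probe in a spot
carries a spot-specific DNA barcode, a semi-randomized unique molecular
identifier (UMI) and an oligo-dT capture sequence, so each captured mRNA
can be traced back to an (x, y) position on the tissue and each original
molecule can be distinguished from its PCR copies. Sequencing yields pairs
of reads: a short forward read carrying barcode + UMI, and a longer
reverse read carrying the transcript fragment. This package turns those
read pairs into molecule-level expression maps and quantifies how
reproducible replicate sections are — the analysis used to compare
library-preparation protocols (e.g. automated vs manual) at the whole-
section and at the spatial level.

## What the pipeline does

For read pair *i* with forward read *f* and reverse read *r*:

1. **Parse** *f* into barcode `b = f[0, L_bc)` and UMI `u = f[L_bc, L_bc+L_umi)`
   (defaults: 36 bp forward read, `L_bc = 18`, `L_umi = 9`).
2. **Trim** *r* with the BWA `-q` rule: cut at the position `c` maximizing
   `Σ_{j≥c} (q_thr − q_j)` from the 3′ end (`q_thr = 20`); drop reads
   shorter than 25 nt.
3. **Screen** ribosomal reads: flag *r* if it shares ≥ 2 distinct 15-mers
   with any rRNA reference sequence (either strand).
4. **Map** *r* to the transcriptome by k-mer seed-and-extend (15-mer
   seeds, ≥ 2 seeds for candidacy, candidates scored by ungapped match
   count on the best diagonal); a unique top hit that is annotated
   polyadenylated is *assigned*; ties are *ambiguous* and discarded.
5. **Demultiplex** by matching *b* against the array design (exact by
   default; optional Hamming tolerance with ambiguity discard).
6. **Deduplicate**: the count for spot *s* and gene *g* is the number of
   distinct UMIs observed, `n_sg = |{u : (s, g, u) observed}|`.

Every read pair receives exactly one status (`assigned`, `unmapped`,
`ribosomal`, `ambiguous`, `not_polyA`, `too_short`), so the per-status
counters partition the input — an invariant asserted throughout.

Downstream analyses:

- **Saturation curves**: downsample the annotated reads to depths *d* and
  count unique (spot, gene, UMI) triples; the expectation has the closed
  form `Σ_m [1 − C(N−c_m, d) / C(N, d)]` for molecules *m* with *c_m*
  duplicate reads out of *N*, which the package also computes
  (`saturation_expected()`).
- **Replicate concordance**: per-gene sample vectors (bulk sums over all
  spots, or averages over a selected region of spots), median-of-ratios
  size-factor normalization `s_j = median_g (k_gj / (Π_v k_gv)^{1/m})`
  over genes with nonzero counts in all samples, `log2(x + 1)` transform,
  pairwise Pearson correlation, and coefficients of variation
  `100 · sd / mean`.

A synthetic-data generator (`make_transcriptome()`, `make_array_design()`,
`make_spot_profiles()`, `simulate_reads()`) emulates the whole read
structure — Poisson molecule counts, a localized "inflamed region"
expression effect shared across replicate sections, geometric PCR
duplication, substitution errors, low-quality 3′ tails, rRNA
contamination — and records the full ground truth, so every stage is
testable without external data.

## Worked example

```r
library(spotquant)

tx       <- make_transcriptome(n_genes = 100, seed = 1)
design   <- make_array_design(n_spots = 50, n_cols = 10, seed = 2)
profiles <- make_spot_profiles(design, tx, baseline_mean = 12.5, seed = 3)
sim <- simulate_reads(profiles, tx, dup_mean = 3, error_rate = 0.005,
                      tail_lowq_prob = 0.1, rrna_fraction = 0.05, seed = 4)
sim
#> sim_reads: 50964 molecules -> 153840 read pairs (+8097 rRNA, +0 noise)

out <- run_pipeline(sim$fwd, sim$rev, design, tx)
out
#> spot_counts: 50 spots x 80 genes, 50961 unique molecules
#>   counters: total_reads=161937, assigned=153827, unmapped=0,
#>   ribosomal=8110, ambiguous=0, not_polyA=0, too_short=0,
#>   barcode_filtered=0, annotated_reads=153827, unique_molecules=50961
```

161,937 read pairs collapse to 50,961 unique molecules (the simulated
duplication rate was 3×); the rRNA screen removes the contaminant reads
plus a handful of transcript reads that genuinely share a ≥16 bp stretch
with the random rRNA. Saturation and concordance:

```r
curve <- saturation_curve(out$annotated, n_replicates = 20, seed = 5,
                          depths = round(seq(.2, 1, .2) * nrow(out$annotated)))
curve
#>  depth mean_unique sd_unique
#>  30765    21943.45  53.59347
#>  61531    34073.55  58.22414
#>  92296    41785.10  70.94542
#> 123062    47082.25  45.79804
#> 153827    50961.00   0.00000

secs <- simulate_section_counts(profiles, n_sections = 3, tech_sd = 0.05,
                                seed = 6)
replicate_concordance(secs)
#> correlation_report: 3 samples, mean pairwise r = 0.9925
```

At 20% depth about 43% of the molecules are already seen; at full depth
the count is exact. Three low-technical-noise replicate sections correlate
at r ≈ 0.99 after normalization; raising `tech_sd` (per-gene lognormal
technical noise) lowers r, reproducing the qualitative gap between tight
and variable library preparations. A thin CLI over these functions is in
`inst/scripts/spotquant-cli.R` (subcommands `simulate`, `process`,
`saturation`, `compare`).

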
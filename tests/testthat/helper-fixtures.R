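# Small shared experiment used across test files (built once per run).

fix_tx <- make_transcriptome(n_genes = 20L, length_range = c(300L, 600L),
                             polyA_fraction = 0.8, n_rrna = 2L, seed = 11L)
fix_design <- make_array_design(n_spots = 30L, n_cols = 6L, seed = 12L)
fix_profiles <- make_spot_profiles(fix_design, fix_tx, baseline_mean = 4,
                                   region_size = 10L, seed = 13L)
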
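test_that("transcriptome generation honors the polyA fraction and is deterministic", {
  tx <- make_transcriptome(n_genes = 10L, polyA_fraction = 0.8, seed = 1L)
  expect_equal(sum(tx$genes$polyA), 8L)
  expect_equal(sum(!tx$genes$polyA), 2L)
  tx2 <- make_transcriptome(n_genes = 10L, polyA_fraction = 0.8, seed = 1L)
  expect_identical(tx, tx2)
})

test_that("every generated transcript length falls within length_range", {
  tx <- make_transcriptome(n_genes = 100L, length_range = c(200L, 900L),
                           seed = 2L)
  lens <- nchar(tx$seqs)
  expect_true(all(lens >= 200L & lens <= 900L))
  expect_equal(unname(lens), tx$genes$length)
  expect_false(anyDuplicated(tx$genes$gene_id) > 0L)
  expect_false(any(grepl("[^ACGT]", tx$seqs)))
})

test_that("degenerate generator parameters are rejected", {
  expect_error(make_transcriptome(n_genes = 1L), "n_genes")
  expect_error(make_transcriptome(polyA_fraction = 1), "polyA_fraction")
  expect_error(make_transcriptome(length_range = c(500L, 100L)),
               "degenerate")
})

test_that("transcriptome FASTA and annotation round-trip on disk", {
  fa <- withr::local_tempfile(fileext = ".fa")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_transcriptome(fix_tx, fa, annotation = ann)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs), fix_tx$seqs)
  tab <- read_annotation(ann)
  expect_equal(tab, fix_tx$genes)
})

test_that("a null region effect leaves region spots identical to background", {
  p <- make_spot_profiles(fix_design, fix_tx, baseline_mean = 4,
                          region_effect = 1, seed = 3L)
  expect_equal(length(p$region_spots), 10L)
  bg <- setdiff(rownames(p$expression), p$region_spots)
  expect_equal(colMeans(p$expression[p$region_spots, ]),
               colMeans(p$expression[bg, ]))
})

test_that("the region fold-change is realized in the expression matrix", {
  p <- make_spot_profiles(fix_design, fix_tx, baseline_mean = 4,
                          region_effect = 4, seed = 4L)
  bg <- setdiff(rownames(p$expression), p$region_spots)
  ratio <- colMeans(p$expression[p$region_spots, p$region_genes,
                                 drop = FALSE]) /
    colMeans(p$expression[bg, p$region_genes, drop = FALSE])
  expect_equal(unname(ratio), rep(4, length(p$region_genes)))
  off <- setdiff(colnames(p$expression), p$region_genes)
  ratio_off <- colMeans(p$expression[p$region_spots, off]) /
    colMeans(p$expression[bg, off])
  expect_equal(unname(ratio_off), rep(1, length(off)))
})

test_that("region_size larger than the array is rejected", {
  expect_error(make_spot_profiles(fix_design, fix_tx, region_size = 31L),
               "region_size")
})

test_that("without duplication or noise, read pairs equal ground-truth molecules", {
  sim <- simulate_reads(fix_profiles, fix_tx, dup_mean = 1, error_rate = 0,
                        rrna_fraction = 0, seed = 5L)
  gt <- sim$ground_truth
  expect_true(all(gt$n_copies == 1L))
  expect_equal(sim$counters$total_read_pairs, nrow(gt))
  expect_equal(length(read_fastq_ids(sim$fwd)), nrow(gt))
})

test_that("dup_mean controls the reads-per-molecule ratio", {
  big <- make_spot_profiles(fix_design, fix_tx, baseline_mean = 20,
                            seed = 6L)
  sim <- simulate_reads(big, fix_tx, dup_mean = 3, seed = 6L)
  ratio <- sum(sim$ground_truth$n_copies) / nrow(sim$ground_truth)
  expect_lt(abs(ratio - 3), 0.15)
})

test_that("the same seed reproduces byte-identical FASTQ files", {
  f1 <- withr::local_tempfile(fileext = ".fq")
  r1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  r2 <- withr::local_tempfile(fileext = ".fq")
  simulate_reads(fix_profiles, fix_tx, fwd = f1, rev = r1, dup_mean = 2,
                 error_rate = 0.01, tail_lowq_prob = 0.2,
                 rrna_fraction = 0.05, seed = 7L)
  simulate_reads(fix_profiles, fix_tx, fwd = f2, rev = r2, dup_mean = 2,
                 error_rate = 0.01, tail_lowq_prob = 0.2,
                 rrna_fraction = 0.05, seed = 7L)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(r1), readLines(r2))
})

test_that("ground-truth accounting matches emitted FASTQ record counts", {
  sim <- simulate_reads(fix_profiles, fix_tx, dup_mean = 2.5,
                        error_rate = 0.005, tail_lowq_prob = 0.1,
                        rrna_fraction = 0.08, noise_fraction = 0.03,
                        seed = 8L)
  gt <- sim$ground_truth
  expected <- sum(gt$n_copies) + attr(gt, "n_rrna_reads") +
    attr(gt, "n_noise_reads")
  expect_equal(attr(gt, "total_read_pairs"), expected)
  expect_equal(length(read_fastq_ids(sim$fwd)), expected)
  expect_equal(length(read_fastq_ids(sim$rev)), expected)
  expect_false(anyDuplicated(paste(gt$barcode, gt$gene_id, gt$umi)) > 0L)
})

test_that("simulated UMIs conform to the IUPAC pattern", {
  sim <- simulate_reads(fix_profiles, fix_tx, seed = 9L)
  pattern <- attr(fix_design, "umi_pattern")
  codes <- strsplit(pattern, "")[[1L]]
  umis <- sim$ground_truth$umi
  expect_true(all(nchar(umis) == nchar(pattern)))
  for (i in seq_along(codes)) {
    allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[codes[i]]], "")[[1L]]
    expect_true(all(substr(umis, i, i) %in% allowed))
  }
})

test_that("transcripts shorter than the reverse read are poly-A padded", {
  tx <- make_transcriptome(n_genes = 6L, length_range = c(60L, 80L),
                           polyA_fraction = 0.8, seed = 10L)
  d <- make_array_design(n_spots = 4L, n_cols = 2L, seed = 10L)
  p <- make_spot_profiles(d, tx, baseline_mean = 5, region_size = 2L,
                          seed = 10L)
  sim <- simulate_reads(p, tx, seed = 10L)
  rev_seq <- read_fastq_seqs(sim$rev)
  expect_true(all(nchar(rev_seq) == 121L))
  expect_true(all(grepl("A{40,}$", rev_seq)))
})

test_that("section count replicates share dimensions and respond to tech_sd", {
  secs <- simulate_section_counts(fix_profiles, n_sections = 3L,
                                  tech_sd = 0, seed = 11L)
  expect_length(secs, 3L)
  expect_true(all(vapply(secs, function(m)
    identical(dim(m), dim(fix_profiles$expression)), logical(1L))))
  expect_true(all(vapply(secs, function(m) all(m >= 0L), logical(1L))))
})
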
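test_that("bulk sums collapse spots and match ground truth when noise-free", {
  m <- matrix(c(1L, 2L, 0L, 5L), nrow = 2L,
              dimnames = list(c("0_0", "1_0"), c("g1", "g2")))
  expect_equal(bulk_sum(m), c(g1 = 3, g2 = 5))
  expect_equal(bulk_sum(m[1L, , drop = FALSE]), c(g1 = 1, g2 = 0))

  sim <- simulate_reads(fix_profiles, fix_tx, dup_mean = 2, seed = 61L)
  out <- run_pipeline(sim$fwd, sim$rev, fix_design, fix_tx)
  gt_totals <- table(factor(sim$ground_truth$gene_id,
                            levels = colnames(out$matrix)))
  expect_equal(bulk_sum(out), setNames(as.numeric(gt_totals),
                                       names(gt_totals)))
})

test_that("region averages are per-gene means over the selected spots", {
  m <- matrix(c(2L, 4L, 1L, 3L), nrow = 2L,
              dimnames = list(c("0_0", "1_0"), c("g1", "g2")))
  expect_equal(region_average(m, c("0_0", "1_0")), c(g1 = 3, g2 = 2))
  expect_equal(region_average(m, "0_0"), c(g1 = 2, g2 = 1))
  expect_error(region_average(m, "9_9"), "9_9")
  expect_error(region_average(m, character(0L)), "empty")
})

test_that("the simulated region effect survives the pipeline into region averages", {
  p <- make_spot_profiles(fix_design, fix_tx, baseline_mean = 30,
                          region_effect = 4, seed = 62L)
  sim <- simulate_reads(p, fix_tx, seed = 62L)
  out <- run_pipeline(sim$fwd, sim$rev, fix_design, fix_tx)
  reg <- region_average(out, p$region_spots)
  bg <- region_average(out, setdiff(rownames(out$matrix), p$region_spots))
  genes <- intersect(p$region_genes, colnames(out$matrix))
  ratio <- mean(reg[genes] / bg[genes])
  expect_lt(abs(ratio - 4), 0.5)
})

test_that("size factors are 1 for identical samples and scale-equivariant", {
  set.seed(63)
  a <- rpois(200L, 20) + 1L
  mat <- cbind(s1 = a, s2 = a, s3 = a)
  expect_equal(size_factors(mat), c(s1 = 1, s2 = 1, s3 = 1))
  mat2 <- cbind(s1 = a, s2 = 2L * a)
  sf <- size_factors(mat2)
  expect_equal(unname(sf[2L] / sf[1L]), 2)
})

test_that("size factors match the brute-force median-of-ratios oracle", {
  set.seed(64)
  mat <- matrix(rpois(300L, 15), ncol = 3L,
                dimnames = list(NULL, paste0("s", 1:3)))
  mat[sample.int(300L, 30L)] <- 0L
  expect_equal(unname(size_factors(mat)), unname(oracle_size_factors(mat)))
})

test_that("size factors agree with DESeq2's estimator on all-nonzero genes", {
  skip_if_not_installed("DESeq2")
  set.seed(65)
  # odd number of all-nonzero genes so the ratio median is a single gene
  mat <- matrix(rpois(205L * 4L, 30) + 1L, ncol = 4L)
  mat[1:40, 1L] <- 0L
  stopifnot(sum(apply(mat, 1L, function(g) all(g > 0))) %% 2L == 1L)
  want <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(unname(size_factors(mat)), unname(want), tolerance = 1e-10)
})

test_that("normalization fails informatively when no gene is shared", {
  mat <- cbind(s1 = c(1L, 0L), s2 = c(0L, 2L))
  expect_error(size_factors(mat), "pseudo-bulk")
})

test_that("log2_pseudo is exact on integer landmarks and rejects negatives", {
  expect_equal(log2_pseudo(c(0, 1, 7)), c(0, 1, 3))
  expect_error(log2_pseudo(-1), "non-negative")
})

test_that("pearson_matrix reproduces the textbook formula and edge cases", {
  set.seed(66)
  x <- rnorm(100L)
  y <- x + rnorm(100L, sd = 0.5)
  rep <- pearson_matrix(cbind(a = x, b = y, c = max(x) - x))
  expect_equal(rep$matrix["a", "b"], oracle_pearson(x, y),
               tolerance = 1e-12)
  expect_equal(rep$matrix["a", "c"], -1)
  expect_equal(rep$matrix["a", "a"], 1)
  expect_true(isSymmetric(rep$matrix))
  expect_equal(rep$mean_r, mean(rep$matrix[upper.tri(rep$matrix)]))
  expect_error(pearson_matrix(cbind(a = x, flat = rep(1, 100L))), "flat")
})

test_that("pearson r is invariant under positive affine rescaling", {
  set.seed(67)
  x <- rpois(150L, 10)
  y <- rpois(150L, 10)
  r0 <- pearson_matrix(cbind(x, y))$matrix[1L, 2L]
  r1 <- pearson_matrix(cbind(x * 3.7 + 2, y))$matrix[1L, 2L]
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("pure depth differences vanish after normalization and log transform", {
  set.seed(68)
  a <- rpois(300L, 25)
  mat <- cbind(s1 = a, s2 = 3 * a)
  sf <- size_factors(mat)
  expect_equal(unname(sf[2L] / sf[1L]), 3, tolerance = 1e-12)
  norm <- log2_pseudo(normalize_counts(mat, sf))
  expect_equal(unname(norm[, 1L]), unname(norm[, 2L]), tolerance = 1e-12)
  expect_equal(pearson_matrix(norm)$matrix[1L, 2L], 1, tolerance = 1e-12)
})

test_that("coefficient of variation matches hand computation", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2,
               tolerance = 1e-12)
  set.seed(69)
  v <- runif(6L, 4e6, 5e6)
  expect_equal(coefficient_of_variation(v), 100 * sd(v) / mean(v))
  expect_error(coefficient_of_variation(c(-1, 1)), "mean 0")
  expect_error(coefficient_of_variation(3), "at least 2")
})

test_that("increasing Poisson noise on one replicate decreases expected r", {
  base <- bulk_sum(fix_profiles$expression) * 20
  levels <- c(0, 2, 8, 32)
  mean_r <- vapply(seq_along(levels), function(i) {
    rs <- vapply(1:8, function(s) {
      set.seed(70L + 8L * i + s)
      noisy <- base + rpois(length(base), levels[i] * 20)
      pearson_matrix(log2_pseudo(cbind(base, noisy)))$matrix[1L, 2L]
    }, numeric(1L))
    mean(rs)
  }, numeric(1L))
  expect_true(all(diff(mean_r) < 0))
})

test_that("region-level correlations vary more than bulk correlations", {
  tx <- make_transcriptome(n_genes = 80L, length_range = c(300L, 500L),
                           seed = 71L)
  d <- make_array_design(n_spots = 120L, n_cols = 12L, seed = 71L)
  p <- make_spot_profiles(d, tx, baseline_mean = 0.6, seed = 71L)
  r_bulk <- numeric(20L)
  r_region <- numeric(20L)
  for (i in 1:20) {
    secs <- simulate_section_counts(p, n_sections = 2L, tech_sd = 0.1,
                                    seed = 100L + i)
    r_bulk[i] <- replicate_concordance(secs)$mean_r
    r_region[i] <- replicate_concordance(secs, region = p$region_spots)$mean_r
  }
  expect_gt(var(r_region), var(r_bulk))
})

test_that("replicate_concordance wires averaging, normalization and correlation", {
  secs <- simulate_section_counts(fix_profiles, n_sections = 3L,
                                  tech_sd = 0.05, seed = 72L)
  rep <- replicate_concordance(secs, sample_ids = c("a", "b", "c"))
  expect_s3_class(rep, "correlation_report")
  expect_equal(dim(rep$matrix), c(3L, 3L))
  expect_equal(unname(diag(rep$matrix)), rep(1, 3L))
  expect_true(all(rep$matrix >= -1 & rep$matrix <= 1))
  expect_length(rep$size_factors, 3L)
})
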
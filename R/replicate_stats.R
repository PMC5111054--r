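#' Sum counts over all spots (pseudo-bulk)
#'
#' Collapses a spot-by-gene matrix to per-gene totals over all spatial
#' barcodes — the sample-level vector used for bulk replicate comparison.
#'
#' @param counts A `spot_counts` or a spots-by-genes matrix.
#' @return Named numeric vector of per-gene totals.
#' @export
bulk_sum <- function(counts) {
  mat <- if (inherits(counts, "spot_counts")) counts$matrix else counts
  colSums(mat)
}

#' Average counts over a region of spots
#'
#' Per-gene arithmetic mean over the selected spots (spots with zero counts
#' count in the denominator) — the "average spot" of a tissue region such
#' as an inflamed area shared across consecutive sections.
#'
#' @param counts A `spot_counts` or a spots-by-genes matrix with `"x_y"`
#'   row labels.
#' @param region Character vector of spot labels (`"x_y"`).
#' @return Named numeric vector of per-gene means.
#' @export
region_average <- function(counts, region) {
  mat <- if (inherits(counts, "spot_counts")) counts$matrix else counts
  if (length(region) == 0L) stop("region is empty")
  missing <- setdiff(region, rownames(mat))
  if (length(missing) > 0L)
    stop("unknown spot(s): ", paste(missing, collapse = ", "))
  colMeans(mat[region, , drop = FALSE])
}

#' Median-of-ratios size factors
#'
#' The median-of-ratios estimator: for sample `j`, the size factor is the
#' median over genes — restricted to genes with nonzero counts in every
#' sample — of `count_gj / geometric_mean_over_samples(count_g.)`.
#' Normalized counts are `count_gj / s_j`; a pure depth difference between
#' samples is removed exactly.
#'
#' @param samples Genes-by-samples numeric matrix (or data frame), or a
#'   list of equal-length named per-gene vectors.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(samples) {
  mat <- as_sample_matrix(samples)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  ok <- rowSums(mat > 0) == ncol(mat)
  if (!any(ok))
    stop("no gene has nonzero counts in every sample; pool spots ",
         "(pseudo-bulk) or filter samples before normalizing")
  logg <- rowMeans(log(mat[ok, , drop = FALSE]))
  apply(mat[ok, , drop = FALSE], 2L, function(v) median(v / exp(logg)))
}

as_sample_matrix <- function(samples) {
  if (is.list(samples) && !is.data.frame(samples)) {
    genes <- names(samples[[1L]])
    if (!all(vapply(samples, function(s)
      identical(names(s), genes), logical(1L))))
      stop("samples must share one gene universe (same names, same order)")
    mat <- do.call(cbind, samples)
  } else {
    mat <- as.matrix(samples)
  }
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("sample_", seq_len(ncol(mat)))
  mat
}

#' Normalize samples by their size factors
#'
#' @inheritParams size_factors
#' @param factors Optional precomputed size factors (default: estimated
#'   with [size_factors()]).
#' @return Genes-by-samples matrix of normalized counts.
#' @export
normalize_counts <- function(samples, factors = NULL) {
  mat <- as_sample_matrix(samples)
  if (is.null(factors)) factors <- size_factors(mat)
  sweep(mat, 2L, factors, "/")
}

#' Shifted log2 transform
#'
#' Adds a pseudo-count of one and takes log2: `log2(v + 1)`.
#'
#' @param values Non-negative numeric vector or matrix.
#' @return Transformed values, same shape.
#' @export
log2_pseudo <- function(values) {
  if (any(values < 0)) stop("log2_pseudo requires non-negative values")
  log2(values + 1)
}

#' Pairwise Pearson correlation of transformed samples
#'
#' Standard Pearson correlation per sample pair over the shared gene
#' vector (all genes, zeros included), with the group summary taken as the
#' mean of the off-diagonal entries.
#'
#' @param samples Genes-by-samples matrix (typically normalized and
#'   log2-transformed), or a list of per-gene vectors.
#' @return An object of class `correlation_report`: list with `matrix`
#'   (pairwise Pearson r), `sample_ids`, and `mean_r` (off-diagonal mean).
#' @export
pearson_matrix <- function(samples) {
  mat <- as_sample_matrix(samples)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  v <- apply(mat, 2L, sd)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[v == 0], collapse = ", "))
  r <- cor(mat, method = "pearson")
  structure(list(matrix = r, sample_ids = colnames(mat),
                 mean_r = mean(r[upper.tri(r)])),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d samples, mean pairwise r = %.4f\n",
              length(x$sample_ids), x$mean_r))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(values) / mean(values)` with the sample (n - 1) standard
#' deviation — the dispersion measure used to compare replicate groups.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("coefficient of variation is undefined for mean 0")
  100 * sd(values) / m
}

#' Replicate concordance of count samples
#'
#' The full between-replicate comparison in one call: per-gene sample
#' vectors (bulk sums over all spots, or region averages when `region` is
#' given) are size-factor normalized, log2(x + 1) transformed, and
#' correlated pairwise; the report carries the correlation matrix and its
#' off-diagonal mean. Region averaging precedes normalization.
#'
#' @param counts_list List of `spot_counts` (or spots-by-genes matrices)
#'   sharing one gene universe.
#' @param region Optional character vector of `"x_y"` spot labels; when
#'   given, samples are region averages instead of bulk sums.
#' @param sample_ids Optional sample names.
#' @return A `correlation_report` with an extra `size_factors` element and
#'   the `normalized` genes-by-samples matrix.
#' @export
replicate_concordance <- function(counts_list, region = NULL,
                                  sample_ids = NULL) {
  vecs <- lapply(counts_list, function(cc) {
    if (is.null(region)) bulk_sum(cc) else region_average(cc, region)
  })
  mat <- do.call(cbind, vecs)
  colnames(mat) <- if (is.null(sample_ids))
    paste0("sample_", seq_along(vecs)) else sample_ids
  sf <- size_factors(mat)
  norm <- normalize_counts(mat, sf)
  rep_report <- pearson_matrix(log2_pseudo(norm))
  rep_report$size_factors <- sf
  rep_report$normalized <- norm
  rep_report
}
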
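#' Library-complexity saturation curve by downsampling
#'
#' Downsamples the annotated-read multiset (reads that survived trimming,
#' ribosomal screening, mapping, annotation and barcode matching, before
#' UMI collapse) to predefined depths without replacement and counts the
#' distinct (spot, gene, UMI) triples — unique transcripts — at each depth.
#' With `n_replicates > 1` each depth is resampled and the per-depth mean
#' and standard deviation reported. Within a replicate the samples are
#' nested (the depth-`d` sample is the first `d` reads of one random
#' permutation), so each depth is a uniform without-replacement sample and
#' every per-replicate curve is monotone non-decreasing. The curve plateaus
#' when the library is sequenced to exhaustion.
#'
#' @param annotated Data frame of annotated reads (columns `spot`,
#'   `gene_id`, `umi`), or a `spot_counts` carrying one.
#' @param depths Integer vector of read depths, ascending; defaults to 10
#'   evenly spaced points from 10 to 100 percent of the total.
#' @param n_replicates Resampling replicates per depth (default 1).
#' @param seed Integer seed.
#' @return An object of class `saturation_curve`: data frame with columns
#'   `depth`, `mean_unique`, `sd_unique` (NA when `n_replicates == 1`).
#' @export
saturation_curve <- function(annotated, depths = NULL, n_replicates = 1L,
                             seed = 1L) {
  if (inherits(annotated, "spot_counts")) annotated <- annotated$annotated
  stopifnot(all(c("spot", "gene_id", "umi") %in% names(annotated)))
  n <- nrow(annotated)
  mol <- as.integer(factor(paste(annotated$spot, annotated$gene_id,
                                 annotated$umi)))
  if (is.null(depths)) depths <- unique(round(seq(0.1, 1, by = 0.1) * n))
  depths <- as.integer(depths)
  if (is.unsorted(depths)) stop("depths must be sorted ascending")
  too_deep <- depths[depths > n]
  if (length(too_deep) > 0L)
    stop("depth ", too_deep[1L], " exceeds the total of ", n,
         " annotated reads")
  set.seed(seed)
  # Nested sampling: one permutation per replicate; the first d reads of the
  # permutation are a uniform without-replacement sample at depth d, and the
  # per-replicate curve is monotone non-decreasing by construction.
  u <- vapply(seq_len(n_replicates), function(r) {
    cum <- cumsum(!duplicated(mol[sample.int(n)]))
    ifelse(depths == 0L, 0L, cum[pmax(depths, 1L)])
  }, numeric(length(depths)))
  u <- matrix(u, nrow = length(depths))
  stats <- rbind(rowMeans(u),
                 if (n_replicates > 1L) apply(u, 1L, sd)
                 else rep(NA_real_, length(depths)))
  structure(data.frame(depth = depths, mean_unique = stats[1L, ],
                       sd_unique = stats[2L, ]),
            n_replicates = as.integer(n_replicates), seed = seed,
            class = c("saturation_curve", "data.frame"))
}

#' Closed-form expected saturation curve
#'
#' For sampling `d` of `N` reads without replacement, a molecule observed
#' in `c` reads is recovered unless all its copies are missed, so the
#' expected unique-transcript count at depth `d` is
#' `sum_m (1 - choose(N - c_m, d) / choose(N, d))` over molecules `m`. Used
#' as the independent oracle for [saturation_curve()].
#'
#' @param copies Integer vector of per-molecule duplicate read counts
#'   (e.g. `n_copies` from the simulator's ground truth).
#' @param depths Integer vector of read depths.
#' @return Numeric vector of expected unique-transcript counts.
#' @export
saturation_expected <- function(copies, depths) {
  copies <- as.integer(copies)
  N <- sum(copies)
  tab <- table(copies)
  cs <- as.integer(names(tab))
  ns <- as.integer(tab)
  vapply(depths, function(d) {
    if (d > N) stop("depth ", d, " exceeds total reads ", N)
    p_miss <- exp(lchoose(N - cs, d) - lchoose(N, d))
    p_miss[N - cs < d] <- 0
    sum(ns * (1 - p_miss))
  }, numeric(1L))
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("saturation_curve: %d depths, %d replicate draw(s) per depth\n",
              nrow(x), attr(x, "n_replicates")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.saturation_curve <- function(x, ...) {
  graphics::plot(x$depth, x$mean_unique, type = "b", pch = 16,
                 xlab = "sequencing depth (annotated reads)",
                 ylab = "unique transcripts", ...)
  invisible(x)
}

#' Downsample a FASTQ pair, preserving pairing
#'
#' Keeps the same uniformly chosen record indices in both files, preserving
#' pairing and original record order — the step used to bring libraries to
#' a common raw-read depth before processing.
#'
#' @param fwd,rev Input FASTQ paths (paired, equal record counts).
#' @param n Number of read pairs to keep.
#' @param fwd_out,rev_out Output paths.
#' @param seed Integer seed.
#' @return Named list of the output paths, invisibly.
#' @export
downsample_fastq <- function(fwd, rev, n,
                             fwd_out = tempfile(fileext = "_R1.fastq"),
                             rev_out = tempfile(fileext = "_R2.fastq"),
                             seed = 1L) {
  lf <- readLines(fwd)
  lr <- readLines(rev)
  if (length(lf) %% 4L != 0L || length(lr) %% 4L != 0L)
    stop("FASTQ record count is not a multiple of 4")
  nf <- length(lf) %/% 4L
  nr <- length(lr) %/% 4L
  if (nf != nr)
    stop("desynchronized FASTQ pair: ", nf, " forward vs ", nr,
         " reverse records")
  if (n > nf) stop("cannot sample ", n, " pairs from ", nf)
  set.seed(seed)
  keep <- sort(sample.int(nf, n))
  rows <- rep((keep - 1L) * 4L, each = 4L) + seq_len(4L)
  writeLines(lf[rows], fwd_out)
  writeLines(lr[rows], rev_out)
  invisible(list(fwd = fwd_out, rev = rev_out))
}
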
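#' Synthetic data generation
#'
#' These functions build a fully specified toy experiment — an array design,
#' a small transcriptome, per-spot expression with a localized inflamed
#' region, and paired FASTQ reads with PCR duplicates, base-call errors,
#' low-quality 3' tails and ribosomal contamination — together with the
#' ground-truth molecule table, so that every downstream stage of the
#' pipeline can be validated against known truth.
#'
#' @name synthetic_data
NULL

random_dna <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1L))
}

spot_labels <- function(design) paste(design$x, design$y, sep = "_")

#' Generate a random barcoded array design
#'
#' Spots are laid out on a rectangular grid (filled row by row) and each
#' receives a unique random barcode. The default of 1007 spots mirrors the
#' subarray format of printed spatial arrays.
#'
#' @param n_spots Number of spots.
#' @param n_cols Number of grid columns (rows are filled as needed).
#' @param barcode_length Barcode length in bases.
#' @param umi_length,umi_pattern UMI geometry, as in [array_design()].
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return An `array_design`.
#' @export
make_array_design <- function(n_spots = 1007L, n_cols = 33L,
                              barcode_length = 18L, umi_length = 9L,
                              umi_pattern = "WSNNWSNNV", seed = 1L) {
  stopifnot(n_spots >= 1L, n_cols >= 1L, barcode_length >= 1L)
  set.seed(seed)
  barcodes <- character(0L)
  while (length(barcodes) < n_spots) {
    barcodes <- unique(c(barcodes,
                         random_dna(rep(barcode_length,
                                        n_spots - length(barcodes)))))
  }
  idx <- seq_len(n_spots) - 1L
  array_design(barcodes[seq_len(n_spots)],
               x = idx %% n_cols, y = idx %/% n_cols,
               umi_length = umi_length, umi_pattern = umi_pattern)
}

#' Generate a toy transcriptome with ribosomal sequences
#'
#' Gene sequences are uniform random DNA; a fixed fraction is flagged
#' polyadenylated (the only species the array's oligo-dT primer captures and
#' the only annotation used for counting). The generated set always contains
#' at least one polyadenylated and one non-polyadenylated gene so the
#' annotation filter has work to do.
#'
#' @param n_genes Number of genes (>= 2).
#' @param length_range Two-vector of transcript length bounds in bases.
#' @param polyA_fraction Fraction of genes flagged polyadenylated (in (0, 1)).
#' @param n_rrna Number of ribosomal sequences.
#' @param rrna_length_range Two-vector of rRNA length bounds in bases.
#' @param seed Integer seed.
#' @return An object of class `transcriptome`: list with `genes` (data frame
#'   `gene_id`, `polyA`, `length`), `seqs` and `rrna` (named character
#'   vectors of sequences).
#' @export
make_transcriptome <- function(n_genes = 100L, length_range = c(400L, 1500L),
                               polyA_fraction = 0.8, n_rrna = 2L,
                               rrna_length_range = c(1500L, 1900L),
                               seed = 1L) {
  if (n_genes < 2L) stop("n_genes must be >= 2")
  if (polyA_fraction <= 0 || polyA_fraction >= 1)
    stop("polyA_fraction must be strictly between 0 and 1")
  check_range <- function(r, what) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L)
      stop("degenerate ", what, ": ", paste(r, collapse = ", "))
  }
  check_range(length_range, "length_range")
  check_range(rrna_length_range, "rrna_length_range")
  set.seed(seed)
  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  lens <- sample(length_range[1L]:length_range[2L], n_genes, replace = TRUE)
  seqs <- setNames(random_dna(lens), gene_id)
  n_polyA <- min(max(round(n_genes * polyA_fraction), 1L), n_genes - 1L)
  polyA <- rep(FALSE, n_genes)
  polyA[sample.int(n_genes, n_polyA)] <- TRUE
  rrna <- character(0L)
  if (n_rrna > 0L) {
    rlens <- sample(rrna_length_range[1L]:rrna_length_range[2L], n_rrna,
                    replace = TRUE)
    rrna <- setNames(random_dna(rlens), sprintf("rRNA_%02d", seq_len(n_rrna)))
  }
  structure(list(genes = data.frame(gene_id = gene_id, polyA = polyA,
                                    length = lens, stringsAsFactors = FALSE),
                 seqs = seqs, rrna = rrna),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d genes (%d polyadenylated), %d rRNA sequences\n",
              nrow(x$genes), sum(x$genes$polyA), length(x$rrna)))
  invisible(x)
}

#' Write transcriptome FASTA and annotation files
#'
#' @param tx A `transcriptome`.
#' @param fasta Path for the gene FASTA.
#' @param annotation Optional path for the annotation TSV (columns `gene_id`,
#'   `polyA`, `length`).
#' @param rrna_fasta Optional path for the ribosomal FASTA.
#' @return Named list of the paths written, invisibly.
#' @export
write_transcriptome <- function(tx, fasta, annotation = NULL,
                                rrna_fasta = NULL) {
  stopifnot(inherits(tx, "transcriptome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx$seqs), fasta)
  if (!is.null(annotation))
    write.table(tx$genes, annotation, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(rrna_fasta))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx$rrna), rrna_fasta)
  invisible(list(fasta = fasta, annotation = annotation,
                 rrna_fasta = rrna_fasta))
}

#' Read a polyadenylation annotation table
#'
#' @param path TSV with header and columns `gene_id`, `polyA`, `length`.
#' @return Data frame with those columns (`polyA` logical).
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("gene_id", "polyA", "length") %in% names(tab)))
    stop("annotation file ", path,
         " must have columns gene_id, polyA, length")
  tab$polyA <- as.logical(tab$polyA)
  tab
}

#' Per-spot expression profiles with an inflamed-region effect
#'
#' Draws a mean expression level per gene (gamma distributed, mean
#' `baseline_mean` molecules per spot) shared by all spots, then scales a
#' random subset of polyadenylated genes by `region_effect` inside a
#' contiguous block of `region_size` spots — the synthetic analogue of an
#' inflamed region shared across consecutive replicate sections.
#'
#' @param design An `array_design`.
#' @param tx A `transcriptome`.
#' @param baseline_mean Mean molecules per spot per gene.
#' @param region_effect Fold-change applied to the affected genes inside the
#'   region (1 = no effect).
#' @param region_size Number of spots in the region (default 10).
#' @param region_gene_fraction Fraction of polyadenylated genes affected.
#' @param seed Integer seed.
#' @return An object of class `spot_profiles`: list with the `design`, the
#'   spots-by-genes `expression` matrix of mean molecule counts (row names
#'   `"x_y"`), `region_spots` (spot labels) and `region_genes`.
#' @export
make_spot_profiles <- function(design, tx, baseline_mean = 10,
                               region_effect = 4, region_size = 10L,
                               region_gene_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(design, "array_design"), inherits(tx, "transcriptome"))
  if (region_size > nrow(design))
    stop("region_size (", region_size, ") exceeds number of spots (",
         nrow(design), ")")
  set.seed(seed)
  n_genes <- nrow(tx$genes)
  mu <- rgamma(n_genes, shape = 2, scale = baseline_mean / 2)
  expr <- matrix(mu, nrow = nrow(design), ncol = n_genes, byrow = TRUE,
                 dimnames = list(spot_labels(design), tx$genes$gene_id))
  ord <- order(design$y, design$x)
  start <- (nrow(design) - region_size) %/% 2L + 1L
  region_idx <- ord[seq(start, length.out = region_size)]
  region_spots <- spot_labels(design)[region_idx]
  polyA_genes <- tx$genes$gene_id[tx$genes$polyA]
  n_aff <- max(1L, round(length(polyA_genes) * region_gene_fraction))
  region_genes <- sample(polyA_genes, n_aff)
  expr[region_idx, region_genes] <- expr[region_idx, region_genes] *
    region_effect
  structure(list(design = design, expression = expr,
                 region_spots = region_spots, region_genes = region_genes,
                 baseline_mean = baseline_mean,
                 region_effect = region_effect),
            class = "spot_profiles")
}

#' @export
print.spot_profiles <- function(x, ...) {
  cat(sprintf(paste0("spot_profiles: %d spots x %d genes, ",
                     "%d-spot region, effect %gx on %d genes\n"),
              nrow(x$expression), ncol(x$expression),
              length(x$region_spots), x$region_effect,
              length(x$region_genes)))
  invisible(x)
}

# Draw n UMIs matching an IUPAC pattern.
draw_umis <- function(n, pattern) {
  codes <- strsplit(pattern, "")[[1L]]
  cols <- lapply(codes, function(code) {
    chars <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1L]]
    chars[sample.int(length(chars), n, replace = TRUE)]
  })
  do.call(paste0, cols)
}

umi_pattern_space <- function(pattern) {
  codes <- strsplit(pattern, "")[[1L]]
  prod(vapply(codes, function(code)
    nchar(Biostrings::IUPAC_CODE_MAP[[code]]), numeric(1L)))
}

#' Simulate paired spatially barcoded reads with ground truth
#'
#' For every (spot, gene), a molecule count is drawn from a Poisson
#' distribution with the profile mean; each molecule receives a UMI drawn
#' from the design's semi-random IUPAC pattern (unique within its spot/gene
#' pair) and emits `1 + Geometric(mean = dup_mean - 1)` read pairs (PCR
#' duplicates share the molecule's fragment). The reverse read is a
#' 3'-biased window of the transcript of length `layout$reverse_length`,
#' with per-base substitution errors and, with probability `tail_lowq_prob`,
#' a low-quality 3' tail; transcripts shorter than the read are padded from
#' the poly-A tail. The forward read is barcode + UMI + oligo-dT filler.
#' Ribosomal and unalignable noise reads can be mixed in at given fractions
#' of the final read total.
#'
#' By default only polyadenylated genes emit molecules (oligo-dT capture);
#' `non_polyA_capture` > 0 adds background-primed molecules from
#' non-polyadenylated genes at that multiple of their profile means.
#'
#' @param profiles A `spot_profiles`.
#' @param tx The `transcriptome` the profiles refer to.
#' @param layout A `read_layout`; its barcode/UMI widths must match the
#'   design.
#' @param fwd,rev Output FASTQ paths (Phred+33).
#' @param dup_mean Mean read pairs per molecule (>= 1).
#' @param error_rate Per-base substitution rate on the reverse read.
#' @param forward_error_rate Per-base substitution rate on the forward read.
#' @param tail_lowq_prob Probability a reverse read gets a low-quality tail.
#' @param rrna_fraction Fraction of emitted read pairs drawn from rRNA.
#' @param noise_fraction Fraction of emitted read pairs that are random DNA.
#' @param non_polyA_capture Multiplier on non-polyadenylated gene means
#'   (0 = pure oligo-dT capture).
#' @param qual_high Phred score of ordinary base calls.
#' @param qual_low_range Two-vector of Phred bounds for low-quality tails.
#' @param tail_length_range Two-vector of tail length bounds in bases.
#' @param frag_offset_mean Mean distance (bases, exponential) of the
#'   fragment 3' end from the transcript 3' end.
#' @param seed Integer seed; output FASTQ files are byte-identical across
#'   runs with the same seed.
#' @return An object of class `sim_reads`: list with `fwd`, `rev` (paths),
#'   `ground_truth` (data frame `barcode`, `x`, `y`, `gene_id`, `umi`,
#'   `n_copies`, class `ground_truth`, with attributes `n_rrna_reads`,
#'   `n_noise_reads`, `total_read_pairs`) and `counters`.
#' @export
simulate_reads <- function(profiles, tx, layout = read_layout(),
                           fwd = tempfile(fileext = "_R1.fastq"),
                           rev = tempfile(fileext = "_R2.fastq"),
                           dup_mean = 1, error_rate = 0,
                           forward_error_rate = 0, tail_lowq_prob = 0,
                           rrna_fraction = 0, noise_fraction = 0,
                           non_polyA_capture = 0, qual_high = 37L,
                           qual_low_range = c(2L, 8L),
                           tail_length_range = c(10L, 40L),
                           frag_offset_mean = 20, seed = 1L) {
  stopifnot(inherits(profiles, "spot_profiles"), inherits(tx, "transcriptome"),
            inherits(layout, "read_layout"))
  if (dup_mean < 1) stop("dup_mean must be >= 1")
  for (p in c(error_rate, forward_error_rate, tail_lowq_prob,
              rrna_fraction, noise_fraction))
    if (p < 0 || p > 1) stop("rates and fractions must lie in [0, 1]")
  if (rrna_fraction + noise_fraction >= 1)
    stop("rrna_fraction + noise_fraction must be < 1")
  design <- profiles$design
  if (attr(design, "barcode_length") !=
      layout$barcode_span[2L] - layout$barcode_span[1L])
    stop("layout barcode width does not match the design barcode length")
  L <- layout$reverse_length
  set.seed(seed)

  expr <- profiles$expression
  polyA <- tx$genes$polyA[match(colnames(expr), tx$genes$gene_id)]
  expr[, !polyA] <- expr[, !polyA] * non_polyA_capture
  # non-polyA transcripts shorter than the read cannot be padded: skip gene
  too_short <- !polyA & tx$genes$length[match(colnames(expr),
                                              tx$genes$gene_id)] < L
  if (any(too_short) && any(expr[, too_short] > 0)) {
    warning("skipping non-polyadenylated gene(s) shorter than the reverse ",
            "read: ", paste(colnames(expr)[too_short], collapse = ", "))
    expr[, too_short] <- 0
  }

  # molecules per (spot, gene)
  n_mol <- rpois(length(expr), as.vector(expr))
  cell <- which(n_mol > 0L)
  mol_spot <- rep(((cell - 1L) %% nrow(expr)) + 1L, n_mol[cell])
  mol_gene <- rep(((cell - 1L) %/% nrow(expr)) + 1L, n_mol[cell])
  n_molecules <- length(mol_spot)
  if (n_molecules == 0L) stop("no molecules drawn; increase expression means")

  # UMIs, unique within each (spot, gene)
  pattern <- attr(design, "umi_pattern")
  space <- umi_pattern_space(pattern)
  group <- paste(mol_spot, mol_gene)
  if (max(tabulate(factor(group))) > space)
    stop("more molecules in one (spot, gene) than the UMI pattern space (",
         space, "); use a longer UMI")
  umi <- draw_umis(n_molecules, pattern)
  repeat {
    dup <- duplicated(paste(group, umi))
    if (!any(dup)) break
    umi[dup] <- draw_umis(sum(dup), pattern)
  }

  # fragments (3'-biased windows; PCR copies share the fragment)
  gene_ids <- colnames(expr)
  tlen <- nchar(tx$seqs)[match(gene_ids, names(tx$seqs))]
  mol_tlen <- tlen[mol_gene]
  offset <- floor(rexp(n_molecules, rate = 1 / frag_offset_mean))
  frag_end <- mol_tlen - pmin(offset, pmax(mol_tlen - L, 0L))
  frag <- substr(tx$seqs[mol_gene], pmax(frag_end - L + 1L, 1L), frag_end)
  pad <- L - nchar(frag)
  if (any(pad > 0L))
    frag[pad > 0L] <- paste0(frag[pad > 0L], strrep("A", pad[pad > 0L]))

  # PCR duplication
  copies <- 1L + if (dup_mean > 1)
    rgeom(n_molecules, prob = 1 / dup_mean) else integer(n_molecules)
  read_mol <- rep(seq_len(n_molecules), copies)
  n_signal <- length(read_mol)

  # contamination read counts so the requested fractions refer to the total
  denom <- 1 - rrna_fraction - noise_fraction
  n_rrna <- round(n_signal * rrna_fraction / denom)
  n_noise <- round(n_signal * noise_fraction / denom)
  if (n_rrna > 0L && length(tx$rrna) == 0L)
    stop("rrna_fraction > 0 but the transcriptome has no rRNA sequences")
  if (n_rrna > 0L && any(nchar(tx$rrna) < L))
    stop("rRNA sequences shorter than the reverse read length")

  rev_seq <- frag[read_mol]
  if (n_rrna > 0L) {
    rsrc <- sample.int(length(tx$rrna), n_rrna, replace = TRUE)
    rstart <- floor(runif(n_rrna, 1, nchar(tx$rrna)[rsrc] - L + 1 + 1))
    rev_seq <- c(rev_seq, substr(tx$rrna[rsrc], rstart, rstart + L - 1L))
  }
  if (n_noise > 0L) rev_seq <- c(rev_seq, random_dna(rep(L, n_noise)))
  rev_seq <- cpp_mutate_seqs(rev_seq, error_rate)

  # forward reads: barcode + UMI + oligo-dT filler
  n_total <- n_signal + n_rrna + n_noise
  fill <- strrep("T", layout$forward_length - layout$umi_span[2L])
  contam_spot <- sample.int(nrow(design), n_rrna + n_noise, replace = TRUE)
  fwd_spot <- c(mol_spot[read_mol], contam_spot)
  fwd_umi <- c(umi[read_mol], draw_umis(n_rrna + n_noise, pattern))
  fwd_seq <- paste0(design$barcode[fwd_spot], fwd_umi, fill)
  fwd_seq <- cpp_mutate_seqs(fwd_seq, forward_error_rate)

  # qualities
  hi <- intToUtf8(33L + qual_high)
  rev_qual <- strrep(hi, nchar(rev_seq))
  if (tail_lowq_prob > 0) {
    tailed <- which(runif(n_total) < tail_lowq_prob)
    if (length(tailed) > 0L) {
      tl <- pmin(sample(tail_length_range[1L]:tail_length_range[2L],
                        length(tailed), replace = TRUE), L - 1L)
      lows <- vapply(tl, function(m)
        intToUtf8(33L + sample(qual_low_range[1L]:qual_low_range[2L], m,
                               replace = TRUE)), character(1L))
      rev_qual[tailed] <- paste0(strrep(hi, L - tl), lows)
    }
  }
  fwd_qual <- strrep(hi, layout$forward_length)

  # shuffle and write
  ord <- sample.int(n_total)
  ids <- sprintf("read_%07d", seq_len(n_total))
  write_fastq(ids, fwd_seq[ord], rep(fwd_qual, n_total), fwd)
  write_fastq(ids, rev_seq[ord], rev_qual[ord], rev)

  gt <- data.frame(barcode = design$barcode[mol_spot],
                   x = design$x[mol_spot], y = design$y[mol_spot],
                   gene_id = gene_ids[mol_gene], umi = umi,
                   n_copies = copies, stringsAsFactors = FALSE)
  attr(gt, "n_rrna_reads") <- n_rrna
  attr(gt, "n_noise_reads") <- n_noise
  attr(gt, "total_read_pairs") <- n_total
  class(gt) <- c("ground_truth", "data.frame")
  structure(list(fwd = fwd, rev = rev, ground_truth = gt, layout = layout,
                 counters = list(n_molecules = n_molecules,
                                 n_signal_reads = n_signal,
                                 n_rrna_reads = n_rrna,
                                 n_noise_reads = n_noise,
                                 total_read_pairs = n_total)),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(paste0("sim_reads: %d molecules -> %d read pairs ",
                     "(+%d rRNA, +%d noise)\n  fwd: %s\n  rev: %s\n"),
              x$counters$n_molecules, x$counters$n_signal_reads,
              x$counters$n_rrna_reads, x$counters$n_noise_reads,
              x$fwd, x$rev))
  invisible(x)
}

write_fastq <- function(ids, seqs, quals, path) {
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- ids
  Biostrings::writeXStringSet(xs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

read_fastq <- function(path) {
  xs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(id = names(xs), seq = as.character(xs),
             qual = as.character(S4Vectors::mcols(xs)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ground-truth spot-by-gene molecule matrix
#'
#' Tabulates the ground-truth molecule table into the same spots-by-genes
#' layout as the pipeline output, for cell-by-cell recovery checks.
#'
#' @param gt A `ground_truth` data frame from [simulate_reads()].
#' @param design The `array_design` used in the simulation.
#' @param gene_ids Column universe (default: the genes present in `gt`).
#' @return Integer matrix, spots (rows, `"x_y"` labels) by genes.
#' @export
ground_truth_matrix <- function(gt, design, gene_ids = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(design, "array_design"))
  if (is.null(gene_ids)) gene_ids <- sort(unique(gt$gene_id))
  labels <- spot_labels(design)
  tab <- table(factor(paste(gt$x, gt$y, sep = "_"), levels = labels),
               factor(gt$gene_id, levels = gene_ids))
  mat <- matrix(as.integer(tab), nrow = length(labels),
                dimnames = list(labels, gene_ids))
  mat
}

#' Simulate count matrices for replicate sections
#'
#' Draws independent Poisson counts per section from the shared spot
#' profiles, optionally perturbed by per-gene, per-section lognormal
#' technical noise (`exp(N(0, tech_sd^2))` scale factors) — the knob used to
#' contrast low-noise (automation-like) and high-noise (manual-like)
#' replicate groups at the count level without re-simulating reads.
#'
#' @param profiles A `spot_profiles`.
#' @param n_sections Number of replicate sections.
#' @param tech_sd Standard deviation of the per-gene log-normal technical
#'   scale factor (0 = pure Poisson replicates).
#' @param seed Integer seed.
#' @return List of `n_sections` integer matrices (spots by genes).
#' @export
simulate_section_counts <- function(profiles, n_sections = 2L, tech_sd = 0,
                                    seed = 1L) {
  stopifnot(inherits(profiles, "spot_profiles"), n_sections >= 1L,
            tech_sd >= 0)
  set.seed(seed)
  expr <- profiles$expression
  lapply(seq_len(n_sections), function(s) {
    fac <- exp(rnorm(ncol(expr), 0, tech_sd))
    lam <- sweep(expr, 2L, fac, "*")
    matrix(rpois(length(lam), as.vector(lam)), nrow = nrow(expr),
           dimnames = dimnames(expr))
  })
}
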
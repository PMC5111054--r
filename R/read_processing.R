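#' BWA-style 3' quality trimming
#'
#' Implements the BWA `-q` rule: scanning from the 3' end, the read is cut
#' at the position that maximizes the running sum of
#' `(q_threshold - quality)`; the prefix before the cut is retained. If the
#' maximum is not positive the read is left untouched. Among tied cut
#' points the longest prefix is kept. Reads shorter than `min_length` after
#' trimming are flagged `kept = FALSE`.
#'
#' @param seq Character vector of read sequences.
#' @param qual Character vector of Phred+33 quality strings (same lengths
#'   as `seq`).
#' @param q_threshold Phred quality threshold (default 20).
#' @param min_length Minimum retained length for a read to be kept
#'   (default 25).
#' @return Data frame with columns `seq`, `qual` (trimmed), `kept` and
#'   `trimmed_bases`.
#' @export
trim_bwa <- function(seq, qual, q_threshold = 20L, min_length = 25L) {
  if (length(seq) != length(qual))
    stop("seq and qual must have equal length")
  bad <- nchar(seq) != nchar(qual)
  if (any(bad))
    stop("sequence/quality length mismatch for read(s) ",
         paste(head(which(bad), 3L), collapse = ", "))
  keep_len <- cpp_trim_bwa(qual, as.integer(q_threshold))
  data.frame(seq = substr(seq, 1L, keep_len),
             qual = substr(qual, 1L, keep_len),
             kept = keep_len >= min_length,
             trimmed_bases = nchar(seq) - keep_len,
             stringsAsFactors = FALSE)
}

#' Flag ribosomal reads by k-mer sharing
#'
#' A read is flagged ribosomal when it shares at least `min_shared` distinct
#' k-mers with any single ribosomal reference sequence; both the read and
#' its reverse complement are checked.
#'
#' @param seq Character vector of read sequences.
#' @param rrna Character vector of ribosomal reference sequences.
#' @param k K-mer size (default 15).
#' @param min_shared Minimum shared k-mer count (default 2).
#' @return Logical vector, `TRUE` where the read is ribosomal.
#' @export
filter_ribosomal <- function(seq, rrna, k = 15L, min_shared = 2L) {
  if (length(rrna) == 0L) return(rep(FALSE, length(seq)))
  cpp_max_shared_kmers(seq, rrna, as.integer(k)) >= min_shared
}

#' Map a read against a toy transcriptome
#'
#' Seed-and-extend over a transcriptome k-mer index: transcripts sharing at
#' least `min_seed` k-mers with the read (either strand) are candidates;
#' each is scored by the ungapped match count along its most-seeded
#' diagonal. Candidates are returned sorted by decreasing score with ties
#' retained; an empty result means unmapped.
#'
#' @param seq A single read sequence.
#' @param tx A `transcriptome`, or a named character vector of transcript
#'   sequences.
#' @param k Seed k-mer size (default 15).
#' @param min_seed Minimum shared seed k-mers for candidacy (default 2).
#' @param both_strands Also check the reverse complement (default `TRUE`).
#' @return Data frame with columns `gene_id` and `score`, sorted by
#'   decreasing score.
#' @export
map_read <- function(seq, tx, k = 15L, min_seed = 2L, both_strands = TRUE) {
  refs <- if (inherits(tx, "transcriptome")) tx$seqs else tx
  hit <- cpp_map_candidates(seq, unname(refs), as.integer(k),
                            as.integer(min_seed), both_strands)
  data.frame(gene_id = names(refs)[hit$gene], score = hit$score,
             stringsAsFactors = FALSE)
}

# Batch mapping: best hit, its score and the number of genes tied at the top
# score for each read.
map_reads <- function(seq, tx, k = 15L, min_seed = 2L, both_strands = TRUE) {
  refs <- if (inherits(tx, "transcriptome")) tx$seqs else tx
  hit <- cpp_map_reads(seq, unname(refs), as.integer(k),
                       as.integer(min_seed), both_strands)
  data.frame(gene_id = names(refs)[hit$gene], score = hit$score,
             n_top = hit$n_top, stringsAsFactors = FALSE)
}

#' Resolve mapping candidates to a gene assignment
#'
#' No candidates give `unmapped`; a unique top-scoring gene is `assigned`
#' unless it is not flagged polyadenylated in the annotation (`not_polyA`);
#' two or more genes tied at the top score give `ambiguous` (the read is
#' discarded, mirroring union-mode ambiguity handling).
#'
#' @param candidates Data frame from [map_read()] (columns `gene_id`,
#'   `score`).
#' @param annotation Annotation data frame (`gene_id`, `polyA`).
#' @return List with `gene_id` (or `NA`) and `status` (one of `assigned`,
#'   `unmapped`, `ambiguous`, `not_polyA`).
#' @export
assign_gene <- function(candidates, annotation) {
  if (nrow(candidates) == 0L)
    return(list(gene_id = NA_character_, status = "unmapped"))
  top <- candidates$score == candidates$score[1L]
  if (sum(top) > 1L)
    return(list(gene_id = NA_character_, status = "ambiguous"))
  gene <- candidates$gene_id[1L]
  i <- match(gene, annotation$gene_id)
  if (is.na(i))
    stop("gene ", gene, " is absent from the annotation ",
         "(index/annotation mismatch)")
  if (!annotation$polyA[i])
    return(list(gene_id = NA_character_, status = "not_polyA"))
  list(gene_id = gene, status = "assigned")
}

read_statuses <- c("assigned", "unmapped", "ribosomal", "ambiguous",
                   "not_polyA", "too_short")

#' Process a pair of FASTQ files into per-read gene assignments
#'
#' Runs the read-level stages in order: forward reads are parsed for
#' barcode and UMI (too-short forwards discard the pair); reverse reads are
#' BWA-style quality trimmed (`too_short` when below `min_length`),
#' screened against the ribosomal reference (`ribosomal`), mapped to the
#' transcriptome, and resolved to `assigned` / `unmapped` / `ambiguous` /
#' `not_polyA` using the polyadenylated-only annotation. Every read pair
#' receives exactly one status; the per-status counts partition the input.
#'
#' @param fwd,rev Paths to the forward and reverse FASTQ files (paired,
#'   same order).
#' @param tx A `transcriptome` (or named character vector of transcripts).
#' @param annotation Annotation data frame (`gene_id`, `polyA`); defaults
#'   to the transcriptome's gene table.
#' @param rrna Ribosomal sequences (default: the transcriptome's).
#' @param layout A `read_layout`.
#' @param q_threshold,min_length Trimming parameters (see [trim_bwa()]).
#' @param k,min_seed Mapper parameters (see [map_read()]).
#' @param rrna_min_shared Ribosomal-screen threshold (see
#'   [filter_ribosomal()]).
#' @return A data frame with one row per read pair: `read_id`, `status`,
#'   `gene_id`, `barcode`, `umi`; attribute `status_counts` holds the
#'   per-status tally.
#' @export
process_reads <- function(fwd, rev, tx, annotation = NULL, rrna = NULL,
                          layout = read_layout(), q_threshold = 20L,
                          min_length = 25L, k = 15L, min_seed = 2L,
                          rrna_min_shared = 2L) {
  if (is.null(annotation)) {
    if (!inherits(tx, "transcriptome"))
      stop("annotation is required when tx is not a transcriptome object")
    annotation <- tx$genes
  }
  if (is.null(rrna) && inherits(tx, "transcriptome")) rrna <- tx$rrna
  fq_f <- read_fastq(fwd)
  fq_r <- read_fastq(rev)
  if (nrow(fq_f) != nrow(fq_r))
    stop("forward and reverse FASTQ files have different record counts (",
         nrow(fq_f), " vs ", nrow(fq_r), ")")
  n <- nrow(fq_f)
  status <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)

  parsed <- parse_forward(fq_f$seq, layout)
  status[!parsed$ok] <- "too_short"

  trimmed <- trim_bwa(fq_r$seq, fq_r$qual, q_threshold = q_threshold,
                      min_length = min_length)
  status[is.na(status) & !trimmed$kept] <- "too_short"

  live <- which(is.na(status))
  if (length(live) > 0L && length(rrna) > 0L) {
    ribo <- filter_ribosomal(trimmed$seq[live], rrna, k = k,
                             min_shared = rrna_min_shared)
    status[live[ribo]] <- "ribosomal"
  }

  live <- which(is.na(status))
  if (length(live) > 0L) {
    hits <- map_reads(trimmed$seq[live], tx, k = k, min_seed = min_seed)
    unmapped <- is.na(hits$gene_id)
    status[live[unmapped]] <- "unmapped"
    multi <- !unmapped & hits$n_top > 1L
    status[live[multi]] <- "ambiguous"
    uniq <- which(!unmapped & !multi)
    if (length(uniq) > 0L) {
      ai <- match(hits$gene_id[uniq], annotation$gene_id)
      if (anyNA(ai))
        stop("gene(s) absent from the annotation: ",
             paste(unique(hits$gene_id[uniq][is.na(ai)]), collapse = ", "))
      ok <- annotation$polyA[ai]
      status[live[uniq[!ok]]] <- "not_polyA"
      status[live[uniq[ok]]] <- "assigned"
      gene[live[uniq[ok]]] <- hits$gene_id[uniq[ok]]
    }
  }

  out <- data.frame(read_id = fq_f$id, status = status, gene_id = gene,
                    barcode = parsed$barcode, umi = parsed$umi,
                    stringsAsFactors = FALSE)
  counts <- table(factor(status, levels = read_statuses))
  attr(out, "status_counts") <- setNames(as.integer(counts), names(counts))
  out
}

#' Import externally mapped reads from a SAM file
#'
#' Alternative entry point for the mapping stage: reads QNAME, FLAG, RNAME
#' and MAPQ from a SAM file produced by an external aligner whose reference
#' names are gene identifiers, and resolves each record with the
#' polyadenylated-only annotation (unmapped flag 0x4 gives `unmapped`;
#' records below `min_mapq` are treated as `ambiguous`).
#'
#' @param path Path to a SAM file.
#' @param annotation Annotation data frame (`gene_id`, `polyA`).
#' @param min_mapq Minimum mapping quality (default 1).
#' @return Data frame with `read_id`, `status`, `gene_id`.
#' @export
read_sam_assignments <- function(path, annotation, min_mapq = 1L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(0L), status = character(0L),
                      gene_id = character(0L), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(parts, `[[`, character(1L), 1L)
  flag <- as.integer(vapply(parts, `[[`, character(1L), 2L))
  rname <- vapply(parts, `[[`, character(1L), 3L)
  mapq <- as.integer(vapply(parts, `[[`, character(1L), 5L))
  status <- rep("assigned", length(qname))
  gene <- rname
  unmapped <- bitwAnd(flag, 4L) > 0L | rname == "*"
  status[unmapped] <- "unmapped"
  gene[unmapped] <- NA_character_
  lowq <- !unmapped & mapq < min_mapq
  status[lowq] <- "ambiguous"
  gene[lowq] <- NA_character_
  live <- status == "assigned"
  if (any(live)) {
    ai <- match(gene[live], annotation$gene_id)
    if (anyNA(ai))
      stop("gene(s) absent from the annotation: ",
           paste(unique(gene[live][is.na(ai)]), collapse = ", "))
    bad <- !annotation$polyA[ai]
    idx <- which(live)[bad]
    status[idx] <- "not_polyA"
    gene[idx] <- NA_character_
  }
  data.frame(read_id = qname, status = status, gene_id = gene,
             stringsAsFactors = FALSE)
}
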
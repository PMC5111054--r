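#' Run the full pipeline: paired FASTQ to spot-by-gene molecule counts
#'
#' Chains the read-level stages ([process_reads()]): forward-read parsing,
#' BWA-style reverse-read trimming, ribosomal screening, transcriptome
#' mapping and polyadenylated-annotation assignment — then filters assigned
#' reads by the array design's spot barcodes ([match_barcodes()]) and
#' collapses PCR duplicates per (spot, gene, UMI) ([dedup_umis()]).
#'
#' The returned counters partition every input read pair: the six
#' read-level statuses sum to the input total, and assigned reads split
#' further into barcode-matched (annotated) and barcode-filtered.
#'
#' @param fwd,rev Paths to the paired FASTQ files.
#' @param design An `array_design`.
#' @param tx A `transcriptome` (or named character vector of transcripts,
#'   in which case `annotation` and `rrna` must be supplied).
#' @param annotation Annotation data frame (`gene_id`, `polyA`); defaults
#'   to the transcriptome's.
#' @param rrna Ribosomal reference sequences; defaults to the
#'   transcriptome's.
#' @param layout A `read_layout`.
#' @param max_mismatch Maximum Hamming distance for barcode matching
#'   (default 0 = exact).
#' @param config Optional list of processing parameters (see
#'   [default_config()]); explicit arguments win over config entries.
#' @inheritParams process_reads
#' @return A `spot_counts` whose `counters` record the full accounting:
#'   `total_reads`, the six per-status counts, `barcode_filtered`,
#'   `annotated_reads` and `unique_molecules`; columns cover all
#'   polyadenylated genes in the annotation. The annotated-read multiset
#'   (pre-dedup) is kept in `$annotated` for [saturation_curve()].
#' @export
run_pipeline <- function(fwd, rev, design, tx, annotation = NULL,
                         rrna = NULL, layout = NULL, q_threshold = NULL,
                         min_length = NULL, k = NULL, min_seed = NULL,
                         rrna_min_shared = NULL, max_mismatch = NULL,
                         config = default_config()) {
  cfg <- default_config()
  cfg[names(config)] <- config
  if (is.null(layout))
    layout <- read_layout(forward_length = cfg$forward_length,
                          reverse_length = cfg$reverse_length,
                          barcode_length = cfg$barcode_length,
                          umi_length = cfg$umi_length)
  if (is.null(q_threshold)) q_threshold <- cfg$q_threshold
  if (is.null(min_length)) min_length <- cfg$min_length
  if (is.null(k)) k <- cfg$k
  if (is.null(min_seed)) min_seed <- cfg$min_seed
  if (is.null(rrna_min_shared)) rrna_min_shared <- cfg$rrna_min_shared
  if (is.null(max_mismatch)) max_mismatch <- cfg$max_mismatch
  if (is.null(annotation)) {
    if (!inherits(tx, "transcriptome"))
      stop("annotation is required when tx is not a transcriptome object")
    annotation <- tx$genes
  }

  assign_tab <- process_reads(fwd, rev, tx, annotation = annotation,
                              rrna = rrna, layout = layout,
                              q_threshold = q_threshold,
                              min_length = min_length, k = k,
                              min_seed = min_seed,
                              rrna_min_shared = rrna_min_shared)
  status_counts <- attr(assign_tab, "status_counts")

  assigned <- assign_tab[assign_tab$status == "assigned", , drop = FALSE]
  spot <- match_barcodes(assigned$barcode, design,
                         max_mismatch = max_mismatch)
  matched <- !is.na(spot)
  annotated <- data.frame(read_id = assigned$read_id[matched],
                          spot = spot[matched],
                          gene_id = assigned$gene_id[matched],
                          umi = assigned$umi[matched],
                          stringsAsFactors = FALSE)
  counters <- c(list(total_reads = nrow(assign_tab)),
                as.list(status_counts),
                list(barcode_filtered = sum(!matched)))
  counts <- dedup_umis(annotated, design,
                       gene_ids = annotation$gene_id[annotation$polyA],
                       counters = counters)
  counts$assignments <- assign_tab
  counts
}

#' Default processing configuration
#'
#' The tunable parameters of the pipeline with their defaults: read layout
#' (36-base forward read = 18-base barcode + 9-base UMI + oligo-dT,
#' 121-base reverse read), UMI pattern, trimming threshold (Phred 20) and
#' minimum retained length (25 nt), mapper seed size (k = 15) and seed
#' count (2), ribosomal-screen threshold (2 shared 15-mers), and barcode
#' mismatch tolerance (0 = exact membership).
#'
#' @return Named list of parameters.
#' @seealso [read_config()]
#' @export
default_config <- function() {
  list(forward_length = 36L, reverse_length = 121L, barcode_length = 18L,
       umi_length = 9L, umi_pattern = "WSNNWSNNV", q_threshold = 20L,
       min_length = 25L, k = 15L, min_seed = 2L, rrna_min_shared = 2L,
       max_mismatch = 0L, seed = 1L)
}

#' Read a YAML configuration file
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_config()].
#'
#' @param path Path to a YAML file of parameter overrides.
#' @return Named list of parameters (defaults merged with the file).
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  if (length(user) == 0L) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}
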
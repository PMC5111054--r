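#' Match spot barcodes against an array design
#'
#' An exact hit wins; otherwise the unique design barcode within Hamming
#' distance `max_mismatch` is taken, and two or more candidates tied at the
#' minimum distance discard the read. Queries whose length differs from the
#' design barcode length are discarded.
#'
#' @param barcode Character vector of observed barcode sequences.
#' @param design An `array_design`.
#' @param max_mismatch Maximum Hamming distance (default 0 = exact
#'   membership).
#' @return Integer vector of row indices into `design` (`NA` where
#'   discarded), with attribute `status` (factor with levels `matched`,
#'   `unmatched`, `ambiguous`, `length_mismatch`).
#' @export
match_barcodes <- function(barcode, design, max_mismatch = 0L) {
  stopifnot(inherits(design, "array_design"))
  code <- cpp_match_barcode(barcode, design$barcode,
                            as.integer(max_mismatch))
  idx <- ifelse(code > 0L, code, NA_integer_)
  status <- factor(ifelse(code > 0L, "matched",
                   ifelse(code == 0L, "unmatched",
                   ifelse(code == -1L, "ambiguous", "length_mismatch"))),
                   levels = c("matched", "unmatched", "ambiguous",
                              "length_mismatch"))
  attr(idx, "status") <- status
  idx
}

#' @rdname match_barcodes
#' @details `match_barcode()` is the single-query form; it returns the
#'   matched spot as a list with `x` and `y`, or `NULL` when the barcode is
#'   discarded.
#' @export
match_barcode <- function(barcode, design, max_mismatch = 0L) {
  idx <- match_barcodes(barcode[1L], design, max_mismatch)
  if (is.na(idx)) return(NULL)
  list(x = design$x[idx], y = design$y[idx])
}

#' Collapse PCR duplicates into unique molecule counts
#'
#' Counts, for every (spot, gene), the number of distinct UMI strings
#' observed (exact-string collapse), producing the spot-by-gene
#' unique-molecule matrix — the pipeline's product. The operation is
#' idempotent and invariant to read order.
#'
#' @param annotated Data frame of annotated reads with columns `spot`
#'   (row index into `design`), `gene_id` and `umi`.
#' @param design The `array_design` (fixes the row universe).
#' @param gene_ids Gene universe for the columns (default: genes observed).
#' @param counters Optional named list of provenance counters carried along.
#' @return An object of class `spot_counts`: list with the integer `matrix`
#'   (spots by genes, row names `"x_y"`), the `design`, `counters`
#'   (including `annotated_reads` and `unique_molecules`), and the untouched
#'   `annotated` read multiset (needed by [saturation_curve()]).
#' @export
dedup_umis <- function(annotated, design, gene_ids = NULL, counters = list()) {
  stopifnot(inherits(design, "array_design"),
            all(c("spot", "gene_id", "umi") %in% names(annotated)))
  if (is.null(gene_ids)) gene_ids <- sort(unique(annotated$gene_id))
  labels <- spot_labels(design)
  key <- paste(annotated$spot, annotated$gene_id, annotated$umi)
  uniq <- annotated[!duplicated(key), , drop = FALSE]
  tab <- table(factor(labels[uniq$spot], levels = labels),
               factor(uniq$gene_id, levels = gene_ids))
  mat <- matrix(as.integer(tab), nrow = length(labels),
                dimnames = list(labels, gene_ids))
  counters$annotated_reads <- nrow(annotated)
  counters$unique_molecules <- nrow(uniq)
  structure(list(matrix = mat, design = design, counters = counters,
                 annotated = annotated),
            class = "spot_counts")
}

#' @export
print.spot_counts <- function(x, ...) {
  cat(sprintf("spot_counts: %d spots x %d genes, %d unique molecules\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  if (length(x$counters) > 0L) {
    cat("  counters: ",
        paste(names(x$counters), unlist(x$counters), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.spot_counts <- function(x) dim(x$matrix)

#' Write a spot-by-gene count matrix
#'
#' `tsv` writes a tab-separated matrix with `"x_y"` spot labels as the
#' first column (`spot`) and gene identifiers as the header. `mtx` writes a
#' MatrixMarket triplet file plus `<path>.rows` / `<path>.cols` label
#' sidecars. [read_counts()] inverts both.
#'
#' @param counts A `spot_counts` (or a plain matrix with dimnames).
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  mat <- if (inherits(counts, "spot_counts")) counts$matrix else counts
  res <- try({
    if (format == "tsv") {
      tab <- data.frame(spot = rownames(mat), mat, check.names = FALSE,
                        stringsAsFactors = FALSE)
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
      writeLines(rownames(mat), paste0(path, ".rows"))
      writeLines(colnames(mat), paste0(path, ".cols"))
    }
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("failed to write counts to ", path, ": ",
         attr(res, "condition")$message)
  invisible(path)
}

#' Read a spot-by-gene count matrix
#'
#' @param path Path written by [write_counts()].
#' @param format `"tsv"` or `"mtx"`.
#' @param design Optional `array_design` to attach (enables downstream
#'   region lookups).
#' @return A `spot_counts` when `design` is given, otherwise the bare
#'   matrix.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), design = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(mat) <- "integer"
    rownames(mat) <- tab$spot
  } else {
    mat <- as.matrix(Matrix::readMM(path))
    storage.mode(mat) <- "integer"
    rownames(mat) <- readLines(paste0(path, ".rows"))
    colnames(mat) <- readLines(paste0(path, ".cols"))
  }
  if (is.null(design)) return(mat)
  structure(list(matrix = mat, design = design, counters = list()),
            class = "spot_counts")
}
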
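#' Construct a barcoded array design
#'
#' An array design is the demultiplexing universe of a spatially barcoded
#' experiment: a table of spot barcodes with their (x, y) grid coordinates,
#' plus the UMI geometry shared by all probes on the array.
#'
#' @param barcode Character vector of spot barcodes (A/C/G/T, one fixed
#'   length).
#' @param x,y Integer spot coordinates (0-based grid indices); the (x, y)
#'   pairs must be unique.
#' @param umi_length UMI length in bases.
#' @param umi_pattern IUPAC string of length `umi_length` describing the
#'   semi-randomized UMI (e.g. `"WSNNWSNNV"`).
#'
#' @return An object of class `array_design`: a data frame with columns
#'   `barcode`, `x`, `y` and attributes `barcode_length`, `umi_length`,
#'   `umi_pattern`.
#' @seealso [load_array_design()], [make_array_design()]
#' @export
array_design <- function(barcode, x, y, umi_length = 9L,
                         umi_pattern = "WSNNWSNNV") {
  barcode <- as.character(barcode)
  x <- as.integer(x)
  y <- as.integer(y)
  if (length(barcode) == 0L) stop("array design has no spots")
  if (length(x) != length(barcode) || length(y) != length(barcode))
    stop("barcode, x and y must have equal length")
  lens <- nchar(barcode)
  if (length(unique(lens)) != 1L)
    stop("ragged barcode lengths: ", paste(sort(unique(lens)), collapse = ", "))
  if (any(grepl("[^ACGT]", barcode)))
    stop("non-ACGT characters in barcode(s): ",
         paste(head(barcode[grepl("[^ACGT]", barcode)], 3L), collapse = ", "))
  dup <- barcode[duplicated(barcode)]
  if (length(dup) > 0L)
    stop("duplicate barcode(s): ", paste(unique(dup), collapse = ", "))
  xy <- paste(x, y, sep = "_")
  if (anyDuplicated(xy))
    stop("duplicate (x, y) coordinates: ",
         paste(unique(xy[duplicated(xy)]), collapse = ", "))
  umi_pattern <- validate_umi_pattern(umi_pattern, umi_length)
  design <- data.frame(barcode = barcode, x = x, y = y,
                       stringsAsFactors = FALSE)
  attr(design, "barcode_length") <- lens[1L]
  attr(design, "umi_length") <- as.integer(umi_length)
  attr(design, "umi_pattern") <- umi_pattern
  class(design) <- c("array_design", "data.frame")
  design
}

validate_umi_pattern <- function(umi_pattern, umi_length) {
  umi_pattern <- toupper(as.character(umi_pattern))
  if (nchar(umi_pattern) != umi_length)
    stop("umi_pattern length (", nchar(umi_pattern),
         ") does not match umi_length (", umi_length, ")")
  codes <- strsplit(umi_pattern, "")[[1L]]
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  if (!all(codes %in% valid))
    stop("umi_pattern contains non-IUPAC code(s): ",
         paste(unique(codes[!codes %in% valid]), collapse = ", "))
  umi_pattern
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf("array_design: %d spots, barcode length %d, UMI %s (%d nt)\n",
              nrow(x), attr(x, "barcode_length"),
              attr(x, "umi_pattern"), attr(x, "umi_length")))
  cat(sprintf("  grid: x in [%d, %d], y in [%d, %d]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Read an array design from a TSV file
#'
#' The file must be tab-separated with a header line and columns `barcode`,
#' `x`, `y`. The barcode length is inferred from the data; validation rules
#' are those of [array_design()].
#'
#' @param path Path to the design TSV.
#' @inheritParams array_design
#' @return An `array_design` object.
#' @export
load_array_design <- function(path, umi_length = 9L,
                              umi_pattern = "WSNNWSNNV") {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "integer"),
                    stringsAsFactors = FALSE)
  need <- c("barcode", "x", "y")
  if (!all(need %in% names(tab)))
    stop("array design file ", path, " must have columns barcode, x, y")
  array_design(tab$barcode, tab$x, tab$y, umi_length = umi_length,
               umi_pattern = umi_pattern)
}

#' Write an array design to a TSV file
#'
#' Inverse of [load_array_design()]; writes the header `barcode\\tx\\ty`.
#'
#' @param design An `array_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_array_design <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  write.table(as.data.frame(design)[, c("barcode", "x", "y")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Describe the paired-read layout
#'
#' Records where the spot barcode and the UMI sit on the forward read. All
#' intervals are 0-based, half-open. The defaults describe a 36-base forward
#' read carrying an 18-base barcode followed by a 9-base UMI, and a 121-base
#' reverse (transcript) read.
#'
#' @param forward_length,reverse_length Read lengths in bases.
#' @param barcode_length,umi_length Widths of the barcode and UMI segments.
#' @param barcode_start 0-based start of the barcode on the forward read;
#'   the UMI follows immediately after the barcode.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(forward_length = 36L, reverse_length = 121L,
                        barcode_length = 18L, umi_length = 9L,
                        barcode_start = 0L) {
  barcode_span <- c(barcode_start, barcode_start + barcode_length)
  umi_span <- c(barcode_span[2L], barcode_span[2L] + umi_length)
  if (barcode_span[1L] < 0L || umi_span[2L] > forward_length)
    stop("barcode + UMI spans do not fit in a ", forward_length,
         "-base forward read")
  structure(list(forward_length = as.integer(forward_length),
                 reverse_length = as.integer(reverse_length),
                 barcode_span = as.integer(barcode_span),
                 umi_span = as.integer(umi_span)),
            class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf(paste0("read_layout: forward %d nt (barcode [%d,%d), ",
                     "UMI [%d,%d)), reverse %d nt\n"),
              x$forward_length, x$barcode_span[1L], x$barcode_span[2L],
              x$umi_span[1L], x$umi_span[2L], x$reverse_length))
  invisible(x)
}

#' Extract barcode and UMI from forward reads
#'
#' Slices the barcode and UMI segments out of forward-read sequences
#' according to a [read_layout()]. Reads too short to cover both spans are
#' flagged as discarded rather than raising an error. Forward-read bases
#' after the UMI (the oligo-dT stretch) are ignored.
#'
#' @param seq Character vector of forward-read sequences.
#' @param layout A `read_layout`.
#' @return A data frame with columns `barcode`, `umi` (NA where discarded)
#'   and logical `ok`.
#' @export
parse_forward <- function(seq, layout) {
  stopifnot(inherits(layout, "read_layout"))
  need <- max(layout$barcode_span[2L], layout$umi_span[2L])
  ok <- nchar(seq) >= need
  bc <- ifelse(ok, substr(seq, layout$barcode_span[1L] + 1L,
                          layout$barcode_span[2L]), NA_character_)
  umi <- ifelse(ok, substr(seq, layout$umi_span[1L] + 1L,
                           layout$umi_span[2L]), NA_character_)
  data.frame(barcode = bc, umi = umi, ok = ok, stringsAsFactors = FALSE)
}
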
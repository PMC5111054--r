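# Brute-force oracles, independent of the package internals, used to verify
# the optimized implementations on small random cases.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# Exhaustive cut-point maximizer for 3' quality trimming: retained length is
# the largest cut index c maximizing sum_{i >= c}(q_threshold - q_i), or the
# full length when no cut has a positive sum.
oracle_trim_len <- function(qual, q_threshold) {
  q <- utf8ToInt(qual) - 33L
  n <- length(q)
  suffix <- rev(cumsum(rev(q_threshold - q)))
  best <- max(suffix)
  if (best <= 0) return(n)
  max(which(suffix == best)) - 1L
}

# Exhaustive minimum-Hamming barcode scan with the ambiguity discard rule.
oracle_match_idx <- function(query, barcodes, max_mismatch) {
  if (nchar(query) != nchar(barcodes[1L])) return(NA_integer_)
  qi <- utf8ToInt(query)
  d <- vapply(barcodes, function(b) sum(qi != utf8ToInt(b)), integer(1L),
              USE.NAMES = FALSE)
  m <- min(d)
  if (m > max_mismatch) return(NA_integer_)
  hits <- which(d == m)
  if (length(hits) > 1L) NA_integer_ else hits
}

# Distinct k-mer set of a sequence.
oracle_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0L))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# Max distinct k-mers shared with any single reference, either strand.
oracle_shared_kmers <- function(read, refs, k) {
  fw <- oracle_kmers(read, k)
  rc <- oracle_kmers(oracle_revcomp(read), k)
  max(vapply(refs, function(r) {
    rk <- oracle_kmers(r, k)
    max(length(intersect(fw, rk)), length(intersect(rc, rk)))
  }, integer(1L)))
}

# Best ungapped match count of read against ref over all diagonals.
oracle_diag_score <- function(read, ref) {
  ri <- utf8ToInt(read)
  fi <- utf8ToInt(ref)
  n <- length(ri)
  m <- length(fi)
  best <- 0L
  for (diag in seq(-(n - 1L), m - 1L)) {
    i <- seq_len(n)
    j <- i + diag
    keep <- j >= 1L & j <= m
    sc <- sum(ri[keep] == fi[j[keep]])
    if (sc > best) best <- sc
  }
  best
}

# Top-scoring gene by exhaustive ungapped alignment against every
# transcript (both strands); NA on a tie.
oracle_top_gene <- function(read, seqs) {
  rc <- oracle_revcomp(read)
  sc <- vapply(seqs, function(ref)
    max(oracle_diag_score(read, ref), oracle_diag_score(rc, ref)),
    integer(1L))
  top <- which(sc == max(sc))
  if (length(top) > 1L) NA_character_ else names(seqs)[top]
}

# Median-of-ratios size factors straight from the definition.
oracle_size_factors <- function(mat) {
  ok <- apply(mat, 1L, function(g) all(g > 0))
  geo <- apply(mat[ok, , drop = FALSE], 1L, function(g)
    prod(g)^(1 / length(g)))
  apply(mat[ok, , drop = FALSE], 2L, function(v) median(v / geo))
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

random_quals <- function(n, len_range = c(30L, 121L), q_range = c(2L, 40L)) {
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    intToUtf8(33L + sample(q_range[1L]:q_range[2L], len, replace = TRUE))
  }, character(1L))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

read_fastq_ids <- function(path) {
  lines <- readLines(path)
  lines[seq(1L, length(lines), by = 4L)]
}

read_fastq_seqs <- function(path) {
  lines <- readLines(path)
  lines[seq(2L, length(lines), by = 4L)]
}

mutate_seq <- function(s, n_sub) {
  ch <- strsplit(s, "")[[1L]]
  pos <- sample.int(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}
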
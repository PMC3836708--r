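#' Genomic interval constructor
#'
#' Intervals are 1-based and fully inclusive throughout the package, so an
#' interval covering positions 97 to 384 has length 288. BED export converts
#' to that format's 0-based half-open convention at the file boundary only.
#'
#' @param seq_id Sequence (chromosome/scaffold) name.
#' @param start,end Integer coordinates, `1 <= start <= end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return A one-row `data.frame` with columns `seq_id`, `start`, `end`,
#'   `strand`.
#' @examples
#' genomic_interval("chr1", 97, 384)
#' @export
genomic_interval <- function(seq_id, start, end, strand = "*") {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(is.character(seq_id), length(seq_id) == length(start),
            length(start) == length(end))
  if (any(start < 1L)) stop("interval start must be >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  if (!all(strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  data.frame(seq_id = seq_id, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Length of a 1-based inclusive interval
#'
#' @param iv Interval as returned by [genomic_interval()], or anything with
#'   `start` and `end` columns.
#' @return Integer vector of lengths, `end - start + 1`.
#' @examples
#' interval_length(genomic_interval("s", 97, 384))  # 288
#' interval_length(genomic_interval("s", 71, 94))   # 24
#' @export
interval_length <- function(iv) {
  as.integer(iv$end - iv$start + 1L)
}

#' Shared positions between two intervals
#'
#' Inclusive-coordinate overlap: intervals touching at a single base share
#' one position; adjacent intervals share none. Intervals on different
#' sequences never overlap.
#'
#' @param a,b One-row intervals (see [genomic_interval()]).
#' @return Integer count of shared positions.
#' @export
overlap_bp <- function(a, b) {
  if (a$seq_id[1] != b$seq_id[1]) return(0L)
  lo <- max(a$start[1], b$start[1])
  hi <- min(a$end[1], b$end[1])
  max(0L, as.integer(hi - lo + 1L))
}

#' Count masked positions inside an interval
#'
#' Lowercase residues denote repeat-masked sequence. `N` positions count as
#' masked by default because they are unalignable assembly gaps; set
#' `assume_n_masked = FALSE` to count lowercase letters only.
#'
#' @param genome Named character vector of sequences (see
#'   [read_genome_fasta()]).
#' @param iv One-row interval on a sequence present in `genome`.
#' @param assume_n_masked Count `N`/`n` positions as masked (default TRUE).
#' @return Integer count of masked positions in the interval.
#' @export
masked_bp <- function(genome, iv, assume_n_masked = TRUE) {
  seq_id <- iv$seq_id[1]
  if (!seq_id %in% names(genome)) {
    stop("sequence '", seq_id, "' not present in genome")
  }
  s <- genome[[seq_id]]
  if (iv$start[1] < 1L || iv$end[1] > nchar(s)) {
    stop("interval out of bounds for sequence '", seq_id, "'")
  }
  chars <- strsplit(substr(s, iv$start[1], iv$end[1]), "", fixed = TRUE)[[1]]
  masked <- chars %in% c("a", "c", "g", "t", "n")
  if (assume_n_masked) masked <- masked | chars == "N"
  sum(masked)
}

# Interval data.frame <-> GRanges; keeps '*' for unstranded rows.
intervals_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$seq_id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand
  )
}

granges_to_intervals <- function(gr) {
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
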
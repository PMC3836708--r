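#' Read a genome FASTA, preserving masking case
#'
#' Repeat-masked genomes mark repeats with lowercase letters; the reader
#' keeps the case intact so downstream repeat filtering can count masked
#' positions. Sequences are returned as a plain named character vector.
#'
#' @param path FASTA file.
#' @return Named character vector, one element per record, in file order.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad)) {
    stop("sequence(s) with characters outside {A,C,G,T,N}: ",
         paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write a genome FASTA (case preserved)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file.
#' @return Interval `data.frame` with `seq_id`, `start`, `end`, `strand`
#'   and, when present, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_intervals(gr)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write intervals to a BED file
#'
#' Converts from 1-based inclusive to BED's 0-based half-open convention:
#' an internal interval `(1, 100)` becomes the BED span `0 100`.
#'
#' @param df Interval `data.frame` (`seq_id`, `start`, `end`, optional
#'   `strand` and `name`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  gr <- intervals_to_granges(df)
  if ("name" %in% names(df)) gr$name <- df$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' The transcription start site (TSS) of a gene is its start coordinate on
#' the plus strand and its end coordinate on the minus strand.
#'
#' @param path GFF3 file with `gene` (and optionally `exon`) features.
#' @return List with `genes` (columns `gene_id`, `seq_id`, `strand`, `tss`,
#'   `start`, `end`) and `exons` (interval data.frame with `gene_id`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gr$type)
  gdf <- granges_to_intervals(gr)
  ids <- as.character(gr$ID)
  if (is.null(gr$ID)) ids <- rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  gi <- type == "gene"
  genes <- data.frame(
    gene_id = ids[gi],
    seq_id = gdf$seq_id[gi],
    strand = gdf$strand[gi],
    start = gdf$start[gi],
    end = gdf$end[gi],
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)

  ei <- type == "exon"
  exons <- data.frame(
    seq_id = gdf$seq_id[ei],
    start = gdf$start[ei],
    end = gdf$end[ei],
    strand = gdf$strand[ei],
    gene_id = parent[ei],
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons)
}

#' Write gene models to GFF3
#'
#' @param genes Gene table (`gene_id`, `seq_id`, `strand`, `start`, `end`).
#' @param exons Exon interval table with a `gene_id` column (may be empty).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, exons, path) {
  ggr <- intervals_to_granges(genes)
  ggr$type <- "gene"
  ggr$ID <- genes$gene_id
  ggr$source <- "cneforge"
  if (nrow(exons) > 0L) {
    egr <- intervals_to_granges(exons)
    egr$type <- "exon"
    egr$ID <- paste0(exons$gene_id, ".exon", seq_len(nrow(exons)))
    egr$Parent <- as.character(exons$gene_id)
    egr$source <- "cneforge"
    ggr$Parent <- NA_character_
    all <- c(ggr, egr)
  } else {
    all <- ggr
  }
  rtracklayer::export(all, path, format = "GFF3")
  invisible(path)
}

#' Write a table as TSV
#'
#' @param df A data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_file()]
#'
#' @param path TSV file with a header row.
#' @return A data.frame.
#' @export
read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
}

# Reverse complement that preserves case and N.
revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# Apply lowercase masking to genome positions covered by repeat intervals.
mask_genome <- function(genome, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0L) return(genome)
  for (i in seq_len(nrow(repeats))) {
    sid <- repeats$seq_id[i]
    if (!sid %in% names(genome)) next
    s <- genome[[sid]]
    sub <- substr(s, repeats$start[i], repeats$end[i])
    substr(s, repeats$start[i], repeats$end[i]) <- tolower(sub)
    genome[[sid]] <- s
  }
  genome
}
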
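#' Scan a sequence for a degenerate motif
#'
#' Matches an IUPAC-coded pattern (with `n` meaning any base) against a
#' sequence, case-insensitively. The canonical Pbx/Hox site `tgatnnat` is
#' the motivating example. By default only the given orientation is
#' scanned; with `both_strands = TRUE` reverse-complement matches are also
#' reported with strand `-` (coordinates on the forward sequence).
#'
#' @param seq Sequence string.
#' @param pattern IUPAC pattern string.
#' @param both_strands Also scan the reverse complement.
#' @return Data frame with `start`, `end`, `strand`, `match` (forward
#'   sequence of the matched span). Zero rows when the pattern is longer
#'   than the sequence or nothing matches.
#' @export
scan_motif <- function(seq, pattern, both_strands = FALSE) {
  iupac <- c(names(Biostrings::IUPAC_CODE_MAP))
  pat_chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (!all(pat_chars %in% iupac)) {
    stop("pattern contains non-IUPAC characters: ",
         paste(unique(pat_chars[!pat_chars %in% iupac]), collapse = ""))
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), match = character(0),
                      stringsAsFactors = FALSE)
  L <- nchar(seq)
  w <- nchar(pattern)
  if (w > L || w < 1L) return(empty)
  subj <- Biostrings::DNAString(toupper(gsub("[^ACGTNacgtn]", "N", seq)))
  pat <- Biostrings::DNAString(toupper(pattern))
  fwd <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
  out <- data.frame(start = Biostrings::start(fwd),
                    end = Biostrings::end(fwd),
                    strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rev <- Biostrings::matchPattern(pat,
                                    Biostrings::reverseComplement(subj),
                                    fixed = FALSE)
    if (length(rev) > 0L) {
      rs <- L - Biostrings::end(rev) + 1L
      re <- L - Biostrings::start(rev) + 1L
      out <- rbind(out, data.frame(start = rs, end = re,
                                   strand = rep("-", length(rev)),
                                   stringsAsFactors = FALSE))
    }
  }
  if (nrow(out) == 0L) return(empty)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out$match <- substr(rep(seq, nrow(out)), out$start, out$end)
  rownames(out) <- NULL
  out
}

new_construct <- function(parent_id, kind, start, end, sequence,
                          note = "") {
  data.frame(parent_id = parent_id, kind = kind,
             start = as.integer(start), end = as.integer(end),
             length = nchar(sequence), sequence = sequence, note = note,
             stringsAsFactors = FALSE)
}

#' Sub-element construct
#'
#' Extracts the inclusive span `start..end` of a parent element, the basic
#' operation of enhancer delineation (e.g. the 288 nt core spanning nt
#' 97-384 of a 457 nt element).
#'
#' @param parent_seq Parent element sequence.
#' @param start,end 1-based inclusive coordinates on the parent.
#' @param parent_id Identifier recorded with the construct.
#' @return One-row construct data frame (`parent_id`, `kind`, `start`,
#'   `end`, `length`, `sequence`, `note`).
#' @export
make_subelement <- function(parent_seq, start, end, parent_id = "parent") {
  L <- nchar(parent_seq)
  if (start < 1L || end > L || start > end) {
    stop("sub-element span out of range")
  }
  new_construct(parent_id, "subelement", start, end,
                substr(parent_seq, start, end))
}

#' Deletion construct
#'
#' Excises the inclusive span `del_start..del_end` from the parent; the
#' construct length is the parent length minus the deleted span. Deleting
#' the whole parent yields an empty sequence flagged degenerate.
#'
#' @param parent_seq Parent element sequence.
#' @param del_start,del_end 1-based inclusive span to remove.
#' @param parent_id Identifier recorded with the construct.
#' @return One-row construct data frame.
#' @export
make_deletion <- function(parent_seq, del_start, del_end,
                          parent_id = "parent") {
  L <- nchar(parent_seq)
  if (del_start < 1L || del_end > L || del_start > del_end) {
    stop("deletion span out of range")
  }
  seq <- paste0(substr(parent_seq, 1L, del_start - 1L),
                substr(parent_seq, del_end + 1L, L))
  note <- if (nchar(seq) == 0L) "degenerate: full-length deletion" else ""
  new_construct(parent_id, "deletion", del_start, del_end, seq, note)
}

#' Annealed-oligo construct
#'
#' Sequence-wise identical to [make_subelement()] but tagged as built from
#' annealed complementary oligonucleotides, the construction used for the
#' shortest functional fragments (e.g. the 24 nt minimal element spanning
#' nt 71-94).
#'
#' @inheritParams make_subelement
#' @return One-row construct data frame with kind `oligo`.
#' @export
make_oligo_construct <- function(parent_seq, start, end,
                                 parent_id = "parent") {
  out <- make_subelement(parent_seq, start, end, parent_id)
  out$kind <- "oligo"
  out$note <- "annealed complementary oligonucleotides"
  out
}

#' Trinucleotide mutagenesis series
#'
#' One variant per consecutive non-overlapping triplet; in each variant the
#' triplet is replaced by its per-base complement (A<->T, C<->G, not
#' reversed), a deterministic maximally disruptive substitution. A trailing
#' partial window is skipped with a warning.
#'
#' @param seq Parent sequence.
#' @param parent_id Identifier recorded with the constructs.
#' @return Construct data frame, one row per triplet variant; `start`/`end`
#'   give the mutated window.
#' @export
triplet_mutant_series <- function(seq, parent_id = "parent") {
  L <- nchar(seq)
  n_tri <- L %/% 3L
  if (L %% 3L != 0L) {
    warning("sequence length not divisible by 3; final partial window skipped")
  }
  rows <- lapply(seq_len(n_tri), function(i) {
    s <- 3L * (i - 1L) + 1L
    e <- s + 2L
    tri <- substr(seq, s, e)
    mut <- chartr("ACGTacgt", "TGCAtgca", tri)
    variant <- paste0(substr(seq, 1L, s - 1L), mut, substr(seq, e + 1L, L))
    new_construct(parent_id, "triplet_mutant", s, e, variant,
                  note = sprintf("triplet %d: %s->%s", i, tri, mut))
  })
  if (length(rows) == 0L) {
    return(new_construct(parent_id, "triplet_mutant", integer(0),
                         integer(0), character(0))[0, ])
  }
  do.call(rbind, rows)
}
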
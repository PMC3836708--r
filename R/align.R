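#' Alignment search configuration
#'
#' Defaults follow the classical BLAST-style whole-genome comparison
#' parameters for diverged genome pairs: exact word seeds of 20 bp, match
#' reward +1, mismatch penalty -2, an E-value ceiling of 0.001, query
#' fragmentation into 500 kb pieces overlapping by 200 bp, and retention of
#' alignments at least 100 bp long. Gap costs are linear (no affine
#' opening) at -3 per gapped base; X-drop extension stops once the running
#' score falls more than `x_drop` below its running maximum. The default
#' X-drop of 50 raw score units matches the BLAST family's final gapped
#' extension threshold (about 100 bits at this scoring); tighter values
#' truncate alignments through genuinely low-identity (~71%) elements.
#'
#' @param word_len Exact seed word length (bp).
#' @param match Match reward (positive integer).
#' @param mismatch Mismatch penalty (negative integer).
#' @param gap Linear gap penalty per base (negative integer).
#' @param x_drop X-drop termination threshold (score units).
#' @param evalue_max Maximum E-value for a reported hit.
#' @param fragment_len Query fragmentation length (bp).
#' @param fragment_overlap Overlap between successive fragments (bp).
#' @param min_hit_len Minimum aligned length (columns) of a retained hit.
#' @param ka_k Karlin-Altschul K; the published ungapped constant for
#'   +1/-2 scoring with uniform base composition.
#' @param base_freqs Background base frequencies (A, C, G, T).
#' @return An object of class `align_config`.
#' @export
align_config <- function(word_len = 20L, match = 1L, mismatch = -2L,
                         gap = -3L, x_drop = 50L, evalue_max = 1e-3,
                         fragment_len = 500000L, fragment_overlap = 200L,
                         min_hit_len = 100L, ka_k = 0.621,
                         base_freqs = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  stopifnot(word_len >= 4L, match > 0L, mismatch < 0L, gap < 0L,
            x_drop > 0L, evalue_max > 0, fragment_overlap < fragment_len,
            min_hit_len >= 1L, ka_k > 0,
            length(base_freqs) == 4L, abs(sum(base_freqs) - 1) < 1e-8)
  structure(list(word_len = as.integer(word_len), match = as.integer(match),
                 mismatch = as.integer(mismatch), gap = as.integer(gap),
                 x_drop = as.integer(x_drop), evalue_max = evalue_max,
                 fragment_len = as.integer(fragment_len),
                 fragment_overlap = as.integer(fragment_overlap),
                 min_hit_len = as.integer(min_hit_len), ka_k = ka_k,
                 base_freqs = base_freqs),
            class = "align_config")
}

#' Calibrate Karlin-Altschul parameters
#'
#' Solves for the decay rate lambda of the local-alignment score
#' distribution: lambda is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) - 1 = 0`, which exists whenever the
#' expected per-letter score is negative. The E-value of a score S between
#' sequences of lengths m and n is then `K * m * n * exp(-lambda * S)`.
#'
#' @param match,mismatch Match/mismatch scores.
#' @param base_freqs Background base frequencies (length 4, sums to 1).
#' @param k K parameter; the series computation is involved, so the
#'   published ungapped constant for the configured scoring is accepted
#'   here and validated by the calibration residual.
#' @return List with `lambda`, `k`, `residual` (value of the calibration
#'   identity at the root) and `expected_score`.
#' @export
calibrate_ka <- function(match = 1L, mismatch = -2L,
                         base_freqs = c(0.25, 0.25, 0.25, 0.25),
                         k = 0.621) {
  p <- base_freqs / sum(base_freqs)
  # pair probabilities: identical pair -> match, otherwise mismatch
  p_match <- sum(p^2)
  p_mis <- 1 - p_match
  es <- p_match * match + p_mis * mismatch
  if (es >= 0) stop("expected per-letter score must be negative")
  f <- function(lambda) {
    p_match * exp(lambda * match) + p_mis * exp(lambda * mismatch) - 1
  }
  # the root is bracketed between 0+ and a score-scale upper bound
  upper <- 10 / max(abs(match), 1)
  while (f(upper) < 0) upper <- upper * 2
  root <- stats::uniroot(f, c(1e-12, upper), tol = 1e-14)
  lambda <- root$root
  list(lambda = lambda, k = k, residual = abs(f(lambda)),
       expected_score = es)
}

#' E-value of an alignment score
#'
#' @param score Alignment score(s).
#' @param m,n Lengths of the two compared sequences (raw lengths; no edge
#'   correction).
#' @param ka Calibration from [calibrate_ka()].
#' @return Expected number of chance alignments scoring `>= score`.
#' @export
ka_evalue <- function(score, m, n, ka) {
  ka$k * as.numeric(m) * as.numeric(n) * exp(-ka$lambda * score)
}

#' Split a sequence into overlapping fragments
#'
#' The first fragment starts at position 1; successive starts advance by
#' `fragment_len - fragment_overlap`; the last fragment is truncated at the
#' sequence end. Every position is covered.
#'
#' @param seq_len Sequence length (bp) or a sequence string.
#' @param cfg [align_config()].
#' @return data.frame with `start`, `end` (1-based inclusive).
#' @export
fragment_genome <- function(seq_len, cfg = align_config()) {
  if (is.character(seq_len)) seq_len <- nchar(seq_len)
  seq_len <- as.integer(seq_len)
  step <- cfg$fragment_len - cfg$fragment_overlap
  starts <- seq.int(1L, max(1L, seq_len), by = step)
  # drop trailing fragments fully covered by their predecessor
  starts <- starts[starts <= seq_len]
  ends <- pmin(starts + cfg$fragment_len - 1L, seq_len)
  keep <- c(TRUE, ends[-1] > ends[-length(ends)])
  data.frame(start = starts[keep], end = ends[keep])
}

#' Find exact word seeds between two sequences
#'
#' All maximal exact matches of length at least `word_len` between the two
#' sequences. Masked positions (lowercase or non-ACGT) never participate in
#' a seed, matching soft-masked search semantics.
#'
#' @param a,b Sequence strings.
#' @param word_len Minimum exact-match length.
#' @return data.frame with 1-based `a_start`, `b_start`, `length`.
#' @export
find_seeds <- function(a, b, word_len = 20L) {
  cpp_find_seeds(a, b, as.integer(word_len))
}

#' Greedily extend a seed into a gapped local alignment
#'
#' Extension proceeds independently in both directions from the exact seed
#' using a banded dynamic program with linear gap costs, terminating when
#' the running score drops more than `cfg$x_drop` below its running
#' maximum; the returned alignment is trimmed to the maximal-score
#' prefix/suffix.
#'
#' @param seed One row from [find_seeds()] (fields `a_start`, `b_start`,
#'   `length`).
#' @param a,b Sequence strings.
#' @param cfg [align_config()].
#' @return One-row data.frame hit (`a_start`, `a_end`, `b_start`, `b_end`,
#'   `score`, `aligned_cols`, `identities`, `pct_identity`, `ops`), or
#'   `NULL` when the seed is empty.
#' @export
extend_seed <- function(seed, a, b, cfg = align_config()) {
  if (is.null(seed) || nrow(seed) == 0L) return(NULL)
  h <- cpp_extend_seed(a, b, seed$a_start[1], seed$b_start[1],
                       seed$length[1], cfg$match, cfg$mismatch, cfg$gap,
                       cfg$x_drop)
  data.frame(a_start = h$a_start, a_end = h$a_end, b_start = h$b_start,
             b_end = h$b_end, score = h$score,
             aligned_cols = h$aligned_cols, identities = h$identities,
             pct_identity = 100 * h$identities / h$aligned_cols,
             ops = h$ops, stringsAsFactors = FALSE)
}

#' Align one sequence pair with seed-and-extend
#'
#' Finds all word seeds, extends each, and removes hits whose intervals on
#' both sequences are contained in a higher-scoring hit. No E-value or
#' length filtering is applied here; see [run_search()].
#'
#' @param a,b Sequence strings.
#' @param cfg [align_config()].
#' @return Hit data.frame (possibly 0 rows) with the columns of
#'   [extend_seed()].
#' @export
align_pair <- function(a, b, cfg = align_config()) {
  df <- cpp_align_pair(a, b, cfg$word_len, cfg$match, cfg$mismatch,
                       cfg$gap, cfg$x_drop)
  if (nrow(df) == 0L) {
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      score = integer(), aligned_cols = integer(),
                      identities = integer(), pct_identity = numeric(),
                      ops = character(), stringsAsFactors = FALSE))
  }
  df$pct_identity <- 100 * df$identities / df$aligned_cols
  # drop hits contained (both intervals) in a higher-scoring hit
  ord <- order(-df$score, df$a_start, df$b_start)
  df <- df[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(df$a_start[prior] <= df$a_start[i] &
            df$a_end[prior] >= df$a_end[i] &
            df$b_start[prior] <= df$b_start[i] &
            df$b_end[prior] >= df$b_end[i])) {
      keep[i] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Genome-vs-genome similarity search
#'
#' Fragments genome B into overlapping pieces, aligns every fragment (and
#' its reverse complement) against each plus-strand sequence of genome A,
#' converts coordinates back to genome space, attaches Karlin-Altschul
#' E-values, and applies the two retention rules: E-value at most
#' `cfg$evalue_max`, then aligned length at least `cfg$min_hit_len`.
#' Duplicate hits arising from the fragment overlap are removed by
#' identical genome coordinates.
#'
#' @param genome_a,genome_b Named character vectors of sequences.
#' @param cfg [align_config()].
#' @return Hit data.frame with columns `a_seq`, `a_start`, `a_end`,
#'   `b_seq`, `b_start`, `b_end`, `b_strand`, `score`, `aligned_cols`,
#'   `identities`, `pct_identity`, `evalue`.
#' @export
run_search <- function(genome_a, genome_b, cfg = align_config()) {
  ka <- calibrate_ka(cfg$match, cfg$mismatch, cfg$base_freqs, cfg$ka_k)
  n_total_a <- sum(nchar(genome_a))
  out <- list()
  for (b_id in names(genome_b)) {
    b_seq_full <- genome_b[[b_id]]
    frags <- fragment_genome(nchar(b_seq_full), cfg)
    for (fi in seq_len(nrow(frags))) {
      f_start <- frags$start[fi]
      f_end <- frags$end[fi]
      f_len <- f_end - f_start + 1L
      frag_fwd <- substr(b_seq_full, f_start, f_end)
      for (strand in c("+", "-")) {
        frag <- if (strand == "+") frag_fwd else revcomp(frag_fwd)
        for (a_id in names(genome_a)) {
          hits <- align_pair(genome_a[[a_id]], frag, cfg)
          if (nrow(hits) == 0L) next
          if (strand == "+") {
            b_start <- f_start + hits$b_start - 1L
            b_end <- f_start + hits$b_end - 1L
          } else {
            # positions on the reverse complement map back to the
            # forward strand of the fragment
            b_start <- f_start + (f_len - hits$b_end)
            b_end <- f_start + (f_len - hits$b_start)
          }
          hits$a_seq <- a_id
          hits$b_seq <- b_id
          hits$b_start <- b_start
          hits$b_end <- b_end
          hits$b_strand <- strand
          hits$evalue <- ka_evalue(hits$score, f_len, n_total_a, ka)
          out[[length(out) + 1L]] <- hits
        }
      }
    }
  }
  cols <- c("a_seq", "a_start", "a_end", "b_seq", "b_start", "b_end",
            "b_strand", "score", "aligned_cols", "identities",
            "pct_identity", "evalue")
  if (length(out) == 0L) {
    empty <- data.frame(a_seq = character(), a_start = integer(),
                        a_end = integer(), b_seq = character(),
                        b_start = integer(), b_end = integer(),
                        b_strand = character(), score = integer(),
                        aligned_cols = integer(), identities = integer(),
                        pct_identity = numeric(), evalue = numeric(),
                        stringsAsFactors = FALSE)
    return(empty)
  }
  hits <- do.call(rbind, out)[, c(cols, "ops")]
  hits <- hits[hits$evalue <= cfg$evalue_max, , drop = FALSE]
  hits <- hits[hits$aligned_cols >= cfg$min_hit_len, , drop = FALSE]
  # fragment-overlap duplicates: same A-genome coordinates and the same
  # B locus (overlapping B intervals; chance end-columns can differ by a
  # base or two between fragments). Distinct B loci are kept apart so the
  # multi-location filter still sees them.
  if (nrow(hits) > 1L) {
    key <- paste(hits$a_seq, hits$a_start, hits$a_end, hits$b_seq,
                 hits$b_strand)
    keep <- rep(TRUE, nrow(hits))
    for (grp in split(seq_len(nrow(hits)), key)) {
      if (length(grp) < 2L) next
      g <- hits[grp, , drop = FALSE]
      ord <- grp[order(-g$score, g$b_start)]
      for (i in seq_along(ord)[-1]) {
        prior <- ord[seq_len(i - 1L)]
        prior <- prior[keep[prior]]
        dup <- any(hits$b_start[prior] <= hits$b_end[ord[i]] &
                     hits$b_end[prior] >= hits$b_start[ord[i]])
        if (dup) keep[ord[i]] <- FALSE
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  # a fragment truncated mid-element yields a sub-alignment of the hit
  # found from the overlapping fragment: drop hits contained (both
  # genomes) in a higher-scoring hit on the same sequences and strand
  if (nrow(hits) > 1L) {
    ord <- order(-hits$score, hits$a_seq, hits$a_start, hits$b_start)
    hits <- hits[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))[-1]) {
      prior <- which(keep[seq_len(i - 1L)])
      contained <- hits$a_seq[prior] == hits$a_seq[i] &
        hits$b_seq[prior] == hits$b_seq[i] &
        hits$b_strand[prior] == hits$b_strand[i] &
        hits$a_start[prior] <= hits$a_start[i] &
        hits$a_end[prior] >= hits$a_end[i] &
        hits$b_start[prior] <= hits$b_start[i] &
        hits$b_end[prior] >= hits$b_end[i]
      if (any(contained)) keep[i] <- FALSE
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$a_seq, hits$a_start, hits$b_seq, hits$b_start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Recompute a hit's score from its operation string and the sequences it
# refers to; used by self-consistency checks.
rescore_hit <- function(hit, a_seq, b_seq, cfg = align_config()) {
  ops <- strsplit(hit$ops, "", fixed = TRUE)[[1]]
  ai <- hit$a_start
  bi <- hit$b_start
  a_chars <- strsplit(toupper(substr(a_seq, hit$a_start, hit$a_end)), "",
                      fixed = TRUE)[[1]]
  b_chars <- strsplit(toupper(substr(b_seq, hit$b_start, hit$b_end)), "",
                      fixed = TRUE)[[1]]
  pa <- 1L
  pb <- 1L
  score <- 0L
  for (op in ops) {
    if (op == "M") {
      ca <- a_chars[pa]
      cb <- b_chars[pb]
      same <- ca == cb && ca %in% c("A", "C", "G", "T")
      score <- score + if (same) cfg$match else cfg$mismatch
      pa <- pa + 1L
      pb <- pb + 1L
    } else if (op == "D") {
      score <- score + cfg$gap
      pa <- pa + 1L
    } else {
      score <- score + cfg$gap
      pb <- pb + 1L
    }
  }
  score
}
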
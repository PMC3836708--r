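#' Filter cascade configuration
#'
#' Thresholds for the annotation filter cascade: elements overlapping an
#' exon by at least `exon_overlap_min` bp are removed; elements containing
#' more than `max_repeat_bp` masked bases are removed (strictly more, so 10
#' masked bp is retained and 11 is rejected); any match to a structured-RNA
#' reference at E-value `ncrna_evalue` removes the element; more than
#' `max_est_matches` distinct expressed-transcript references remove it,
#' while 1 to `max_est_matches` matches label it as weakly transcribed.
#'
#' @param max_repeat_bp Maximum tolerated masked bases (strict).
#' @param max_est_matches Maximum tolerated distinct EST matches (strict).
#' @param ncrna_evalue,est_evalue E-value cut-offs for the two screens.
#' @param exon_overlap_min Minimum shared bases that count as exon overlap.
#' @param screen_word_len Seed word length for the RNA/EST screens.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_repeat_bp = 10L, max_est_matches = 3L,
                          ncrna_evalue = 1e-3, est_evalue = 1e-3,
                          exon_overlap_min = 1L, screen_word_len = 20L) {
  stopifnot(max_repeat_bp >= 0L, max_est_matches >= 0L,
            ncrna_evalue > 0, est_evalue > 0, exon_overlap_min >= 1L)
  structure(list(max_repeat_bp = as.integer(max_repeat_bp),
                 max_est_matches = as.integer(max_est_matches),
                 ncrna_evalue = ncrna_evalue, est_evalue = est_evalue,
                 exon_overlap_min = as.integer(exon_overlap_min),
                 screen_word_len = as.integer(screen_word_len)),
            class = "filter_config")
}

#' Merge alignment hits into candidate elements
#'
#' Hits whose genome-A intervals overlap and whose genome-B intervals also
#' overlap describe the same biological element (seed multiplicity and
#' query-fragment overlap otherwise double-count it); they are merged into
#' one element whose coordinates are the union. Hits sharing a genome-A
#' interval but matching distinct genome-B loci stay separate and are
#' handled by the multi-location filter.
#'
#' @param hits Hit table from [run_search()].
#' @return Element data.frame with `element_id`, `a_seq`, `a_start`,
#'   `a_end`, `length`, `b_seq`, `b_start`, `b_end`, `b_strand`,
#'   `pct_identity` (alignment-column weighted), `n_hits`.
#' @export
merge_hits_to_elements <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(element_id = character(0), a_seq = character(0),
                      a_start = integer(0), a_end = integer(0),
                      length = integer(0), b_seq = character(0),
                      b_start = integer(0), b_end = integer(0),
                      b_strand = character(0), pct_identity = numeric(0),
                      n_hits = integer(0), stringsAsFactors = FALSE))
  }
  n <- nrow(hits)
  # union-find over hits: same component iff A intervals overlap AND B
  # intervals overlap (same sequences)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  agr <- GenomicRanges::GRanges(hits$a_seq,
                                IRanges::IRanges(hits$a_start, hits$a_end))
  ovl <- GenomicRanges::findOverlaps(agr, agr)
  qi <- S4Vectors::queryHits(ovl)
  si <- S4Vectors::subjectHits(ovl)
  for (k in seq_along(qi)) {
    i <- qi[k]; j <- si[k]
    if (i >= j) next
    if (hits$b_seq[i] == hits$b_seq[j] &&
        hits$b_start[i] <= hits$b_end[j] &&
        hits$b_end[i] >= hits$b_start[j]) {
      union_(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(ix) {
    h <- hits[ix, , drop = FALSE]
    data.frame(a_seq = h$a_seq[1], a_start = min(h$a_start),
               a_end = max(h$a_end), b_seq = h$b_seq[1],
               b_start = min(h$b_start), b_end = max(h$b_end),
               b_strand = h$b_strand[which.max(h$aligned_cols)],
               pct_identity = sum(h$identities) / sum(h$aligned_cols) * 100,
               n_hits = nrow(h), stringsAsFactors = FALSE)
  })
  el <- do.call(rbind, rows)
  el <- el[order(el$a_seq, el$a_start, el$b_seq, el$b_start), , drop = FALSE]
  el$length <- el$a_end - el$a_start + 1L
  el$element_id <- sprintf("CNE%05d", seq_len(nrow(el)))
  rownames(el) <- NULL
  el[, c("element_id", "a_seq", "a_start", "a_end", "length", "b_seq",
         "b_start", "b_end", "b_strand", "pct_identity", "n_hits")]
}

#' Partition elements by exon overlap
#'
#' An element is removed when it shares at least `cfg$exon_overlap_min`
#' positions with any annotated exon.
#'
#' @param elements Element table.
#' @param exons Exon interval table (`seq_id`, `start`, `end`).
#' @param cfg [filter_config()].
#' @return Logical vector, TRUE where the element is removed.
#' @export
filter_exon_overlap <- function(elements, exons, cfg = filter_config()) {
  if (nrow(elements) == 0L) return(logical(0))
  if (is.null(exons) || nrow(exons) == 0L) return(rep(FALSE, nrow(elements)))
  egr <- GenomicRanges::GRanges(exons$seq_id,
                                IRanges::IRanges(exons$start, exons$end))
  agr <- GenomicRanges::GRanges(elements$a_seq,
                                IRanges::IRanges(elements$a_start,
                                                 elements$a_end))
  ovl <- GenomicRanges::findOverlaps(agr, egr,
                                     minoverlap = cfg$exon_overlap_min)
  out <- rep(FALSE, nrow(elements))
  out[unique(S4Vectors::queryHits(ovl))] <- TRUE
  out
}

#' Partition elements by repeat (masked-base) content
#'
#' Removed when the element contains strictly more than `cfg$max_repeat_bp`
#' masked bases on genome A.
#'
#' @param elements Element table.
#' @param genome_a Masked genome (named character vector).
#' @param cfg [filter_config()].
#' @param assume_n_masked Count `N` as masked (see [masked_bp()]).
#' @return Logical vector, TRUE where removed.
#' @export
filter_repeats <- function(elements, genome_a, cfg = filter_config(),
                           assume_n_masked = TRUE) {
  if (nrow(elements) == 0L) return(logical(0))
  vapply(seq_len(nrow(elements)), function(i) {
    iv <- genomic_interval(elements$a_seq[i], elements$a_start[i],
                           elements$a_end[i])
    masked_bp(genome_a, iv, assume_n_masked) > cfg$max_repeat_bp
  }, logical(1))
}

# Count reference sequences matched by an element sequence at the screen
# E-value, using the same seed-and-extend scoring as the main search.
screen_matches <- function(el_seq, refs, evalue_max, acfg, word_len) {
  if (length(refs) == 0L) return(character(0))
  ka <- calibrate_ka(acfg$match, acfg$mismatch, acfg$base_freqs, acfg$ka_k)
  scfg <- acfg
  scfg$word_len <- as.integer(word_len)
  matched <- character(0)
  for (rid in names(refs)) {
    hits <- align_pair(el_seq, refs[[rid]], scfg)
    if (nrow(hits) == 0L) next
    ev <- ka_evalue(hits$score, nchar(el_seq), nchar(refs[[rid]]), ka)
    if (any(ev <= evalue_max)) matched <- c(matched, rid)
  }
  matched
}

#' Partition elements by structured-RNA similarity
#'
#' Removed when the element sequence aligns to any non-coding RNA
#' reference at E-value `cfg$ncrna_evalue` or better.
#'
#' @param elements Element table.
#' @param genome_a Genome providing element sequences.
#' @param ncrna_refs Named character vector of reference sequences.
#' @param cfg [filter_config()].
#' @param align_cfg [align_config()] used for screen scoring.
#' @return Logical vector, TRUE where removed.
#' @export
filter_ncrna <- function(elements, genome_a, ncrna_refs,
                         cfg = filter_config(),
                         align_cfg = align_config()) {
  if (nrow(elements) == 0L) return(logical(0))
  vapply(seq_len(nrow(elements)), function(i) {
    el_seq <- toupper(substr(genome_a[[elements$a_seq[i]]],
                             elements$a_start[i], elements$a_end[i]))
    length(screen_matches(el_seq, ncrna_refs, cfg$ncrna_evalue, align_cfg,
                          cfg$screen_word_len)) >= 1L
  }, logical(1))
}

#' Count expressed-transcript evidence and classify
#'
#' Counts distinct expressed-sequence references with at least one
#' alignment at E-value `cfg$est_evalue` or better. More than
#' `cfg$max_est_matches` matches removes the element; 1 to
#' `cfg$max_est_matches` matches labels it `weak`; zero labels it `none`.
#'
#' @param elements Element table.
#' @param genome_a Genome providing element sequences.
#' @param est_refs Named character vector of reference sequences.
#' @param cfg [filter_config()].
#' @param align_cfg [align_config()].
#' @return List with `remove` (logical) and `est_matches` (integer),
#'   `evidence_class` (character: `none`/`weak`, NA where removed).
#' @export
classify_est_evidence <- function(elements, genome_a, est_refs,
                                  cfg = filter_config(),
                                  align_cfg = align_config()) {
  if (nrow(elements) == 0L) {
    return(list(remove = logical(0), est_matches = integer(0),
                evidence_class = character(0)))
  }
  counts <- vapply(seq_len(nrow(elements)), function(i) {
    el_seq <- toupper(substr(genome_a[[elements$a_seq[i]]],
                             elements$a_start[i], elements$a_end[i]))
    length(screen_matches(el_seq, est_refs, cfg$est_evalue, align_cfg,
                          cfg$screen_word_len))
  }, integer(1))
  remove <- counts > cfg$max_est_matches
  cls <- ifelse(remove, NA_character_,
                ifelse(counts == 0L, "none", "weak"))
  list(remove = remove, est_matches = counts, evidence_class = cls)
}

#' Partition elements by multi-locus matching
#'
#' An element is removed when its genome-A interval participates in
#' retained alignments to two or more mutually non-overlapping genome-B
#' loci (duplicated sequence; single-copy analysis only).
#'
#' @param elements Element table.
#' @param all_hits Full retained hit table from [run_search()].
#' @return Logical vector, TRUE where removed.
#' @export
filter_multihit <- function(elements, all_hits) {
  if (nrow(elements) == 0L) return(logical(0))
  vapply(seq_len(nrow(elements)), function(i) {
    same <- all_hits$a_seq == elements$a_seq[i] &
      all_hits$a_start <= elements$a_end[i] &
      all_hits$a_end >= elements$a_start[i]
    h <- all_hits[same, , drop = FALSE]
    if (nrow(h) <= 1L) return(FALSE)
    # cluster B loci by overlap; >= 2 clusters means multiple locations
    gr <- GenomicRanges::GRanges(h$b_seq,
                                 IRanges::IRanges(h$b_start, h$b_end))
    length(GenomicRanges::reduce(gr)) >= 2L
  }, logical(1))
}

#' Run the annotation filter cascade
#'
#' Stages are applied in the fixed order of the discovery protocol: exon
#' overlap, repeat content, structured-RNA screen, expressed-transcript
#' screen, multi-location removal. Every rejected element carries the name
#' of the first stage that rejected it; retained elements carry a
#' transcription-evidence class (`none` or `weak`).
#'
#' @param hits Retained hit table from [run_search()].
#' @param annotations List with `exons` (interval table), `ncrna` and
#'   `ests` (named character vectors of reference sequences). A missing
#'   layer is an error naming the layer.
#' @param genome_a Masked genome A (named character vector).
#' @param cfg [filter_config()].
#' @param align_cfg [align_config()] used by the sequence screens.
#' @return List with `elements` (all element records with `status`,
#'   `rejected_by`, `evidence_class`, `est_matches`), `retained` (the
#'   retained subset) and `funnel` (stage, n_in, n_out).
#' @export
run_cascade <- function(hits, annotations, genome_a,
                        cfg = filter_config(),
                        align_cfg = align_config()) {
  for (layer in c("exons", "ncrna", "ests")) {
    if (!layer %in% names(annotations)) {
      stop("missing annotation layer: ", layer)
    }
  }
  el <- merge_hits_to_elements(hits)
  el$status <- rep("retained", nrow(el))
  el$rejected_by <- rep("", nrow(el))
  el$evidence_class <- rep(NA_character_, nrow(el))
  el$est_matches <- rep(NA_integer_, nrow(el))

  funnel <- data.frame(stage = "merge", n_in = nrow(hits),
                       n_out = nrow(el), stringsAsFactors = FALSE)
  active <- rep(TRUE, nrow(el))

  apply_stage <- function(name, remove_active) {
    idx <- which(active)
    rem <- idx[remove_active]
    el$status[rem] <<- "rejected"
    el$rejected_by[rem] <<- name
    active[rem] <<- FALSE
    funnel <<- rbind(funnel,
                     data.frame(stage = name, n_in = length(idx),
                                n_out = sum(active),
                                stringsAsFactors = FALSE))
  }

  apply_stage("exon_overlap",
              filter_exon_overlap(el[active, , drop = FALSE],
                                  annotations$exons, cfg))
  apply_stage("repeats",
              filter_repeats(el[active, , drop = FALSE], genome_a, cfg))
  apply_stage("ncrna",
              filter_ncrna(el[active, , drop = FALSE], genome_a,
                           annotations$ncrna, cfg, align_cfg))
  est <- classify_est_evidence(el[active, , drop = FALSE], genome_a,
                               annotations$ests, cfg, align_cfg)
  idx <- which(active)
  el$est_matches[idx] <- est$est_matches
  el$evidence_class[idx] <- est$evidence_class
  apply_stage("est", est$remove)
  apply_stage("multi_location",
              filter_multihit(el[active, , drop = FALSE], hits))

  retained <- el[el$status == "retained", , drop = FALSE]
  rownames(retained) <- NULL
  list(elements = el, retained = retained, funnel = funnel)
}
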
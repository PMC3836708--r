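#' Synthetic genome-pair configuration
#'
#' The generator emulates a pair of highly diverged genomes in which only
#' functionally constrained elements still align: the two backgrounds are
#' generated independently (the divergence regime where neutral sequence no
#' longer aligns at the search thresholds), and conserved elements are
#' planted with a target identity, a short perfectly conserved core, and
#' occasional short indels. Decoy classes exercise every stage of the
#' annotation filter cascade: conserved exons, repeat-overlapping elements,
#' structured-RNA elements, transcript-covered elements, and elements
#' duplicated at two loci of genome B.
#'
#' Planted element lengths follow a shifted exponential (minimum plus an
#' exponential tail matching the observed mean of 181.6 bp) and identities
#' are uniform on `cne_identity_range`. Because the observed length and
#' identity distributions of real CNE sets describe *discovered* elements,
#' the generator conditions each (length, identity) pair on being
#' discoverable at the default search thresholds: the planted substitution
#' load must leave an alignment score of at least `min_planted_score`
#' (E-value ceiling plus indel and end-trim slack) and a length of at
#' least 125 bp.
#'
#' @param seed Integer seed; all randomness flows from one stream.
#' @param n_chrom,chrom_len Number and length (bp) of chromosomes per
#'   genome.
#' @param n_cnes Number of planted conserved non-coding elements.
#' @param cne_len_range,cne_len_mean Planted length range and mean (bp).
#' @param cne_identity_range Planted identity range (fractions).
#' @param n_decoy_exons,n_decoy_repeats,n_decoy_ncrnas,n_est_covered,n_duplicated
#'   Decoy counts per class.
#' @param n_genes Number of background gene models.
#' @param n_background_repeats Unrelated masked repeat intervals.
#' @param n_gap_runs Assembly-gap (`N`) runs placed in genome A.
#' @param domain_enrichment_lor Planted log-odds ratio of the target
#'   protein domain among CNE-associated genes.
#' @param domain_baseline_prev Baseline prevalence of the target domain.
#' @param n_null_domains Unenriched domains in the annotation table.
#' @param core_len Length of the perfectly conserved core of each planted
#'   element (bp).
#' @param min_planted_score Minimum alignment score a planted element must
#'   be able to reach given its substitution load.
#' @param rev_strand_prob Probability a genome-B copy is inserted on the
#'   reverse strand.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_chrom = 2L, chrom_len = 500000L,
                             n_cnes = 40L,
                             cne_len_range = c(94L, 1883L),
                             cne_len_mean = 181.6,
                             cne_identity_range = c(0.71, 0.97),
                             n_decoy_exons = 8L, n_decoy_repeats = 8L,
                             n_decoy_ncrnas = 6L, n_est_covered = 8L,
                             n_duplicated = 4L, n_genes = 120L,
                             n_background_repeats = 30L, n_gap_runs = 5L,
                             domain_enrichment_lor = 1.5,
                             domain_baseline_prev = 0.12,
                             n_null_domains = 12L,
                             core_len = 28L, min_planted_score = 55L,
                             rev_strand_prob = 0.3) {
  counts <- c(n_chrom, n_cnes, n_decoy_exons, n_decoy_repeats,
              n_decoy_ncrnas, n_est_covered, n_duplicated, n_genes,
              n_background_repeats, n_gap_runs, n_null_domains)
  stopifnot(all(counts >= 0L), chrom_len >= 1000L,
            cne_len_range[1] <= cne_len_range[2],
            cne_identity_range[1] <= cne_identity_range[2],
            all(cne_identity_range >= 0), all(cne_identity_range <= 1),
            core_len >= 20L, rev_strand_prob >= 0, rev_strand_prob <= 1)
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len),
                 n_cnes = as.integer(n_cnes),
                 cne_len_range = as.integer(cne_len_range),
                 cne_len_mean = cne_len_mean,
                 cne_identity_range = cne_identity_range,
                 n_decoy_exons = as.integer(n_decoy_exons),
                 n_decoy_repeats = as.integer(n_decoy_repeats),
                 n_decoy_ncrnas = as.integer(n_decoy_ncrnas),
                 n_est_covered = as.integer(n_est_covered),
                 n_duplicated = as.integer(n_duplicated),
                 n_genes = as.integer(n_genes),
                 n_background_repeats = as.integer(n_background_repeats),
                 n_gap_runs = as.integer(n_gap_runs),
                 domain_enrichment_lor = domain_enrichment_lor,
                 domain_baseline_prev = domain_baseline_prev,
                 n_null_domains = as.integer(n_null_domains),
                 core_len = as.integer(core_len),
                 min_planted_score = as.integer(min_planted_score),
                 rev_strand_prob = rev_strand_prob),
            class = "synthetic_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Sample (length, identity) for one planted element. Identity is uniform on
# the configured range; length follows the shifted exponential truncated
# below at the smallest length compatible with discovery at that identity
# (truncation uses the memorylessness of the exponential, so no rejection
# loop is needed).
sample_element_geometry <- function(cfg, len_floor = 125L) {
  q <- stats::runif(1, cfg$cne_identity_range[1], cfg$cne_identity_range[2])
  lo <- cfg$cne_len_range[1]
  hi <- cfg$cne_len_range[2]
  drift <- 3 * q - 2  # expected score per aligned column at +1/-2
  need <- if (drift > 0) ceiling(cfg$min_planted_score / drift) else Inf
  l_min <- max(lo, len_floor, need)
  if (l_min > hi) {
    stop("no feasible planted length at identity ", round(q, 3),
         " within the configured length range")
  }
  rate <- 1 / max(cfg$cne_len_mean - lo, 1)
  # truncated shifted exponential on [l_min, hi]
  a <- l_min - lo
  b <- hi - lo
  u <- stats::runif(1)
  fa <- 1 - exp(-rate * a)
  fb <- 1 - exp(-rate * b)
  x <- -log(1 - (fa + u * (fb - fa))) / rate
  len <- as.integer(round(lo + x))
  len <- max(l_min, min(hi, len))
  # rounding of the substitution count can nudge the score below the
  # floor; lengthen by a base or two if so
  while (len - 3 * round((1 - q) * len) < cfg$min_planted_score &&
         len < hi) {
    len <- len + 1L
  }
  list(length = as.integer(len), identity = q)
}

# Mutate an element copy toward a target identity. Substitutions are placed
# by stratified sampling outside the conserved core (one substitution per
# equal-width stratum, uniform within the stratum), so local identity stays
# close to the element-wide target: functional elements under purifying
# selection keep a floor of local conservation, which is what makes them
# detectable as single blocks. Up to two short (1-2 bp) indels are added
# outside the core.
mutate_element <- function(seq, identity, core_start, core_len,
                           max_indels = 2L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  core_pos <- seq.int(core_start, core_start + core_len - 1L)
  eligible <- setdiff(seq_len(L), core_pos)
  n_sub <- round((1 - identity) * L)
  n_sub <- min(n_sub, length(eligible))
  if (n_sub > 0L) {
    strata <- split(eligible,
                    cut(seq_along(eligible), breaks = n_sub, labels = FALSE))
    pos <- vapply(strata, function(s) if (length(s) == 1L) s else sample(s, 1),
                  integer(1))
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), toupper(chars[p])), 1)
    }
  }
  out <- paste(chars, collapse = "")
  n_indel <- sample(0:max_indels, 1, prob = c(0.6, 0.3, 0.1)[1:(max_indels + 1)])
  if (n_indel > 0L) {
    for (i in seq_len(n_indel)) {
      l <- sample(1:2, 1)
      # keep indels clear of the (fixed-coordinate) core
      L_now <- nchar(out)
      ok <- setdiff(seq_len(L_now),
                    seq.int(max(1L, core_start - l),
                            min(L_now, core_start + core_len + l)))
      if (length(ok) == 0L) next
      p <- sample(ok, 1)
      if (stats::runif(1) < 0.5 && p + l - 1L <= L_now && !any(
            seq.int(p, p + l - 1L) %in% seq.int(core_start,
                                                core_start + core_len - 1L))) {
        out <- paste0(substr(out, 1, p - 1L), substr(out, p + l, L_now))
      } else {
        out <- paste0(substr(out, 1, p), random_dna(l),
                      substr(out, p + 1L, L_now))
      }
    }
  }
  out
}

# Place items of given widths on chromosomes without overlapping previously
# placed intervals (padded). Errors when capacity is exhausted.
place_intervals <- function(widths, chrom_lens, occupied, pad = 100L,
                            max_tries = 10000L) {
  out <- data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  chroms <- names(chrom_lens)
  for (w in widths) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      sid <- sample(chroms, 1, prob = as.numeric(chrom_lens))
      if (chrom_lens[[sid]] < w) next
      s <- sample.int(chrom_lens[[sid]] - w + 1L, 1)
      e <- s + w - 1L
      occ <- occupied[[sid]]
      clash <- !is.null(occ) && nrow(occ) > 0L &&
        any(occ$start <= e + pad & occ$end >= s - pad)
      if (!clash) {
        occupied[[sid]] <- rbind(occ, data.frame(start = s, end = e))
        out <- rbind(out, data.frame(seq_id = sid, start = s, end = e,
                                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("planted features exceed genome capacity")
  }
  list(placed = out, occupied = occupied)
}

#' Simulate a gene-to-domain annotation with one planted enrichment
#'
#' Every gene carries the target domain with baseline probability `p0`;
#' CNE-associated genes carry it with the elevated probability implied by
#' the requested log-odds ratio. The target domain is annotated through two
#' child identifiers so the hierarchy roll-up is exercised; `n_null_domains`
#' additional domains have CNE-independent prevalences.
#'
#' @param n_genes Total genes (ids generated as `gA0001`, ... when
#'   `gene_ids` is NULL).
#' @param n_cne_genes Number of CNE-associated genes.
#' @param lor Planted natural-log odds ratio.
#' @param p0 Baseline prevalence of the target domain.
#' @param n_null_domains Number of unenriched domains.
#' @param gene_ids,cne_genes Optional explicit gene id vectors.
#' @param seed Optional seed (omit to use the ambient RNG stream).
#' @return List with `annotations` (gene_id, domain_id), `hierarchy`
#'   (child, parent), `target_domain`, `all_genes`, `cne_genes`.
#' @export
simulate_domain_annotation <- function(n_genes = 1000L, n_cne_genes = 200L,
                                       lor = 1.5, p0 = 0.12,
                                       n_null_domains = 12L,
                                       gene_ids = NULL, cne_genes = NULL,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("gA%04d", seq_len(n_genes))
  }
  n_genes <- length(gene_ids)
  if (is.null(cne_genes)) {
    cne_genes <- sample(gene_ids, min(n_cne_genes, n_genes))
  }
  target <- "homeodomain_like"
  children <- paste0(target, "_sub", 1:2)
  p1 <- stats::plogis(stats::qlogis(p0) + lor)
  is_cne <- gene_ids %in% cne_genes
  has_target <- stats::runif(n_genes) < ifelse(is_cne, p1, p0)
  ann <- data.frame(gene_id = gene_ids[has_target],
                    domain_id = sample(children, sum(has_target),
                                       replace = TRUE),
                    stringsAsFactors = FALSE)
  if (n_null_domains > 0L) {
    prev <- stats::runif(n_null_domains, 0.05, 0.30)
    for (j in seq_len(n_null_domains)) {
      has <- stats::runif(n_genes) < prev[j]
      if (any(has)) {
        ann <- rbind(ann, data.frame(gene_id = gene_ids[has],
                                     domain_id = sprintf("dom%02d", j),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  hierarchy <- data.frame(child = children,
                          parent = target,
                          stringsAsFactors = FALSE)
  list(annotations = ann, hierarchy = hierarchy, target_domain = target,
       all_genes = gene_ids, cne_genes = cne_genes)
}

#' Generate a synthetic genome pair with planted truth
#'
#' Emits two genomes, annotation layers and a truth ledger. Genome
#' backgrounds are independent random sequence; planted conserved elements
#' (and conserved decoys) are copied from genome A into genome B after
#' mutation to the target identity. Decoy classes are constructed so the
#' filter cascade must reject each at its designated stage: conserved exons
#' (overlapping an annotated exon), repeat elements (more than 10 masked
#' bp), structured-RNA elements (verbatim in the ncRNA reference set),
#' transcript-covered elements (2 matching expressed-sequence references
#' for the retained "weak" half, 5 for the removed half), and duplicated
#' elements (two distinct genome-B loci).
#'
#' @param cfg [synthetic_config()].
#' @param out_dir Output directory; created if missing. When `NULL`,
#'   nothing is written and the truth set is only returned.
#' @return Invisibly, a list with `genome_a`, `genome_b`, `truth`
#'   (elements ledger), `genes`, `exons`, `repeats`, `ncrna`, `ests`,
#'   `domains`, `hierarchy`, `orthology`, `b_cne_genes`, `files`, `config`.
#' @export
generate_pair <- function(cfg = synthetic_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  chroms_a <- sprintf("chrA%02d", seq_len(cfg$n_chrom))
  chroms_b <- sprintf("chrB%02d", seq_len(cfg$n_chrom))
  chrom_lens_a <- stats::setNames(rep(cfg$chrom_len, cfg$n_chrom), chroms_a)
  chrom_lens_b <- stats::setNames(rep(cfg$chrom_len, cfg$n_chrom), chroms_b)

  genome_a <- stats::setNames(
    vapply(chroms_a, function(x) random_dna(cfg$chrom_len), character(1)),
    chroms_a)
  genome_b <- stats::setNames(
    vapply(chroms_b, function(x) random_dna(cfg$chrom_len), character(1)),
    chroms_b)

  occupied_a <- stats::setNames(
    replicate(cfg$n_chrom, data.frame(start = integer(0), end = integer(0)),
              simplify = FALSE), chroms_a)

  # assembly gaps (N runs) in genome A
  if (cfg$n_gap_runs > 0L) {
    pg <- place_intervals(rep(50L, cfg$n_gap_runs), chrom_lens_a, occupied_a)
    occupied_a <- pg$occupied
    for (i in seq_len(nrow(pg$placed))) {
      r <- pg$placed[i, ]
      substr(genome_a[[r$seq_id]], r$start, r$end) <-
        strrep("N", r$end - r$start + 1L)
    }
  }

  # unrelated background repeats (masked in A, recorded in the BED layer)
  repeats <- data.frame(seq_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  if (cfg$n_background_repeats > 0L) {
    widths <- sample(50:500, cfg$n_background_repeats, replace = TRUE)
    pr <- place_intervals(widths, chrom_lens_a, occupied_a)
    occupied_a <- pr$occupied
    repeats <- rbind(repeats, pr$placed)
  }

  # background gene models: two terminal exons per gene
  genes <- data.frame(gene_id = character(0), seq_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  exons <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
  if (cfg$n_genes > 0L) {
    body <- sample(1500:3000, cfg$n_genes, replace = TRUE)
    pgn <- place_intervals(body, chrom_lens_a, occupied_a)
    occupied_a <- pgn$occupied
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    genes <- data.frame(gene_id = sprintf("gA%04d", seq_len(cfg$n_genes)),
                        seq_id = pgn$placed$seq_id, strand = strand,
                        start = pgn$placed$start, end = pgn$placed$end,
                        stringsAsFactors = FALSE)
    exw <- 250L
    exons <- rbind(
      data.frame(seq_id = genes$seq_id, start = genes$start,
                 end = genes$start + exw - 1L, strand = genes$strand,
                 gene_id = genes$gene_id, stringsAsFactors = FALSE),
      data.frame(seq_id = genes$seq_id, start = genes$end - exw + 1L,
                 end = genes$end, strand = genes$strand,
                 gene_id = genes$gene_id, stringsAsFactors = FALSE))
  }
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)

  # planted conserved elements, in fixed class order
  classes <- c(rep("cne", cfg$n_cnes),
               rep("exon", cfg$n_decoy_exons),
               rep("repeat", cfg$n_decoy_repeats),
               rep("ncrna", cfg$n_decoy_ncrnas),
               rep("est_covered", cfg$n_est_covered),
               rep("duplicated", cfg$n_duplicated))
  n_el <- length(classes)
  truth <- NULL
  ncrna_refs <- character(0)
  est_refs <- character(0)
  occupied_b <- stats::setNames(
    replicate(cfg$n_chrom, data.frame(start = integer(0), end = integer(0)),
              simplify = FALSE), chroms_b)

  if (n_el > 0L) {
    geoms <- vector("list", n_el)
    for (i in seq_len(n_el)) {
      floor_i <- if (classes[i] == "repeat") 160L else 125L
      geoms[[i]] <- sample_element_geometry(cfg, len_floor = floor_i)
    }
    lens <- vapply(geoms, function(g) g$length, integer(1))
    pe <- place_intervals(lens, chrom_lens_a, occupied_a)
    occupied_a <- pe$occupied
    placed <- pe$placed

    n_weak <- if (cfg$n_est_covered > 0L) ceiling(cfg$n_est_covered / 2) else 0L
    est_idx <- which(classes == "est_covered")
    weak_set <- if (length(est_idx)) est_idx[seq_len(n_weak)] else integer(0)

    rows <- list()
    for (i in seq_len(n_el)) {
      cls <- classes[i]
      sid <- placed$seq_id[i]
      a_start <- placed$start[i]
      a_end <- placed$end[i]
      L <- lens[i]
      q <- geoms[[i]]$identity
      a_seq_el <- toupper(substr(genome_a[[sid]], a_start, a_end))
      core_start <- as.integer(floor((L - cfg$core_len) / 2) + 1L)

      n_copies <- if (cls == "duplicated") 2L else 1L
      for (cp in seq_len(n_copies)) {
        b_copy <- mutate_element(a_seq_el, q, core_start, cfg$core_len)
        b_strand <- if (stats::runif(1) < cfg$rev_strand_prob) "-" else "+"
        ins <- if (b_strand == "-") revcomp(b_copy) else b_copy
        pb <- place_intervals(nchar(ins), chrom_lens_b, occupied_b)
        occupied_b <- pb$occupied
        bq <- pb$placed
        substr(genome_b[[bq$seq_id]], bq$start, bq$end) <- ins
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = sprintf("el%04d", i), class = cls,
          a_seq = sid, a_start = a_start, a_end = a_end, length = L,
          target_identity = q, core_start = a_start + core_start - 1L,
          core_end = a_start + core_start + cfg$core_len - 2L,
          b_seq = bq$seq_id, b_start = bq$start, b_end = bq$end,
          b_strand = b_strand, copy = cp,
          n_est_refs = 0L, expected_fate = "", expected_stage = "",
          stringsAsFactors = FALSE)
      }

      if (cls == "exon") {
        gid <- sprintf("gX%04d", i)
        genes <- rbind(genes, data.frame(
          gene_id = gid, seq_id = sid, strand = "+", start = a_start,
          end = a_end, tss = a_start, stringsAsFactors = FALSE))
        exons <- rbind(exons, data.frame(
          seq_id = sid, start = a_start, end = a_end, strand = "+",
          gene_id = gid, stringsAsFactors = FALSE))
      } else if (cls == "repeat") {
        # a 20 bp masked stretch clear of the conserved core
        ms <- a_start + core_start + cfg$core_len + 9L
        if (ms + 19L > a_end) ms <- max(a_start, a_start + core_start - 31L)
        me <- min(ms + 19L, a_end)
        repeats <- rbind(repeats, data.frame(seq_id = sid, start = ms,
                                             end = me,
                                             stringsAsFactors = FALSE))
      } else if (cls == "ncrna") {
        ncrna_refs <- c(ncrna_refs,
                        stats::setNames(a_seq_el, sprintf("ncRNA_el%04d", i)))
      } else if (cls == "est_covered") {
        n_ref <- if (i %in% weak_set) 2L else 5L
        for (k in seq_len(n_ref)) {
          wlen <- min(L - 10L, sample(80:150, 1))
          ws <- sample.int(L - wlen + 1L, 1)
          est_refs <- c(est_refs,
                        stats::setNames(substr(a_seq_el, ws, ws + wlen - 1L),
                                        sprintf("EST_el%04d_%d", i, k)))
        }
        idx <- length(rows)
        rows[[idx]]$n_est_refs <- n_ref
      }
    }
    truth <- do.call(rbind, rows)
    truth$expected_fate <- ifelse(
      truth$class %in% c("cne") |
        (truth$class == "est_covered" & truth$n_est_refs <= 3L),
      "retained", "rejected")
    truth$expected_stage <- c(cne = "", exon = "exon_overlap",
                              "repeat" = "repeats", ncrna = "ncrna",
                              est_covered = "est",
                              duplicated = "multi_location")[truth$class]
    truth$expected_stage[truth$expected_fate == "retained"] <- ""
  } else {
    truth <- data.frame(element_id = character(0), class = character(0),
                        a_seq = character(0), a_start = integer(0),
                        a_end = integer(0), length = integer(0),
                        target_identity = numeric(0),
                        core_start = integer(0), core_end = integer(0),
                        b_seq = character(0), b_start = integer(0),
                        b_end = integer(0), b_strand = character(0),
                        copy = integer(0), n_est_refs = integer(0),
                        expected_fate = character(0),
                        expected_stage = character(0),
                        stringsAsFactors = FALSE)
  }

  # unrelated reference sequences so the RNA/EST screens are non-trivial
  for (k in 1:5) {
    ncrna_refs <- c(ncrna_refs,
                    stats::setNames(random_dna(sample(100:300, 1)),
                                    sprintf("ncRNA_bg%02d", k)))
  }
  for (k in 1:10) {
    est_refs <- c(est_refs,
                  stats::setNames(random_dna(sample(200:500, 1)),
                                  sprintf("EST_bg%02d", k)))
  }

  # mask genome A at all repeat intervals
  genome_a <- mask_genome(genome_a, repeats)

  # gene-to-domain annotation with the planted enrichment
  cne_rows <- truth[truth$class == "cne" & truth$copy == 1L, , drop = FALSE]
  cne_gene_ids <- character(0)
  if (nrow(cne_rows) > 0L && nrow(genes) > 0L) {
    asg <- assign_nearest_tss(cne_rows, genes)
    cne_gene_ids <- unique(asg$gene_id[!is.na(asg$gene_id)])
  }
  dom <- simulate_domain_annotation(
    gene_ids = genes$gene_id, cne_genes = cne_gene_ids,
    lor = cfg$domain_enrichment_lor, p0 = cfg$domain_baseline_prev,
    n_null_domains = cfg$n_null_domains)

  # orthology to a virtual second species; some genes map to two orthologs
  orth <- NULL
  b_cne_genes <- character(0)
  if (nrow(genes) > 0L) {
    has1 <- stats::runif(nrow(genes)) < 0.6
    has2 <- has1 & stats::runif(nrow(genes)) < 0.33
    o1 <- data.frame(gene_a = genes$gene_id[has1],
                     gene_b = sprintf("vg%04d", which(has1)),
                     stringsAsFactors = FALSE)
    o2 <- data.frame(gene_a = genes$gene_id[has2],
                     gene_b = sprintf("vg%04d", 5000L + which(has2)),
                     stringsAsFactors = FALSE)
    orth <- rbind(o1, o2)
    shared_a <- cne_gene_ids[stats::runif(length(cne_gene_ids)) < 0.6]
    b_cne_genes <- unique(orth$gene_b[orth$gene_a %in% shared_a])
    extra <- setdiff(orth$gene_b, b_cne_genes)
    if (length(extra) > 0L) {
      b_cne_genes <- c(b_cne_genes, sample(extra, min(5L, length(extra))))
    }
  } else {
    orth <- data.frame(gene_a = character(0), gene_b = character(0),
                       stringsAsFactors = FALSE)
  }

  out <- list(genome_a = genome_a, genome_b = genome_b, truth = truth,
              genes = genes, exons = exons, repeats = repeats,
              ncrna = ncrna_refs, ests = est_refs,
              domains = dom$annotations, hierarchy = dom$hierarchy,
              target_domain = dom$target_domain,
              cne_gene_ids = cne_gene_ids,
              orthology = orth, b_cne_genes = b_cne_genes,
              files = NULL, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      genome_a = file.path(out_dir, "genomeA.fa"),
      genome_b = file.path(out_dir, "genomeB.fa"),
      genes = file.path(out_dir, "genes.gff3"),
      repeats = file.path(out_dir, "repeats.bed"),
      ncrna = file.path(out_dir, "ncrna.fa"),
      ests = file.path(out_dir, "ests.fa"),
      domains = file.path(out_dir, "domains.tsv"),
      hierarchy = file.path(out_dir, "domain_hierarchy.tsv"),
      orthology = file.path(out_dir, "orthology.tsv"),
      b_cne_genes = file.path(out_dir, "b_cne_genes.txt"),
      truth = file.path(out_dir, "truth.tsv"))
    write_genome_fasta(genome_a, files$genome_a)
    write_genome_fasta(genome_b, files$genome_b)
    write_gene_models(genes, exons, files$genes)
    if (nrow(repeats) > 0L) write_bed(repeats, files$repeats)
    else writeLines(character(0), files$repeats)
    write_genome_fasta(ncrna_refs, files$ncrna)
    write_genome_fasta(est_refs, files$ests)
    write_tsv_file(out$domains, files$domains)
    write_tsv_file(out$hierarchy, files$hierarchy)
    write_tsv_file(orth, files$orthology)
    writeLines(b_cne_genes, files$b_cne_genes)
    write_tsv_file(truth, files$truth)
    out$files <- files
  }
  invisible(out)
}

#' Score recovery of planted elements
#'
#' A planted CNE counts as recovered when a retained element overlaps at
#' least half of its genome-A interval. Precision treats a call as
#' supported when it covers at least half of any planted element whose
#' expected fate is retention (planted CNEs and weakly transcribed
#' elements).
#'
#' @param truth Truth ledger from [generate_pair()] (the `truth` element).
#' @param called Data frame of retained elements with `a_seq`, `a_start`,
#'   `a_end`.
#' @return List with `recall`, `precision` and `confusion` (per planted
#'   class: `n`, `n_detected`).
#' @export
score_recovery <- function(truth, called) {
  tr <- truth[truth$copy == 1L, , drop = FALSE]
  covered <- function(tr_row) {
    if (nrow(called) == 0L) return(FALSE)
    same <- called$a_seq == tr_row$a_seq
    if (!any(same)) return(FALSE)
    ov <- pmax(0L, pmin(called$a_end[same], tr_row$a_end) -
                     pmax(called$a_start[same], tr_row$a_start) + 1L)
    any(ov >= 0.5 * (tr_row$a_end - tr_row$a_start + 1L))
  }
  det <- vapply(seq_len(nrow(tr)), function(i) covered(tr[i, ]), logical(1))

  cne <- tr$class == "cne"
  recall <- if (any(cne)) mean(det[cne]) else NA_real_

  retainable <- tr[tr$expected_fate == "retained", , drop = FALSE]
  supported <- function(i) {
    if (nrow(retainable) == 0L) return(FALSE)
    same <- retainable$a_seq == called$a_seq[i]
    if (!any(same)) return(FALSE)
    ov <- pmax(0L, pmin(retainable$a_end[same], called$a_end[i]) -
                     pmax(retainable$a_start[same], called$a_start[i]) + 1L)
    any(ov >= 0.5 * (retainable$a_end[same] - retainable$a_start[same] + 1L))
  }
  precision <- if (nrow(called) > 0L) {
    mean(vapply(seq_len(nrow(called)), supported, logical(1)))
  } else NA_real_

  confusion <- do.call(rbind, lapply(split(seq_len(nrow(tr)), tr$class),
    function(ix) data.frame(class = tr$class[ix[1]], n = length(ix),
                            n_detected = sum(det[ix]),
                            stringsAsFactors = FALSE)))
  rownames(confusion) <- NULL
  list(recall = recall, precision = precision, confusion = confusion)
}

#' Check that each decoy was rejected at its designated stage
#'
#' @param truth Truth ledger from [generate_pair()].
#' @param elements Element records from [run_cascade()] (all statuses).
#' @return Data frame with one row per planted decoy: `element_id`,
#'   `class`, `expected_stage`, `observed_stage`, `detected`, `ok`.
#' @export
decoy_stage_report <- function(truth, elements) {
  tr <- truth[truth$copy == 1L & truth$expected_fate == "rejected", ,
              drop = FALSE]
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    t <- tr[i, ]
    same <- elements$a_seq == t$a_seq
    ov <- rep(0L, nrow(elements))
    ov[same] <- pmax(0L, pmin(elements$a_end[same], t$a_end) -
                           pmax(elements$a_start[same], t$a_start) + 1L)
    hit <- ov >= 1L
    obs <- unique(elements$rejected_by[hit])
    obs <- obs[nzchar(obs)]
    data.frame(element_id = t$element_id, class = t$class,
               expected_stage = t$expected_stage,
               observed_stage = if (length(obs)) paste(obs, collapse = ",")
                                else "",
               detected = any(hit),
               ok = any(hit) && length(obs) >= 1L &&
                 all(obs == t$expected_stage),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(element_id = character(0), class = character(0),
                      expected_stage = character(0),
                      observed_stage = character(0), detected = logical(0),
                      ok = logical(0), stringsAsFactors = FALSE)
  }
  out
}
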
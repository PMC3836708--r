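# Helpers to build element tables without running the aligner.
el_row <- function(id, seq, s, e, b_seq = "chrB", b_s = 1L, b_e = NULL) {
  if (is.null(b_e)) b_e <- b_s + (e - s)
  data.frame(element_id = id, a_seq = seq, a_start = s, a_end = e,
             length = e - s + 1L, b_seq = b_seq, b_start = b_s,
             b_end = b_e, b_strand = "+", pct_identity = 90,
             n_hits = 1L, stringsAsFactors = FALSE)
}

test_that("exon overlap removal triggers at a single shared base", {
  exons <- data.frame(seq_id = "chrA", start = 1000L, end = 1500L)
  els <- rbind(el_row("e1", "chrA", 1500L, 1700L),   # 1 bp shared
               el_row("e2", "chrA", 1501L, 1700L),   # adjacent
               el_row("e3", "chrA", 800L, 999L),     # adjacent left
               el_row("e4", "chrB", 1000L, 1500L))   # other sequence
  rem <- filter_exon_overlap(els, exons)
  expect_equal(rem, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("exon overlap via interval index equals the all-pairs scan", {
  set.seed(43)
  exons <- data.frame(seq_id = sample(c("c1", "c2"), 40, TRUE),
                      start = sample(1:5000, 40))
  exons$end <- exons$start + sample(50:300, 40, TRUE)
  els <- do.call(rbind, lapply(1:100, function(i) {
    s <- sample(1:5200, 1)
    el_row(paste0("e", i), sample(c("c1", "c2"), 1), s,
           s + sample(50:400, 1))
  }))
  naive <- vapply(seq_len(nrow(els)), function(i) {
    any(exons$seq_id == els$a_seq[i] & exons$start <= els$a_end[i] &
          exons$end >= els$a_start[i])
  }, logical(1))
  expect_equal(filter_exon_overlap(els, exons), naive)
})

test_that("repeat filter is strict at more than 10 masked bases", {
  genome <- c(chrA = paste0(strrep("A", 500), tolower(strrep("c", 50)),
                            strrep("G", 500)))
  # element with exactly 10 masked: positions 491..600 cover 501..510
  els <- rbind(el_row("ten", "chrA", 461L, 510L),     # 10 masked bp
               el_row("eleven", "chrA", 461L, 511L),  # 11 masked bp
               el_row("clean", "chrA", 1L, 400L))     # unmasked
  rem <- filter_repeats(els, genome)
  expect_equal(rem, c(FALSE, TRUE, FALSE))
})

test_that("RNA screen removes verbatim matches and spares unrelated elements", {
  set.seed(47)
  el_seq <- rand_dna(150)
  genome <- c(chrA = paste0(rand_dna(200), el_seq, rand_dna(200)))
  els <- rbind(el_row("hit", "chrA", 201L, 350L),
               el_row("clean", "chrA", 401L, 550L))
  refs <- c(nc1 = el_seq, nc2 = rand_dna(120))
  rem <- filter_ncrna(els, genome, refs, filter_config(), align_config())
  expect_equal(rem, c(TRUE, FALSE))
  # concordance with an independent full-DP screen
  ka <- calibrate_ka()
  for (i in 1:2) {
    s <- toupper(substr(genome[["chrA"]], els$a_start[i], els$a_end[i]))
    sw_hit <- any(vapply(refs, function(r) {
      o <- sw_oracle(s, r)
      ka_evalue(o$score, nchar(s), nchar(r), ka) <= 1e-3
    }, logical(1)))
    expect_equal(rem[i], sw_hit)
  }
})

test_that("transcript evidence splits at three matching references", {
  set.seed(53)
  el_seq <- rand_dna(300)
  genome <- c(chrA = paste0(rand_dna(100), el_seq, rand_dna(100)))
  els <- el_row("e", "chrA", 101L, 400L)
  mk_refs <- function(n) {
    stats::setNames(
      vapply(seq_len(n), function(k) substr(el_seq, 1L + 30L * (k - 1L),
                                            120L + 30L * (k - 1L)),
             character(1)),
      paste0("est", seq_len(n)))
  }
  r3 <- classify_est_evidence(els, genome, mk_refs(3L))
  expect_false(r3$remove)
  expect_equal(r3$est_matches, 3L)
  expect_equal(r3$evidence_class, "weak")

  r4 <- classify_est_evidence(els, genome, mk_refs(4L))
  expect_true(r4$remove)
  expect_equal(r4$est_matches, 4L)

  r0 <- classify_est_evidence(els, genome,
                              c(bg = rand_dna(200)))
  expect_false(r0$remove)
  expect_equal(r0$est_matches, 0L)
  expect_equal(r0$evidence_class, "none")
})

test_that("multi-locus removal needs two non-overlapping partner loci", {
  hit <- function(a_s, a_e, b_seq, b_s, b_e) {
    data.frame(a_seq = "chrA", a_start = a_s, a_end = a_e, b_seq = b_seq,
               b_start = b_s, b_end = b_e, b_strand = "+", score = 100L,
               aligned_cols = a_e - a_s + 1L, identities = a_e - a_s + 1L,
               pct_identity = 100, evalue = 0, stringsAsFactors = FALSE)
  }
  els <- el_row("dup", "chrA", 1000L, 1199L)
  two_loci <- rbind(hit(1000L, 1199L, "chrB", 5000L, 5199L),
                    hit(1000L, 1199L, "chrB", 9000L, 9199L))
  expect_true(filter_multihit(els, two_loci))
  one_locus <- two_loci[1, ]
  expect_false(filter_multihit(els, one_locus))
  # two hits whose partner intervals overlap each other count as one locus
  overlapping <- rbind(hit(1000L, 1199L, "chrB", 5000L, 5199L),
                       hit(1000L, 1150L, "chrB", 5050L, 5199L))
  expect_false(filter_multihit(els, overlapping))
})

test_that("hit merging unifies same-locus hits and keeps distinct loci apart", {
  hit <- function(a_s, a_e, b_s, b_e) {
    data.frame(a_seq = "chrA", a_start = a_s, a_end = a_e, b_seq = "chrB",
               b_start = b_s, b_end = b_e, b_strand = "+", score = 100L,
               aligned_cols = a_e - a_s + 1L, identities = a_e - a_s + 1L,
               pct_identity = 100, evalue = 0, stringsAsFactors = FALSE)
  }
  # overlapping on both genomes: one element with union coordinates
  m <- merge_hits_to_elements(rbind(hit(100L, 300L, 1000L, 1200L),
                                    hit(250L, 400L, 1150L, 1300L)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$a_start, m$a_end), c(100L, 400L))
  expect_equal(c(m$b_start, m$b_end), c(1000L, 1300L))
  # same genome-A span, far-apart partner loci: two elements
  m2 <- merge_hits_to_elements(rbind(hit(100L, 300L, 1000L, 1200L),
                                     hit(100L, 300L, 9000L, 9200L)))
  expect_equal(nrow(m2), 2L)
})

test_that("the cascade runs in order, attributes first failures, is idempotent", {
  set.seed(59)
  cfg <- do.call(synthetic_config, c(list(seed = 21L), small_synth()))
  sim <- generate_pair(cfg)
  hits <- run_search(sim$genome_a, sim$genome_b, align_config())
  ann <- list(exons = sim$exons, ncrna = sim$ncrna, ests = sim$ests)
  res <- run_cascade(hits, ann, sim$genome_a)

  # funnel is stage-consistent and non-increasing
  f <- res$funnel
  expect_equal(f$n_in[-1], f$n_out[-nrow(f)])
  expect_true(all(f$n_out <= f$n_in))
  expect_equal(f$stage, c("merge", "exon_overlap", "repeats", "ncrna",
                          "est", "multi_location"))

  # retained records carry no rejection tag; rejected carry exactly one
  expect_true(all(res$retained$rejected_by == ""))
  rej <- res$elements[res$elements$status == "rejected", ]
  expect_true(all(nzchar(rej$rejected_by)))
  expect_true(all(is.na(rej$evidence_class) |
                    rej$rejected_by %in% c("est", "multi_location")))

  # evidence classes partition the retained set
  expect_equal(sum(res$retained$evidence_class == "none") +
                 sum(res$retained$evidence_class == "weak"),
               nrow(res$retained))

  # permuting hit order leaves the retained set unchanged
  perm <- hits[sample(nrow(hits)), ]
  res2 <- run_cascade(perm, ann, sim$genome_a)
  key <- function(x) sort(paste(x$a_seq, x$a_start, x$a_end))
  expect_identical(key(res2$retained), key(res$retained))

  # each filter is idempotent on its own survivors
  surv <- res$retained
  expect_false(any(filter_exon_overlap(surv, ann$exons)))
  expect_false(any(filter_repeats(surv, sim$genome_a)))
  expect_false(any(filter_multihit(surv, hits)))

  # missing annotation layer errors, naming the layer
  expect_error(run_cascade(hits, list(exons = sim$exons,
                                      ncrna = sim$ncrna), sim$genome_a),
               "ests")
})
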
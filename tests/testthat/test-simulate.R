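test_that("generation is deterministic given the seed", {
  cfg <- do.call(synthetic_config, c(list(seed = 9L), small_synth()))
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  s1 <- generate_pair(cfg, d1)
  s2 <- generate_pair(cfg, d2)
  expect_identical(s1$genome_a, s2$genome_a)
  expect_identical(s1$genome_b, s2$genome_b)
  expect_identical(s1$truth, s2$truth)
  # emitted files are byte-identical
  for (f in c("genomeA.fa", "genomeB.fa", "truth.tsv", "domains.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_equal(sum(s1$truth$class == "cne"), cfg$n_cnes)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth records map to valid coordinates in the emitted files", {
  cfg <- do.call(synthetic_config, c(list(seed = 10L), small_synth()))
  dir <- file.path(tempdir(), "simC")
  sim <- generate_pair(cfg, dir)
  ga <- read_genome_fasta(sim$files$genome_a)
  gb <- read_genome_fasta(sim$files$genome_b)
  tr <- sim$truth
  expect_true(all(tr$a_seq %in% names(ga)))
  expect_true(all(tr$b_seq %in% names(gb)))
  expect_true(all(tr$a_end <= nchar(ga[tr$a_seq])))
  expect_true(all(tr$b_end <= nchar(gb[tr$b_seq])))
  # every planted feature class that was requested appears in the ledger
  expect_setequal(unique(tr$class),
                  c("cne", "exon", "repeat", "ncrna", "est_covered",
                    "duplicated"))
  # duplicated elements have exactly two genome-B copies
  dup <- tr[tr$class == "duplicated", ]
  expect_true(all(table(dup$element_id) == 2L))
  unlink(dir, recursive = TRUE)
})

test_that("planted pairs realize the configured identity", {
  # fixed geometry, identity 0.85: mean realized identity (measured by an
  # independent full-DP alignment of each planted pair) within 0.85 +/- 0.02
  ids <- c()
  for (sd in c(3L, 17L)) {
    cfg <- synthetic_config(seed = sd, n_cnes = 40L,
                            cne_len_range = c(200L, 200L),
                            cne_identity_range = c(0.85, 0.85),
                            n_decoy_exons = 0L, n_decoy_repeats = 0L,
                            n_decoy_ncrnas = 0L, n_est_covered = 0L,
                            n_duplicated = 0L, n_genes = 30L)
    sim <- generate_pair(cfg)
    tr <- sim$truth[sim$truth$class == "cne", ]
    m <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
    for (i in seq_len(nrow(tr))) {
      t <- tr[i, ]
      a <- toupper(substr(sim$genome_a[[t$a_seq]], t$a_start, t$a_end))
      b <- substr(sim$genome_b[[t$b_seq]], t$b_start, t$b_end)
      if (t$b_strand == "-") b <- cneforge:::revcomp(b)
      pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                          substitutionMatrix = m,
                                          gapOpening = 0, gapExtension = 3)
      ids <- c(ids, Biostrings::pid(pa) / 100)
    }
  }
  expect_lt(abs(mean(ids) - 0.85), 0.02)
})

test_that("a generator with nothing planted yields an alignment desert", {
  cfg <- synthetic_config(seed = 4L, n_chrom = 1L, chrom_len = 100000L,
                          n_cnes = 0L, n_decoy_exons = 0L,
                          n_decoy_repeats = 0L, n_decoy_ncrnas = 0L,
                          n_est_covered = 0L, n_duplicated = 0L,
                          n_genes = 20L)
  sim <- generate_pair(cfg)
  hits <- run_search(sim$genome_a, sim$genome_b, align_config())
  expect_equal(nrow(hits), 0L)
})

test_that("planting more than the genome can hold is an error", {
  cfg <- synthetic_config(seed = 1L, n_chrom = 1L, chrom_len = 5000L,
                          n_cnes = 100L, n_genes = 0L,
                          n_decoy_exons = 0L, n_decoy_repeats = 0L,
                          n_decoy_ncrnas = 0L, n_est_covered = 0L,
                          n_duplicated = 0L, n_background_repeats = 0L,
                          n_gap_runs = 0L)
  expect_error(generate_pair(cfg), "capacity")
})

test_that("recovery scoring applies the 50% overlap rule", {
  truth <- data.frame(
    element_id = c("el1", "el2"), class = "cne",
    a_seq = "chrA01", a_start = c(1000L, 5000L), a_end = c(1199L, 5199L),
    length = 200L, target_identity = 0.9, core_start = 1L, core_end = 28L,
    b_seq = "chrB01", b_start = 1L, b_end = 200L, b_strand = "+",
    copy = 1L, n_est_refs = 0L, expected_fate = "retained",
    expected_stage = "", stringsAsFactors = FALSE)
  exact <- data.frame(a_seq = "chrA01", a_start = c(1000L, 5000L),
                      a_end = c(1199L, 5199L), stringsAsFactors = FALSE)
  r <- score_recovery(truth, exact)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)

  none <- exact[0, ]
  r0 <- score_recovery(truth, none)
  expect_equal(r0$recall, 0)
  expect_true(is.na(r0$precision))

  # 40% overlap does not count as recovery (50% rule is strict)
  part <- data.frame(a_seq = "chrA01", a_start = 1000L, a_end = 1079L,
                     stringsAsFactors = FALSE)
  rp <- score_recovery(truth, part)
  expect_equal(rp$recall, 0)
  expect_equal(rp$precision, 0)
  # exactly half counts
  half <- data.frame(a_seq = "chrA01", a_start = 1000L, a_end = 1099L,
                     stringsAsFactors = FALSE)
  rh <- score_recovery(truth, half)
  expect_equal(rh$recall, 0.5)
})
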
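test_that("fragmentation tiles the sequence with the configured overlap", {
  cfg <- align_config()
  f1 <- fragment_genome(400000L, cfg)
  expect_equal(nrow(f1), 1L)
  expect_equal(c(f1$start, f1$end), c(1L, 400000L))

  f2 <- fragment_genome(1000000L, cfg)
  expect_equal(f2$start, c(1L, 499801L, 999601L))
  expect_equal(f2$end, c(500000L, 999800L, 1000000L))

  set.seed(5)
  for (len in sample(1000:2000000, 8)) {
    f <- fragment_genome(len, cfg)
    expect_equal(f$start[1], 1L)
    expect_equal(f$end[nrow(f)], len)
    if (nrow(f) > 1L) {
      # successive fragments overlap, so coverage has no holes
      expect_true(all(f$start[-1] <= f$end[-nrow(f)] + 1L))
      expect_equal(diff(f$start),
                   rep(cfg$fragment_len - cfg$fragment_overlap,
                       nrow(f) - 1L))
    }
  }
})

test_that("seed finding equals brute-force common-word enumeration", {
  brute_words <- function(a, b, w) {
    au <- toupper(a); bu <- toupper(b)
    ok_a <- function(i) {
      sub <- substr(a, i, i + w - 1L)
      sub == toupper(sub) && !grepl("[^ACGT]", sub)
    }
    out <- character(0)
    for (i in seq_len(nchar(a) - w + 1L)) {
      if (!ok_a(i)) next
      wa <- substr(au, i, i + w - 1L)
      for (j in seq_len(nchar(b) - w + 1L)) {
        sub <- substr(b, j, j + w - 1L)
        if (sub != toupper(sub) || grepl("[^ACGT]", sub)) next
        if (substr(bu, j, j + w - 1L) == wa) out <- c(out, paste(i, j))
      }
    }
    sort(out)
  }
  expand_runs <- function(runs, w) {
    if (nrow(runs) == 0L) return(character(0))
    out <- character(0)
    for (k in seq_len(nrow(runs))) {
      off <- 0:(runs$length[k] - w)
      out <- c(out, paste(runs$a_start[k] + off, runs$b_start[k] + off))
    }
    sort(out)
  }
  set.seed(11)
  w <- 8L
  for (i in 1:20) {
    block <- rand_dna(30)
    a <- paste0(rand_dna(60), block, rand_dna(60))
    b <- paste0(rand_dna(40), block, rand_dna(80))
    runs <- find_seeds(a, b, w)
    expect_identical(expand_runs(runs, w), brute_words(a, b, w))
  }
  # masked positions never seed
  am <- paste0(rand_dna(30), tolower(block <- rand_dna(40)), rand_dna(30))
  bm <- paste0(rand_dna(25), block, rand_dna(25))
  expect_equal(nrow(find_seeds(am, bm, 20L)), 0L)
  expect_identical(expand_runs(find_seeds(am, bm, 8L), 8L),
                   brute_words(am, bm, 8L))
})

test_that("a 19 bp shared run yields no seeds at word length 20", {
  set.seed(13)
  repeat {
    shared <- rand_dna(19)
    a <- paste0(rand_dna(50), shared, rand_dna(50))
    b <- paste0(rand_dna(50), shared, rand_dna(50))
    s19 <- find_seeds(a, b, 19L)
    if (nrow(s19) == 1L && s19$length[1] == 19L) break
    # resample on accidental longer context matches
  }
  expect_equal(nrow(find_seeds(a, b, 20L)), 0L)
  # identical 100-mers: a seed covering the full length
  x <- rand_dna(100)
  s <- find_seeds(x, x, 20L)
  expect_equal(nrow(s), 1L)
  expect_equal(s$length, 100L)
})

test_that("extension of identical sequences recovers the full match", {
  set.seed(17)
  x <- rand_dna(150)
  h <- extend_seed(data.frame(a_start = 50L, b_start = 50L, length = 20L),
                   x, x, align_config())
  expect_equal(h$score, 150L)
  expect_equal(h$aligned_cols, 150L)
  expect_equal(h$identities, 150L)
  expect_equal(h$pct_identity, 100)
  expect_equal(c(h$a_start, h$a_end), c(1L, 150L))
})

test_that("greedy scores equal the full-DP oracle on planted pairs", {
  set.seed(19)
  cfg <- align_config()
  for (i in 1:60) {
    p <- planted_pair(sample(80:140, 1), 0.9)
    hits <- align_pair(p$a, p$b, cfg)
    g <- if (nrow(hits)) max(hits$score) else 0
    o <- sw_oracle(p$a, p$b)
    expect_equal(g, o$score)
    if (nrow(hits)) {
      best <- hits[which.max(hits$score), ]
      # co-optimal alignments may differ at zero-scoring ends; the
      # recovered interval must still locate the planted block
      expect_lt(abs(best$a_start - o$a_start), 2 * cfg$x_drop)
      expect_lt(abs(best$a_end - o$a_end), 2 * cfg$x_drop)
    }
  }
})

test_that("hit scores are self-consistent with their gapped operations", {
  set.seed(23)
  cfg <- align_config()
  for (i in 1:20) {
    p <- planted_pair(120, 0.85)
    hits <- align_pair(p$a, p$b, cfg)
    for (k in seq_len(nrow(hits))) {
      expect_equal(cneforge:::rescore_hit(hits[k, ], p$a, p$b, cfg),
                   hits$score[k])
      expect_equal(nchar(hits$ops[k]), hits$aligned_cols[k])
      expect_lte(hits$identities[k], hits$aligned_cols[k])
    }
  }
})

test_that("calibration solves the Karlin-Altschul identity", {
  ka <- calibrate_ka(1L, -2L)
  # independent bisection on the same identity
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lo <- 1e-9; hi <- 5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_lt(abs(ka$lambda - (lo + hi) / 2), 1e-8)
  expect_lt(ka$residual, 1e-9)
  # doubling all scores halves lambda
  ka2 <- calibrate_ka(2L, -4L)
  expect_equal(ka2$lambda, ka$lambda / 2, tolerance = 1e-9)
  # E-value strictly decreasing in score
  ev <- ka_evalue(1:50, 1e5, 1e6, ka)
  expect_true(all(diff(ev) < 0))
  expect_error(calibrate_ka(3L, -1L), "negative")
})

test_that("genome search applies E-value and length retention rules", {
  set.seed(29)
  g99 <- exact_block_genomes(99L)
  g100 <- exact_block_genomes(100L)
  cfg <- align_config(fragment_len = 2000L, fragment_overlap = 200L)
  h99 <- run_search(g99$genome_a, g99$genome_b, cfg)
  h100 <- run_search(g100$genome_a, g100$genome_b, cfg)
  expect_equal(nrow(h99), 0L)   # 99 aligned columns: dropped
  expect_equal(nrow(h100), 1L)  # 100 aligned columns: kept
  expect_equal(h100$aligned_cols, 100L)
  expect_equal(h100$a_start, g100$a_start)
  expect_equal(h100$a_end, g100$a_end)
  expect_lte(h100$evalue, cfg$evalue_max)
})

test_that("elements inside the fragment overlap are reported once", {
  set.seed(31)
  block <- rand_dna(150)
  # place the block across the boundary zone of two overlapping fragments
  b_seq <- paste0(rand_dna(1850), block, rand_dna(500))
  a_seq <- paste0(rand_dna(300), block, rand_dna(300))
  cfg <- align_config(fragment_len = 2000L, fragment_overlap = 400L)
  hits <- run_search(c(chrA = a_seq), c(chrB = b_seq), cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$b_start, 1851L)
  # chance matches beyond the block may add a column or two
  expect_gte(hits$b_end, 2000L)
  expect_lte(hits$b_end, 2005L)
})

test_that("reverse-strand copies are found and reported with strand minus", {
  set.seed(37)
  block <- rand_dna(150)
  a_seq <- paste0(rand_dna(400), block, rand_dna(400))
  b_seq <- paste0(rand_dna(300), cneforge:::revcomp(block), rand_dna(300))
  cfg <- align_config(fragment_len = 5000L)
  hits <- run_search(c(chrA = a_seq), c(chrB = b_seq), cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$b_strand, "-")
  expect_equal(c(hits$a_start, hits$a_end), c(401L, 550L))
  expect_equal(c(hits$b_start, hits$b_end), c(301L, 450L))
})

test_that("no hit is reported from fully masked sequence", {
  set.seed(41)
  block <- rand_dna(200)
  a_seq <- paste0(rand_dna(200), tolower(block), rand_dna(200))
  b_seq <- paste0(rand_dna(150), block, rand_dna(150))
  hits <- run_search(c(chrA = a_seq), c(chrB = b_seq),
                     align_config(fragment_len = 2000L))
  expect_equal(nrow(hits), 0L)
})
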
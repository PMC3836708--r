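# Shared fixture builders. Everything is generated in code; no data files.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Scatter substitutions to a target identity, keeping an exact core so a
# word seed always exists (the structure the aligner is meant to exploit).
mutate_with_core <- function(s, identity, core_len = 24L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  cs <- sample.int(L - core_len + 1L, 1)
  core <- cs:(cs + core_len - 1L)
  elig <- setdiff(seq_len(L), core)
  pos <- sample(elig, min(round((1 - identity) * L), length(elig)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# A random sequence pair (each <= 300 bp) sharing one planted conserved
# block; returns the pair plus the block coordinates in each.
planted_pair <- function(block_len = 120L, identity = 0.9) {
  block <- rand_dna(block_len)
  fa1 <- rand_dna(sample(10:80, 1))
  fa2 <- rand_dna(sample(10:80, 1))
  fb1 <- rand_dna(sample(10:80, 1))
  fb2 <- rand_dna(sample(10:80, 1))
  a <- substr(paste0(fa1, block, fa2), 1, 300)
  b <- substr(paste0(fb1, mutate_with_core(block, identity), fb2), 1, 300)
  list(a = a, b = b,
       a_block = c(nchar(fa1) + 1L, nchar(fa1) + block_len),
       b_block = c(nchar(fb1) + 1L, nchar(fb1) + block_len))
}

# Independent full-DP local alignment oracle (linear gaps).
sw_oracle <- function(a, b, match = 1, mismatch = -2, gap = 3) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                mismatch = mismatch,
                                                baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(toupper(a), toupper(b),
                                      type = "local",
                                      substitutionMatrix = m,
                                      gapOpening = 0, gapExtension = gap)
  list(score = Biostrings::score(pa),
       a_start = Biostrings::start(Biostrings::pattern(pa)),
       a_end = Biostrings::end(Biostrings::pattern(pa)),
       b_start = Biostrings::start(Biostrings::subject(pa)),
       b_end = Biostrings::end(Biostrings::subject(pa)),
       identities = Biostrings::nmatch(pa))
}

# Two mini-genomes sharing exactly one identical block of `shared_len`,
# with deterministic mismatching flanks so the alignment has exactly
# `shared_len` columns.
exact_block_genomes <- function(shared_len) {
  block <- rand_dna(shared_len)
  a <- paste0(rand_dna(400), "GGGGGGGG", block, "AAAAAAAA", rand_dna(400))
  b <- paste0(rand_dna(300), "TTTTTTTT", block, "CCCCCCCC", rand_dna(300))
  list(genome_a = c(chrA = a), genome_b = c(chrB = b),
       a_start = 409L, a_end = 408L + shared_len)
}

# Fast alignment config for small fixtures (no length filter).
mini_align_cfg <- function(...) {
  align_config(min_hit_len = 1L, fragment_len = 10000L,
               fragment_overlap = 100L, ...)
}

# Small synthetic-run config for pipeline-level tests.
small_synth <- function(...) {
  modifyList(list(n_chrom = 2L, chrom_len = 120000L, n_cnes = 10L,
                  n_decoy_exons = 2L, n_decoy_repeats = 2L,
                  n_decoy_ncrnas = 2L, n_est_covered = 4L,
                  n_duplicated = 2L, n_genes = 30L,
                  n_background_repeats = 8L, n_gap_runs = 2L),
             list(...))
}
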
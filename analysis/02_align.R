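#!/usr/bin/env Rscript
# Stage 2: genome-vs-genome similarity search.
#
# Reads the two genomes emitted by stage 1 from disk, fragments genome B
# into 500 kb overlapping pieces, and runs the greedy seed-and-extend
# search (word 20, +1/-2, linear gaps -3, X-drop 50) on both strands.
# Hits are kept at E-value <= 0.001 and aligned length >= 100 bp, and
# written to results/hits.tsv.

suppressMessages(library(cneforge))

genome_a <- read_genome_fasta(file.path("results", "sim", "genomeA.fa"))
genome_b <- read_genome_fasta(file.path("results", "sim", "genomeB.fa"))

cfg <- align_config()
ka <- calibrate_ka(cfg$match, cfg$mismatch, cfg$base_freqs, cfg$ka_k)
cat(sprintf("scoring: +%d/%d, gaps %d/base, lambda = %.6f (residual %.1e), K = %.3f\n",
            cfg$match, cfg$mismatch, cfg$gap, ka$lambda, ka$residual, ka$k))

hits <- run_search(genome_a, genome_b, cfg)
write_tsv_file(hits[, setdiff(names(hits), "ops")],
               file.path("results", "hits.tsv"))

cat(sprintf("retained %d hits (E <= %g, length >= %d)\n", nrow(hits),
            cfg$evalue_max, cfg$min_hit_len))
cat(sprintf("  aligned length: %d-%d cols, identity %.1f-%.1f%%\n",
            min(hits$aligned_cols), max(hits$aligned_cols),
            min(hits$pct_identity), max(hits$pct_identity)))
cat(sprintf("  reverse-strand hits: %d\n", sum(hits$b_strand == "-")))
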
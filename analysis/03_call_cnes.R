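#!/usr/bin/env Rscript
# Stage 3: annotation filter cascade.
#
# Applies the discovery filters to the alignment hits, in order: exon
# overlap (>= 1 bp shared), repeat content (> 10 masked bp), structured
# RNA screen (any match at E <= 0.001), expressed-transcript screen
# (> 3 distinct matching references removes; 1-3 labels "weak"),
# multi-location removal. Writes the element records, the retained set as
# BED, the per-stage funnel, and recovery scores against the truth.

suppressMessages(library(cneforge))

sim_dir <- file.path("results", "sim")
genome_a <- read_genome_fasta(file.path(sim_dir, "genomeA.fa"))
models <- read_gene_models(file.path(sim_dir, "genes.gff3"))
repeats <- read_bed(file.path(sim_dir, "repeats.bed"))
ncrna <- read_genome_fasta(file.path(sim_dir, "ncrna.fa"))
ests <- read_genome_fasta(file.path(sim_dir, "ests.fa"))
hits <- read_tsv_file(file.path("results", "hits.tsv"))
truth <- read_tsv_file(file.path(sim_dir, "truth.tsv"))

# re-apply the repeat masking from the BED layer (idempotent when the
# FASTA is already soft-masked)
genome_a <- cneforge:::mask_genome(genome_a, repeats)

res <- run_cascade(hits, list(exons = models$exons, ncrna = ncrna,
                              ests = ests), genome_a)

write_tsv_file(res$elements, file.path("results", "elements.tsv"))
write_tsv_file(res$funnel, file.path("results", "funnel.tsv"))
retained <- res$retained
write_bed(data.frame(seq_id = retained$a_seq, start = retained$a_start,
                     end = retained$a_end, name = retained$element_id,
                     stringsAsFactors = FALSE),
          file.path("results", "cnes.bed"))

cat("funnel (stage, in -> out):\n")
for (i in seq_len(nrow(res$funnel))) {
  cat(sprintf("  %-15s %4d -> %4d\n", res$funnel$stage[i],
              res$funnel$n_in[i], res$funnel$n_out[i]))
}
cat(sprintf("retained %d elements: %d without transcription evidence, %d weak\n",
            nrow(retained), sum(retained$evidence_class == "none"),
            sum(retained$evidence_class == "weak")))

rec <- score_recovery(truth, retained)
cat(sprintf("recovery vs truth: recall %.3f, precision %.3f\n",
            rec$recall, rec$precision))
decoys <- decoy_stage_report(truth, res$elements)
cat(sprintf("decoys rejected at their designated stage: %d / %d\n",
            sum(decoys$ok), nrow(decoys)))
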
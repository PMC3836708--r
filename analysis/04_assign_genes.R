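#!/usr/bin/env Rscript
# Stage 4: nearest-TSS gene assignment and orthology cross-reference.
#
# Each retained element is assigned to the gene with the nearest
# transcription start site on its sequence (distance from the closest
# element edge; 0 when the TSS lies inside). Elements on gene-less
# sequences stay unassigned. The CNE-associated gene set is then
# cross-referenced through the orthology table against the partner
# species' CNE-associated genes.

suppressMessages(library(cneforge))

sim_dir <- file.path("results", "sim")
models <- read_gene_models(file.path(sim_dir, "genes.gff3"))
elements <- read_tsv_file(file.path("results", "elements.tsv"))
retained <- elements[elements$status == "retained", ]
orth <- read_tsv_file(file.path(sim_dir, "orthology.tsv"))
b_cne_genes <- readLines(file.path(sim_dir, "b_cne_genes.txt"))

asg <- assign_nearest_tss(retained, models$genes)
write_tsv_file(asg, file.path("results", "assignments.tsv"))

st <- per_gene_stats(asg)
cat(sprintf("%d of %d elements assigned (%d on gene-less sequences)\n",
            st$n_assigned, nrow(retained), st$n_unassigned))
cat(sprintf("%d associated genes, %.1f elements per gene\n",
            st$n_genes, st$mean_per_gene))
cat(sprintf("equidistant-TSS ties: %d\n", sum(asg$tie_flag)))

cne_genes <- unique(asg$gene_id[!is.na(asg$gene_id)])
writeLines(cne_genes, file.path("results", "cne_genes.txt"))
shared <- shared_cne_genes(cne_genes, b_cne_genes, orth)
write_tsv_file(shared$pairs, file.path("results", "shared_genes.tsv"))
cat(sprintf("shared CNE-gene set: %d genes here orthologous to %d partner genes\n",
            shared$n_a, shared$n_b))
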
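#!/usr/bin/env Rscript
# Stage 6: construct arithmetic for dissecting one element.
#
# Takes the longest retained element from stage 3 and builds the standard
# dissection series: three non-overlapping sub-elements, a central core,
# an internal deletion, an annealed-oligo fragment, and a trinucleotide
# mutagenesis series over a short 3' window; scans everything for the
# canonical Pbx/Hox site (tgatnnat). Writes a construct manifest and
# FASTA.

suppressMessages(library(cneforge))

genome_a <- read_genome_fasta(file.path("results", "sim", "genomeA.fa"))
elements <- read_tsv_file(file.path("results", "elements.tsv"))
retained <- elements[elements$status == "retained", ]
el <- retained[which.max(retained$length), ]
parent <- toupper(substr(genome_a[[el$a_seq]], el$a_start, el$a_end))
L <- nchar(parent)
cat(sprintf("dissecting %s (%s:%d-%d, %d bp)\n", el$element_id, el$a_seq,
            el$a_start, el$a_end, L))

third <- L %/% 3L
win <- 24L
win_start <- L - win + 1L
constructs <- rbind(
  make_subelement(parent, 1L, L, el$element_id),
  make_subelement(parent, 1L, third, el$element_id),
  make_subelement(parent, third + 1L, 2L * third, el$element_id),
  make_subelement(parent, 2L * third + 1L, L, el$element_id),
  make_subelement(parent, max(1L, round(L * 0.2)), round(L * 0.8),
                  el$element_id),
  make_deletion(parent, max(1L, round(L * 0.4)),
                min(L, round(L * 0.4) + 9L), el$element_id),
  make_oligo_construct(parent, win_start, L, el$element_id),
  triplet_mutant_series(substr(parent, win_start, L),
                        paste0(el$element_id, "_3p", win, "mer"))
)
constructs$construct_id <- sprintf("%s_c%02d", el$element_id,
                                   seq_len(nrow(constructs)))
write_tsv_file(constructs[, c("construct_id", "parent_id", "kind",
                              "start", "end", "length", "note")],
               file.path("results", "constructs.tsv"))
keep <- constructs$length > 0L
write_genome_fasta(stats::setNames(constructs$sequence[keep],
                                   constructs$construct_id[keep]),
                   file.path("results", "constructs.fa"))
cat(sprintf("wrote %d constructs (%d sub-elements, %d deletions, %d oligos, %d triplet mutants)\n",
            nrow(constructs), sum(constructs$kind == "subelement"),
            sum(constructs$kind == "deletion"),
            sum(constructs$kind == "oligo"),
            sum(constructs$kind == "triplet_mutant")))

sites <- scan_motif(parent, "tgatnnat", both_strands = TRUE)
cat(sprintf("Pbx/Hox (tgatnnat) sites in the element: %d\n", nrow(sites)))
if (nrow(sites) > 0) print(sites, row.names = FALSE)
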
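Package: cneforge
Title: Discovery and Dissection of Conserved Non-Coding Elements from
    Diverged Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide discovery of conserved non-coding elements (CNEs)
    from a pair of highly diverged genomes. Implements a greedy
    seed-and-extend local aligner with Karlin-Altschul E-value calibration,
    an annotation-based filter cascade (exon overlap, repeat content,
    structured-RNA and expressed-transcript screens, multi-locus removal),
    nearest-TSS gene assignment with orthology cross-referencing,
    protein-domain enrichment with log-odds statistics and
    Benjamini-Hochberg FDR control, and construct arithmetic for dissecting
    individual elements into functional sub-sequences. Ships a synthetic
    genome-pair generator with planted truth so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
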
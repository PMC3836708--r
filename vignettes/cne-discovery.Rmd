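---
title: "Discovering conserved non-coding elements from a diverged genome pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved non-coding elements from a diverged genome pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Embryonic patterning genes are flanked by conserved non-coding elements
(CNEs): stretches of DNA kept recognisably similar between species whose
neutral sequence has long since diverged beyond alignment. When two
genomes are far enough apart that chance alignments essentially vanish —
the regime of the two *Ciona* sea-squirt species, whose divergence
exceeds that of human and chicken — any non-coding region that still
aligns is a candidate cis-regulatory module. `cneforge` implements the
full discovery procedure for such a genome pair: a BLAST-style
seed-and-extend similarity search, an annotation filter cascade that
strips everything with a mundane explanation (exons, repeats, structural
RNAs, transcribed fragments, duplicated sequence), nearest-TSS gene
assignment, protein-domain enrichment over the associated genes, and the
construct arithmetic used to dissect single elements into functional
sub-sequences. Because the real assemblies and annotation releases are
large and external, the package also ships a synthetic genome-pair
generator with a planted, fully known truth set; every stage of the
pipeline is exercised and scored against that truth.

## The search stage

`run_search()` fragments genome B into 500 kb pieces overlapping by
200 bp and aligns every fragment — forward and reverse complement —
against the plus strand of genome A.

Seeding is by maximal exact matches of at least `word_len = 20`
consecutive bases, found by a hash join over 2-bit-encoded words
(`src/seedextend.cpp`). Soft-masking semantics apply: lowercase
(repeat-masked) and `N` positions never participate in a seed but are
scored normally during extension.

Extension is greedy and gapped: from each seed end, a banded dynamic
program with match +1, mismatch −2 and linear gap cost −3/base advances
until the running score falls more than `x_drop` below its running
maximum, then trims back to the maximal-scoring cell. Two defaults
deserve comment:

* **Gap costs are linear.** In the megablast regime for reward/penalty
  +1/−2, gap costs this small behave non-affinely; a single per-base cost
  of 3 keeps the dynamic program simple and the scoring self-consistent
  (every reported hit's score re-derives exactly from its operation
  string; this is a tested invariant).
* **X-drop is 50 raw score units.** At the bottom of the identity range
  this class of elements occupies (~71%), the per-column score drift is
  only `3q − 2 ≈ 0.13`, and a drawdown of X occurs with probability about
  `e^{−θX}` with θ ≈ 0.13 per excursion. An X-drop of 20 therefore
  truncates genuinely conserved low-identity elements routinely, whereas
  50 — equivalent to the ~100-bit final-extension threshold used by the
  BLAST family at this scoring — makes truncation negligible without
  admitting any background (background needs score ≥ ~25 to pass the
  E-value gate regardless of how far an extension wanders). Both are
  configurable via `align_config()`.

Statistical significance uses the Karlin–Altschul theory:
`E = K·m·n·e^{−λS}`, with λ solved from
`Σ pᵢpⱼ e^{λ sᵢⱼ} = 1` by `stats::uniroot` to a residual below 1e−12
(`calibrate_ka()`), m and n the raw fragment/genome lengths (edge
corrections are second-order at these scales), and K = 0.621, the
published ungapped constant for +1/−2 with uniform composition. Hits are
kept at `E ≤ 0.001`, then at aligned length ≥ 100 columns. Duplicate
hits created by the fragment overlap are removed by coordinate identity
and containment; hits to *distinct* partner loci are deliberately kept
apart so the multi-location filter can see them.

## The filter cascade

`run_cascade()` first merges hits whose intervals overlap on **both**
genomes into single elements (union coordinates) — seed multiplicity and
fragment overlap otherwise double-count one biological element — then
applies, in fixed order:

1. `exon_overlap` — any element sharing ≥ 1 bp with an annotated exon is
   removed. The strictest reading of "overlapping exons"; the threshold
   is configurable, and transcript-level footprints can be screened by
   passing transcript intervals as the exon table.
2. `repeats` — more than 10 masked bases removes the element; exactly 10
   is retained. `N` counts as masked by default (assembly gaps are
   unalignable; `assume_n_masked = FALSE` restricts to lowercase).
3. `ncrna` — any alignment to a structured-RNA reference at E ≤ 0.001
   (same scoring as the main search) removes the element.
4. `est` — matches are counted as *distinct* expressed-sequence
   references with at least one alignment at E ≤ 0.001 ("three matches
   to expressed transcripts" reads as a transcript count, not an
   alignment-block count). More than 3 removes; 1–3 retains with
   evidence class `weak`; 0 retains with class `none`.
5. `multi_location` — an element whose genome-A interval participates in
   retained alignments to two or more mutually non-overlapping genome-B
   loci is removed (duplicated sequence is out of scope for single-copy
   element analysis).

Rejection is attributed to the *first* failing stage only, matching the
sequential narrative of the protocol, and the funnel report (stage,
in-count, out-count) is emitted with every run; stage-consistency and
monotonicity of the funnel are tested invariants, as is idempotency of
each filter on its own survivors.

## Gene association and enrichment

`assign_nearest_tss()` measures the distance from the closest element
edge to each gene's transcription start site (strand-aware: gene start
on +, gene end on −), zero when the TSS falls inside the element.
Edge-to-TSS rather than midpoint-to-TSS is the stricter reading of
"nearest TSS" and the easier invariant to verify exhaustively.
Equidistant TSSs are broken by the lexicographically smallest gene id
with a `tie_flag` — the protocol does not state a tie rule, so the
package picks a deterministic, documented one. Elements on sequences
without genes stay unassigned; proximity assignment knowingly
over-estimates the associated gene set (enhancers can act at a
distance), and no enhancer–target inference is attempted.

`enrich_all()` rolls every protein domain up to its top-level parent
(fixpoint of parent lookup, cycles are an error), drops domains present
in fewer than 10 genes, and for each surviving domain forms the 2×2
table of CNE-associated genes versus the remaining background genes.
The statistic is the natural-log sample odds ratio — the printed
log-odds values this style of analysis reports (e.g. 2.03 for
homeodomain-like factors) are consistent with ln, not log₂ — with the
Haldane–Anscombe +0.5 applied to all cells only when a zero cell occurs,
so non-degenerate tables are not biased. The p-value is the two-sided
Fisher exact probability ("log-odds ratio test" under-determines the
test; Fisher is exact and dependency-free, and a Wald alternative is
available via `method = "wald"` for comparison). p-values are reported
exactly rather than floored at a machine-epsilon print threshold.
Multiplicity is controlled by Benjamini–Hochberg step-up q-values
(`bh_correct()`, delegating to `stats::p.adjust`; the test suite checks
the staircase against a hand computation).

## Element dissection

`scan_motif()` matches IUPAC-degenerate patterns (with `n` = any base)
case-insensitively, on the given strand by default — the canonical
Pbx/Hox site `tgatnnat` is the motivating pattern — with
`both_strands = TRUE` reporting reverse-complement matches in forward
coordinates. `make_subelement()`, `make_deletion()` and
`make_oligo_construct()` implement inclusive-coordinate construct
arithmetic (a sub-element spanning nt 97–384 of a 457 nt element is
288 nt; deleting nt 71–79 from a 108 nt element leaves 99 nt). One
convention note: a fragment spanning nt 71–108 is 38 nt by inclusive
arithmetic even though such fragments are sometimes labelled "37 bp" in
figure legends; the package consistently uses the inclusive convention.
`triplet_mutant_series()` produces one variant per consecutive
non-overlapping triplet. Published mutagenesis figures typically show
mutated triplets only in bold without giving the replacement bases, so
the package uses a deterministic, maximally disruptive scheme: each base
is replaced by its complement (A↔T, C↔G), not reversed.

## The synthetic genome pair

`generate_pair()` emulates the discovery setting, not any particular
assembly:

* **Backgrounds are independent** random uniform-composition sequence,
  one RNG stream from the single seed, all sampling orders fixed. This
  is the limiting case of the diverged-beyond-alignment regime; with the
  default thresholds the expected number of chance ≥ 20-mer seeds
  between two 1 Mb backgrounds is below one, and no background hit can
  reach the E-value score threshold (~25).
* **Planted elements** get lengths from a shifted exponential (minimum
  94 bp plus an exponential tail matching the observed 181.6 bp mean,
  truncated at 1,883 bp) and identities uniform on 0.71–0.97 — the
  marginal distributions this class of element exhibits; the joint
  distribution is unreported, so the marginals are sampled independently.
  Two structural choices make planted elements behave like real
  conserved elements rather than i.i.d.-noise blocks:
  * a 28 bp perfectly conserved central core (real CNEs contain deeply
    constrained cores; it also guarantees a seed exists), and
  * stratified substitution placement (one substitution per equal-width
    stratum), which pins local identity near the element-wide target.
    Under i.i.d. placement, elements near the +1/−2 break-even identity
    of 2/3 develop long sub-break-even windows that *no* correct local
    aligner will cross — the full dynamic program refuses them just as
    the greedy one does — fragmenting what is meant to be one element.
  Up to two short (1–2 bp) indels per copy are added outside the core.
* **Discoverability conditioning.** The observed length/identity
  marginals describe *discovered* elements, so the sampler conditions
  each (length, identity) pair on being discoverable at the default
  thresholds: substitution load must leave a whole-element score of at
  least 55 (the E-value score threshold ~25 plus indel and end-trim
  slack, so each element half stays net-positive) and length at least
  125 bp (the 100-column retention rule plus the same slack). An
  unconditioned sampler would plant, e.g., 94 bp at 71% identity —
  expected score 12 — which could never have appeared in a discovered
  set; planting it and scoring its loss as a recall failure would
  measure the generator, not the pipeline. A consequence is that planted
  low-identity elements are long (at 71%, at least ~420 bp), and the
  realized mean planted length (~270 bp) sits above the target mean.
* **Decoys** are conserved exactly like CNEs and are rejected only by
  annotation: exon decoys carry a gene whose exon coincides with the
  element; repeat decoys contain a 20 bp soft-masked stretch placed
  clear of the core (masked in the FASTA and recorded in the BED layer);
  RNA decoys appear verbatim in the ncRNA reference set; transcript
  decoys get 2 (retained, class `weak`) or 5 (removed) matching
  expressed-sequence references cut from their own sequence; duplicated
  decoys are copied to two distinct genome-B loci. About 30% of all
  genome-B copies are inserted reverse-complemented to exercise the
  minus-strand search path.
* **Gene layer and enrichment.** Background gene models (2 terminal
  exons each) are placed first and reserve their footprints, so planted
  CNEs are intergenic by construction. The gene→domain table plants the
  target domain ("homeodomain-like") among CNE-adjacent genes at a
  configurable log-odds ratio (default 1.5) against a 12% baseline, via
  two child identifiers so the hierarchy roll-up is exercised, plus 12
  unenriched domains; a many-to-many orthology table to a virtual
  partner species supports the shared-gene report.

What the generator does **not** model — and hence what passing tests do
not show about real data: non-uniform base composition and isochores
(the Karlin–Altschul K would need recomputation), clustered or nested
real repeat families, genuine transcription (EST evidence is planted,
not expressed), phylogeny beyond a two-taxon pair, context-dependent
mutation, and real InterPro hierarchies (the roll-up here is two levels
deep). Recovery scores on synthetic data measure the pipeline's
correctness under its stated model, not its sensitivity on real
assemblies.

## Scoring a run

`score_recovery()` counts a planted CNE as recovered when a retained
element overlaps at least 50% of its genome-A interval; precision treats
a call as supported when it covers at least half of any planted element
whose expected fate is retention (CNEs and the weakly transcribed
decoys, which the cascade is *supposed* to keep).
`decoy_stage_report()` verifies each decoy was rejected exactly at its
designated stage, using any-overlap rather than the 50% rule — a decoy
truncated to a fragment by low identity is still attributed to the stage
that rejected the fragment.

## Problem sizes and numerical choices

The default synthetic run uses two genomes of 2 × 500 kb with 40 planted
CNEs and 34 decoys; it completes in a few seconds and is the
configuration used by the end-to-end tests and the acceptance script.
The aligner's oracle-equivalence suite uses 500 random pairs of ≤ 300 bp
with one planted 90%-identity block each, scored against
`Biostrings::pairwiseAlignment` (local, identical scoring) — the full
dynamic program serves strictly as an independent oracle, never as the
implementation. Enrichment recovery uses 1,000 genes over 20 seeds;
null-FDR calibration uses 40 null runs of 400 genes. Co-optimal local
alignments are a real degeneracy: zero-scoring end segments can be
included or excluded at equal score, so the test contract is exact score
equality plus bounded coordinate deviation, not byte-identical
alignments. Root finding, E-values and log-odds are double precision
throughout; determinism is per-seed (`run_all()` reruns byte-identically
under a fixed config).

## Known limitations

Single-pass greedy extension can in principle miss an optimum whose path
dips more than X below the running maximum inside a genuinely conserved
element; at the default X this requires an event of probability ~e^{−6}
per excursion even at 71% identity. The per-element RNA/EST screens
rebuild the reference index per element (acceptable at these scales; a
persistent index would be the first optimisation for genome-scale
reference sets). The multi-location filter clusters partner loci by
simple interval overlap, so tandem near-adjacent duplications separated
by less than one element length count as one locus. Proximity-based
gene assignment is a deliberate over-estimate, as discussed above.
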
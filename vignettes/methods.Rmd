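---
title: "Detecting intergenic trans-splicing events: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intergenic trans-splicing events: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transchimera)
```

## The detection model

An intergenic trans-splicing event joins the 3′ boundary of a donor gene's
exon to the 5′ boundary of an acceptor gene's exon, producing a mature
chimeric mRNA. The caller treats this as a sequence-evidence problem: a
junction is real only if RNA-seq reads exist that (a) cannot be explained by
the genome or by canonical cis-splicing, (b) align across the hypothesized
fusion boundary with substantial anchors on both sides, and (c) are
corroborated by an independent read pair whose mates fall on the two sides
of the boundary in a fragment-consistent way. The universe of hypotheses is
the *fusion junction library*: for every ordered pair of distinct genes,
every donor-exon 3′ boundary is fused to every acceptor-exon 5′ boundary.

Assumptions worth making explicit:

* **Annotated boundaries only.** Junctions are hypothesized at annotated
  exon boundaries; a trans junction at an unannotated site is invisible.
  This mirrors the library-based design of the detection strategy and keeps
  the hypothesis space quadratic in gene count rather than genome length.
* **Mature-mRNA model.** Junction arms and bridge templates are drawn from
  spliced transcripts: a junction-spanning read from a chimera that retains
  its parents' cis introns would not be matched. Arms therefore extend
  across upstream/downstream cis junctions of the same transcript when an
  exon is shorter than the arm length.
* **Ungapped read matching.** Both the cis filter and junction alignment
  use end-to-end, ungapped matching with a small mismatch budget. This
  imitates the short-read aligner stages the approach is modelled on and is
  deliberately conservative: reads with indels are neither cis-explained
  nor junction evidence, so they drop out of both sides of the comparison.

## Evidence criteria and their parameters

The thresholds live in `evidence_thresholds()`:

| parameter | default | units | role |
|---|---|---|---|
| `min_overhang` | 20 | bp | minimum anchor on *each* arm of a spanning read (criterion ii) |
| `min_nonredundant_reads` | 2 | reads | distinct spanning read sequences required (criterion i) |
| `require_perfect` | TRUE | — | one spanning read must be mismatch-free (criterion i) |
| `min_bridge_pairs` | 1 | pairs | bridging pairs required (criterion iii) |
| `max_mismatches` | 2 | bases | mismatch budget of the ungapped matcher |
| `neighbor_max_gap` | Inf | bp | how far apart same-strand genes with no gene between them still count as neighbours (criterion iv) |
| `max_insert` | 1000 | bp | largest fragment accepted when validating a bridge |

Design decisions behind them:

* **Non-redundancy by sequence.** Distinct read *sequences* are counted
  (after orienting every hit to the junction strand), which collapses PCR
  duplicates and opposite-orientation copies of the same molecule. Counting
  distinct offsets instead was rejected: duplicates share offsets anyway,
  and sequence identity is the stronger deduplication.
* **Ambiguity is disqualifying.** A read whose best-mismatch hits tie
  across more than one distinct (donor gene, acceptor gene) pair —
  including ties hidden by deduplicated identical fused sequences —
  contributes to no junction. Multi-mapping junction evidence is the main
  false-positive channel for paralogue-rich genomes, and discarding it is
  the conservative choice.
* **A spanning read's own mate may bridge.** Criterion (iii) accepts a pair
  in which one mate spans the junction itself (with both anchors) and the
  other sits entirely on one side. Requiring a second, fully independent
  pair is available by raising `min_bridge_pairs`.
* **Neighbour gap unlimited by default.** Criterion (iv) removes
  same-strand pairs whose spans overlap or have no annotated gene strictly
  between them, at *any* distance. Known same-strand trans-spliced loci of
  the mod(mdg4) kind are excluded by exactly this rule even when donor and
  acceptor are hundreds of kb apart, so the default reproduces that
  behaviour; `neighbor_max_gap` restores distance-bounded behaviour where
  wanted.
* **Arm length.** `arm_length` defaults to
  `max(read_length − min_overhang, 80)`: any read fully embedded in a fused
  sequence with full-length arms can then satisfy the two-arm rule, so arm
  length never silently caps sensitivity.
* **Isoform handling.** The library is built on one representative
  transcript per gene (longest spliced length, ties to the
  lexicographically smallest id) — a deterministic choice that bounds
  library size; `isoform_mode = "all"` enumerates every transcript for
  small genomes. Whether the original strategy enumerated all isoforms is
  not documented; both modes are provided.

## Read QC

`qc_params()` encodes a three-step filter: (1) at least 60% of bases at
Q ≥ 20, evaluated on the untrimmed read (the rule is stated first in the
protocol it follows, hence applied before trimming); (2) contiguous
low-quality (< Q20) runs trimmed from both ends; (3) more than one `N`
after trimming rejects the read. `min_length_after_trim = 20` bp is an
addition (the protocol is silent): anything shorter could never satisfy the
20 bp two-arm rule downstream. A pair is dropped when either mate fails,
because bridging logic needs both mates; `keep_singletons = TRUE` retains
the surviving mate for other uses.

## The matcher

The cis filter and junction aligner share one primitive: end-to-end
ungapped Hamming matching of a read (either orientation) against an indexed
sequence set. Seed-and-verify with `max_mismatches + 1` disjoint k-mer
seeds (k = `min_overhang`) guarantees by pigeonhole that every placement
within budget is found; reads too short to carry that many disjoint seeds
fall back to a full scan, so the guarantee holds at every length. Reads
shorter than k are treated as cis-explained — they are uninformative at the
evidence thresholds anyway. The inner loops are C++ (Rcpp); tests verify
the matcher against a brute-force all-offsets scan and the protein aligner
against an exhaustive dynamic-programming oracle.

## Annotation conventions

* **Types.** DfChr (different sequences), DfStr (same sequence, different
  strands), else SmDA/SmAD with "upstream" defined along the shared
  transcription direction — purely genomic left/right would misclassify
  minus-strand pairs.
* **Distance** is the gap between gene *spans* (0 when they overlap), not
  junction-to-junction. For DfChr events between two unplaced scaffolds the
  putative distance orients each scaffold so the donor transcribes toward
  its 3′ edge and the acceptor away from its 5′ edge and sums the two
  edge distances; between placed, named chromosomes no convention is
  defined and the distance is reported missing rather than guessed.
  Scaffold-ness is decided by a configurable name pattern
  (`^(scaffold|scf|contig|ctg)`).
* **Chimeric ORFs.** ATG codons starting before the junction are scanned in
  all three frames and translated to the first stop; an ORF qualifies with
  ≥ 10 complete codons on each side, the junction-straddling codon counting
  to *neither* side (the strictest reading of the two-side rule). Longest
  peptide wins, ties to the most 5′ start.
* **Frames.** In-frame flags compare codon phase at the junction in spliced
  coordinates, so exons of non-multiple-of-3 length are handled; genes
  without annotated CDS yield NA and are excluded from frame statistics.
* **Cis sharing.** The donor arm is "shared" when any cis intron of the
  donor gene uses the event's boundary as a splice donor (acceptor
  analogous), across all annotated transcripts.

## Profile statistics

Quartiles use linear interpolation (R's type 7) — the convention is not
specified by the box-plot figures this mirrors, so the R default is used
and documented. Whiskers extend to the most extreme observations within
1.5 IQR. Report percentages round half away from zero (77.93-style
printing), implemented in `proportion_pct()`; base R's round-half-even
would print 0.125 as 0.12. The frame-bias test is a one-degree-of-freedom
χ² goodness-of-fit of the in-frame count against p = 1/3 — the null of a
random frame offset between two CDSs; the test itself is named in the
source analysis but the null is not, so the 1/3 assumption is documented
here. An exact binomial tail is the test-suite oracle for its small-n
behaviour. Splice-site base matrices use windows of 5 exonic and 10
intronic positions by default (configurable; the original figure's window
is unstated).

## Homology screens

`local_align_protein()` is Smith–Waterman under BLOSUM62 with affine gaps
(open 11, extend 1 — the BLASTP defaults), delegated to
`Biostrings::pairwiseAlignment()`; the E-value uses gapped Karlin–Altschul
constants (λ = 0.267, K = 0.041) with search space m·n. Parity with BLASTP
is therefore approximate ("BLAST-like"); exact parity is available by
importing real BLAST tabular output through `read_blast_tab()`. Two
further conventions the source methods leave open: *coverage* is
query-side, the query being the trans-spliced segment or protein (the
screens iterate over trans products); *identity* uses alignment columns
including gaps as denominator (the pident convention). The paralogue screen
reuses the 1e-5 / 60% / 30% thresholds of the conserved-event screen, which
the source reports without printing thresholds. The mod(mdg4) rule consumes
HMMER domtblout files — running hmmsearch itself is out of scope — and
requires both BTB and FLYWCH hits at full-sequence *and* per-domain
E ≤ 1e-5 with the 5′-most BTB envelope upstream of the 5′-most FLYWCH
envelope.

## The synthetic-data generator

`simulation_config()` defaults define the study conditions used throughout
the tests: 2 chromosomes (60 kb) + 2 unplaced scaffolds (25 kb), 18 genes
of 4–7 exons (90–240 bp exons, 60–400 bp GT..AG introns, GC 0.45), one
planted event of each type plus two readthrough decoys, 100 bp paired-end
reads at 50× per transcript with Normal(300, 30) fragments, 0.2% base
errors, and half of an affected locus's expression given to its chimera.
Every spliced transcript is a complete CDS (ATG, stop-free codons, terminal
stop), so CDS phase at any spliced coordinate is the coordinate mod 3 and
frame engineering in fixtures is exact.

Placement realizes each type by construction: SmDA/SmAD events occupy three
consecutive gene slots so an annotated spacer gene always lies between
donor and acceptor — only then can criterion (iv) be isolated as the sole
difference between real same-strand events and the decoys, which occupy two
*adjacent* same-strand slots and are fused with the same junction grammar.
DfChr events go to the two scaffolds so the putative-distance convention is
exercised.

One geometric subtlety drove a generator parameter: if a chimeric
transcript is about as short as the sequenced fragments, read pairs pin to
the template ends and positions near an interior junction are never covered
— junction-spanning reads become impossible regardless of coverage.
`min_segment_length` (default 320 bp ≈ insert mean + 3 SD per side) makes
the generator pick junction exon indices whose donor and acceptor segments
both reach that spliced length where the gene structure allows, so planted
events are detectable for the geometric reason a real expressed chimera
would be, not by luck of the draw.

What the generator does *not* emulate — and what green tests therefore do
not show about real data: reverse-transcription template switching (an
experimental artifact handled at the bench, not computationally),
inter-allelic events, indels and adapter contamination in reads, intron
retention, expression heterogeneity beyond one coverage knob, and
paralogue-rich gene families (the toy genes are random sequence, so the
ambiguity rule is exercised only by constructed duplications in the test
suite). Quality strings are two-valued (a constant Q from the error rate,
plus Q2 tails on 10% of reads to exercise trimming), not learned profiles.

Determinism: `generate_genome_and_genes()` seeds R's RNG with
`config$seed`; `simulate_read_pairs()` derives its stream from
`config$seed + 1000003` so the two stages are independently reproducible;
fixed seeds give byte-identical FASTA/GFF3/FASTQ output.

## Numerical and degenerate-input choices

* The 60% QC rule is inclusive (exactly 60% passes) with a 1e-9 slack
  against floating-point drift; base-frequency columns must sum to 1 within
  1e-9.
* `box_stats()` on a single value returns that value for all quartiles;
  empty input is an error, as are zero denominators in proportions and
  n = 0 in the frame test.
* Junctions whose arms fall below `min_overhang` (first/last short exons)
  or carry > 20% N are dropped at library build; splice-site windows that
  run off a contig skip that event with a warning.
* Duplicate fused sequences are collapsed to one library row; every
  contributing junction's provenance is retained and widens the ambiguity
  test for reads hitting that row.
* Ties: representative transcript (longest spliced length → smallest id),
  ORF choice (longest peptide → most 5′ start).

## Problem sizes

The test suite and the acceptance script run the default synthetic genome
(18 genes, ~170 kb, ≈ 4,900 read pairs, ≈ 10,000-junction library), 100
randomized matcher-oracle instances, 20 protein-aligner oracle pairs of
≤ 30 aa, and a 3-point threshold-monotonicity grid per threshold. These
sizes were chosen so every stage's behaviour is exercised with comfortable
evidence depth (≈ 15–25 spanning reads per planted junction) while a full
run stays interactive.

## Known limitations

* Novel (unannotated) cis junctions are not modelled in the cis filter, so
  a read from an unannotated cis isoform can surface as a candidate; the
  evidence criteria (perfect spanning reads on both arms of a *between-gene*
  junction plus a bridge) are what keeps such reads from becoming events.
* Events between alleles of one gene are indistinguishable from
  between-paralogue events without phased variants; both are outside the
  caller's scope.
* The built-in aligner's E-values are approximate relative to BLASTP;
  screens at the published thresholds should be near-identical for strong
  hits but may differ at the margin — the BLAST tabular reader is the
  exact-parity route.
* Trans-genes annotated across scaffold joins, and FASTQ Phred+64 legacy
  encodings, are unsupported.
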
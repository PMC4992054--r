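---
title: "Annotating transcript boundaries from targeted RACE long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating transcript boundaries from targeted RACE long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Long non-coding RNAs are typically expressed at low levels, and their
annotated gene models often lack the hallmarks of real transcript ends:
no CAGE tag at the 5' terminus, no polyadenylation evidence at the 3'
terminus. Untargeted RNA-seq cannot fix this — at realistic sequencing
depths, lowly expressed transcripts receive too few reads to resolve
their boundaries. Rapid amplification of cDNA ends (RACE) solves the
sensitivity problem by PCR-amplifying from a gene-specific primer toward
the unknown transcript terminus; coupling RACE to long-read sequencing
turns each amplification into hundreds of reads that each span from the
primer to a candidate transcript end.

`racekit` implements the complete computational side of such an
experiment: choosing targets, designing specificity-masked outer and
nested primers, preprocessing the long reads, accounting for on-target
enrichment, collapsing reads into transcript models, and characterizing
the novel 5'/3' boundaries (clustering, novelty, evidence support,
polyA-site inference, locus extension and merging). A deterministic
simulator generates complete synthetic experiments with a truth ledger,
so every stage is testable without any external data.

## Workflow and models

### Target selection

Expression is summarized as RPKM (reads per kilobase of merged exonic
length per million mapped reads), `1e9 * reads / (exonic_length *
total_mapped)`. A transcript is a candidate when its RPKM exceeds 5 in
at least one sample (strictly greater) and no CAGE/PET tag lies within
50 bp of its annotated TSS on the same strand — the targets are
expressed genes whose 5' ends are *not* already well supported.
Candidates are ranked by mean RPKM and the list truncated to the panel
size (398 by default).

### Specificity masking

A primer placed in sequence shared between loci amplifies off-target
products. Before primer enumeration, every region of the candidate's
spliced sequence with more than 80% identity over at least 50 aligned
nucleotides to a transcript of a *different* locus is hard-masked
(`N`). The published protocol used a heuristic aligner for this step
without stating its parameters, so the package defines a concrete,
reproducible criterion: alignments are seeded on shared 11-mers and
extended ungapped in both directions with an X-drop rule (match +1,
mismatch −3, drop 20), and identity is computed over the extended span.
Only sense-to-sense similarity is considered: antisense similarity does
not interfere with gene-specific priming of first-strand cDNA. The
criterion is deliberately conservative in one respect — a similar region
containing no exact 11-mer (mismatches spaced closer than every 11 bases)
produces no seed and is not masked; such regions are also poor templates
for mispriming.

### Primer design

All windows of 23–27 nt fully inside unmasked sequence are scored.
Melting temperature uses unified nearest-neighbour thermodynamics with
the entropic salt correction `0.368 (n−1) ln[Na+]` at 50 mM monovalent
cation and 200 nM oligo (the priming concentration of the protocol);
the implementation reproduces an independent published-table oracle
within 0.05 °C. Windows pass with Tm in [68, 72] °C and GC in [50, 70]%,
and are scored by weighted distance to the optima (25 nt, 70 °C, 60%
GC; the GC deviation is weighted ×25 so that a 4% GC deviation costs
about as much as 1 °C). A 3' RACE primer is the sense window itself; a
5' RACE primer is its reverse complement. The outer primer is the
best-scoring window whose predicted product (annealing site to the
targeted transcript end) falls within the platform span window —
300–3,000 nt by default, chosen for a ~600 bp read-length platform; the
nested primer is the eligible window closest downstream (toward the
targeted end) of the outer one and may be absent. Directions are
designed independently; hairpin/self-dimer screening is out of scope.

### Read preprocessing

Three rules, applied in order and idempotent as a composition:

1. **Adapters.** The best occurrence of any supplied adapter at either
   read end is removed together with all bases distal to it. Occurrences
   are found by a semi-global edit-distance alignment (C++ kernel)
   allowing partial overlap off the read end, at most 10% errors of the
   aligned length and at least 10 aligned bases; internal occurrences
   are honoured only when anchored within the terminal 60% of the read.
2. **3' quality.** While the mean phred score of the last three bases is
   not greater than 20 (Sanger scale), the last base is dropped; reads
   shorter than the window are left alone.
3. **Length.** Reads shorter than 100 nt are discarded (exactly 100 is
   kept).

### Alignment-derived features

Only uniquely mapping reads enter any downstream analysis: a read is
dropped when it has secondary/supplementary records, an NH tag above 1,
or mapping quality below the configurable floor (0 by default, since
different aligners report uniqueness differently). Inter-block gaps
become introns when larger than 20 nt, at least 30 nt, and flanked by a
canonical dinucleotide pair (GT–AG, GC–AG, AT–AC) on either genomic
strand; the junction strand follows the motif, not the read flag,
because RACE libraries are unstranded at the read level. Junction
support is quantified as the base-2 Shannon entropy of the distinct
read alignment-start offsets relative to the donor — RACE products are
anchored at their primer, so stacks of identically placed reads carry
little independent evidence; the default filter requires 3 bits.
Comparative statistics restrict junction sets to target locus spans
±5 kb and, to compensate for depth differences, keep only the top
quartile by read count (ties broken by coordinate for determinism).

### Boundary characterization

Because a 5' RACE product is anchored at its primer on the 3' side (and
vice versa), each collapsed transcript model is first assigned its most
probable originating RACE direction: it is a 5' product if it extends
its locus further 5' or its 3' end lies within 50 bp of a 5' primer
footprint on the opposite strand; the 3' rule is symmetric with the
primer on the same strand; models firing both rules count in both
analyses. TSS positions of 5' products are clustered by single linkage
(same strand, distance < 51 bp merges; < 151 bp for TTSs, reflecting the
leakier nature of termination), with the 5'-most member as
representative — a conservative choice for extension calls. A cluster
is novel when farther than 100 bp from every annotated site of the
targeted transcripts, and supported when a CAGE tag (TSS, ±50 bp) or
polyA-site tag (TTS, ±100 bp) lies on the same strand within the
window; all windows are inclusive at the boundary.

PolyA sites are inferred from the terminal soft clips of mapped reads: a
clip whose outward-facing sequence begins (within 2 nt of the clip
boundary, to stop internal A-rich clip sequence from masquerading as a
tail) with a run longer than 20 nt that is at least 90% A (right clips;
site on `+` at the last aligned base) or T (left clips; site on `-` at
the first aligned base) calls a site; identical sites are merged with
support summed, with no windowed merging by default.

Locus extensions are signed on the transcription axis — negative for a
novel TSS upstream of the annotated 5' extreme, positive for a novel
TTS downstream of the 3' extreme — and a locus end is "extending" only
when strictly beyond the annotated extreme. Loci bridged by a new
transcript with same-strand exonic overlap to two or more of them are
merged transitively (union–find); merging never increases the locus
count and conserves transcripts.

Manual curation of read alignments into transcript models is replaced by
an automated collapse: uniquely mapped spliced reads sharing an
identical intron chain become one model spanning the widest member;
single-exon reads collapse by overlap and remain unstranded, which
excludes them from stranded boundary rules by design.

### On-target accounting

A read is on-target when at least one aligned block overlaps at least
one base of the merged exonic regions of a targeted locus; intronic
overlap does not count. Enrichment is `R/E`, the ratio of the on-target
proportion in the targeted experiment to the proportion expected in
untargeted sequencing, with per-tissue proportions combined by
unweighted mean. Derived reporting follows table conventions:
percentages round half up to integers, folds and per-locus ratios half
up to one decimal. One caveat documented here on purpose: a published
table we reproduce contains one percentage (975 supported of 3,085
junctions) printed as 31% although the quotient is 31.6%; no rounding
rule reproduces both that cell and the others (e.g. 206/535 printed as
39%), so the package keeps half-up throughout and its own output for
that cell is 32%.

## The simulator

`sim_config()` defines the emulated study conditions: 50 targeted
multi-exon loci plus 25 decoy loci on a random genome (GC 0.55),
canonical splice sites planted at every intron; a truncated "pre-RACE"
annotation hiding the transcription-order terminal exon of each
truncated locus end (probability 0.6 per end), which plants a known
signed extension; primers designed against the truncated annotation
with the package's own design path (targets where the thermodynamic
window yields no eligible primer receive a fallback mid-transcript
annealing site so every locus can be primed); 200 reads per target,
each on-target with probability 0.364 (nested mode) or 0.039 (standard
mode) — the observed on-target proportions of the two priming
strategies; reads run from the primer to the true end with probability
0.8; full-length 3' products carry error-free polyA tails of 20–45 nt
(20-nt tails are deliberate negatives for the >20 rule) followed by the
3' RACE adapter; substitution errors at 0.5%; 2% of reads receive a
decoy secondary alignment to exercise the unique-mapping filter.
Evidence tracks place CAGE/polyA tags at true ends with ≤10 nt jitter,
10% drop-out and wrong-strand distractors. Genome GC of 0.55 was chosen
once so that the fixed 68–72 °C primer window is attainable on random
transcript sequence; at GC 0.5 the window sits in the upper tail of the
window-Tm distribution and many targets would fall back to synthetic
annealing sites.

Because the simulator knows every read's true placement, it emits
alignments directly as SAM (soft-clipping tails), keeping the test
suite hermetic; integration with a real spliced aligner is possible but
not required by any test. Fixed seed and configuration give
byte-identical outputs.

What the simulator does not emulate — and what passing tests therefore
do not show about real data: homopolymer indel errors characteristic of
pyrosequencing (the edit-distance trimmer tolerates them, but no test
exercises them), realistic expression-level variation across loci,
alignment ambiguity in repetitive sequence (decoy loci are random, so
off-target reads never cross-map), internal priming artefacts, and
incomplete splice-site conservation. Recovery rates near 100% on
simulated data reflect the clean planted truth, not expected real-data
performance.

## Problem sizes and runtime choices

The acceptance-scale experiment is 50 target loci × 200 reads (10,000
reads, ~27 Mb genome); the pipeline runs in well under a minute after
the per-read stages were vectorized, and the full simulate+analyse+score
round trip takes a few minutes on one CPU. Unit tests use 3–6 locus
configurations. The brute-force clustering cross-check runs 1,000
random site sets of up to 60 sites against a transitive-closure oracle.

## Known limitations

* The masking criterion is seed-limited (no seeds, no mask); true
  BLAST-parameter parity with the original pipeline is not attempted.
* Primer scoring weights are a package choice; primer3 compatibility is
  a non-goal.
* Junction offset entropy is defined on alignment starts relative to the
  donor; the original filter's exact definition is unpublished, so the
  threshold is configurable.
* Support-percentage rounding is half-up everywhere; see the caveat
  above about one published cell that cannot be reproduced under any
  consistent rule.
* `transcript_tss()`/`transcript_tts()` and friends operate on whole
  annotation tables rather than single-transcript objects — the
  vectorized surface suits R; the per-transcript semantics are
  unchanged.
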
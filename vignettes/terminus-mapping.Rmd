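---
title: "Mapping phage genome termini from coverage discontinuities and tag ligation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping phage genome termini from coverage discontinuities and tag ligation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetermini)
```

## The problem

Many tailed phages package their chromosome as a linear molecule carrying a
long direct terminal repeat (DTR): the same sequence, often ~10 kb, present
at both physical ends (T5/SPO1-style non-permuted packaging). Shotgun
assemblers collapse the two identical copies into one, producing an
apparently circular contig. Two signatures of the repeat survive the
collapse:

1. **Coverage doubling.** Every packaged molecule contributes two copies of
   the repeat but only one of every unique region, so mean read depth over
   the collapsed repeat is twice the depth elsewhere, with step
   discontinuities at the repeat boundaries.
2. **Tag-ligation junctions.** Blunt-ligating a known oligonucleotide
   (here a 49-mer) to intact genomic DNA and resequencing marks free DNA
   ends: reads containing the complete tag place the physical termini at
   the tag-genome junction. True termini recur in every molecule and form
   junction hotspots; random breaks from DNA isolation scatter uniformly.

`phagetermini` implements both detectors, reconciles them, and rewrites the
collapsed assembly as the physical chromosome. A mechanistic simulator
generates every input with full ground truth, so the whole pipeline is
testable without any sequencing data.

## The simulator: what it emulates

`build_genome()` draws an i.i.d. circular unit genome at a requested GC
fraction (default 66.2%, typical of a high-GC host) and declares a repeat
interval whose start is uniform on the circle, so repeats routinely straddle
the arbitrary assembly origin. The default dimensions — a 205,423 bp unit
genome with a 10,287 bp repeat — are the study conditions used throughout
the tests.

`package_molecules()` produces the physical molecules:

* `nonpermuted_repeat` — every molecule starts at the left repeat boundary
  (packaging initiation), traverses the circle once and continues through
  the repeat again: length is exactly unit + repeat with both copies intact.
* `nonpermuted_imprecise` — identical initiation, but the right-end
  cleavage deviates from the nominal boundary by a Gaussian draw
  (default sd considered in tests: 70 bp, giving a coverage transition of
  roughly 200 bp, the behaviour seen in phages with sloppier termination).
* `headful_permuted` — uniform starts and fixed headful length; on the
  circle this gives statistically flat coverage, the negative control.

`shotgun_reads()` samples reads as uniform arcs over each molecule with
truncated-normal lengths (mean 400 bp, sd 80, minimum 50 — a 454
FLX-Titanium-like model; the substitution-only error model and constant
Q30 qualities are deliberate simplifications, since homopolymer indel
chemistry contributes nothing to the detection contracts). Arcs are
*clipped at the molecule's physical ends*: a fragment overlapping a
terminus necessarily ends there. This choice matters. It reproduces two
properties of real libraries made from a population of identical linear
molecules — read ends pile up at the termini, and per-base coverage is
uniform right up to the first and last base — and it is what makes the
coverage step at a repeat boundary sharp at single-base resolution. A
start-uniform, extend-rightward model instead produces a read-length-wide
ramp at the left terminus and would make base-accurate boundary recovery
impossible under any detector.

What the simulator does **not** model: library composition bias (real
libraries have shown repeat enrichment of ~2.2-fold rather than the
theoretical 2.0 — the plausibility band below is configurable for such
data), flowgram/homopolymer errors, paired ends, chimeras, and host DNA
contamination. Passing tests therefore demonstrate correctness of the
detection logic under the packaging model, not robustness to every
artifact of real 454 chemistry.

`ligate_tags()` emits tag-carrying reads: a configurable fraction of
ligation events hit true molecule termini, the rest are uniform internal
double-strand breaks; read orientation is randomized. The default of 52
tagged reads with a terminus fraction of 0.37 mirrors the scale of a real
labeling experiment (52 tag reads, 15 of them at the two true loci).

All randomness flows from integer seeds; every stage takes its own seed, so
any stage is independently reproducible, and `run_pipeline()` derives fixed
per-stage seeds from a single run seed.

## Coverage analysis

`map_reads()` places reads by exact 31-mer prefix seeding (both
orientations) on the *doubled* circle followed by full-length verification
with at most 2 substitutions, then deposits depth per base modulo the unit
length. Because a packaged molecule is a contiguous arc of the circle,
every read is a single circular arc — reads spanning the repeat/unique
junctions or the assembly origin stay contiguous, so the depth steps remain
sharp without any heuristic splitting. Reads with errors in the seed or
more than 2 total mismatches drop out and are counted, not fatal.
Pre-computed placements are accepted as SAM (`coverage_from_sam()`), so any
external mapper honouring the circular contract can stand in.

`detect_breakpoints()` scans the ratio of adjacent window means (default
window 200 bp) around the circle, keeps well-separated local extrema above
`min_fold` (default 1.5), and refines each candidate to single-base
resolution with a two-plateau least-squares step fit. Conventions:

* An *up* breakpoint's position is the first base of the high plateau; a
  *down* breakpoint's position is the **last** base of the high plateau.
  ("First base of the higher side" is only well defined for up-steps; this
  pairing makes the repeat exactly the closed interval `[up, down]`, with
  `repeat_length = down - up + 1` on the circle, and makes right-terminus
  tag junctions land on the down position at distance 0.)
* The transition width is estimated by a plateau-ramp-plateau least-squares
  fit: 0 for an ideal step, the full ramp span for a linear ramp, and about
  3.5 standard deviations for a Gaussian-spread boundary. Among models
  within 2% of the optimal fit the narrowest ramp wins — plateau noise can
  imitate a shallow ramp around a genuinely abrupt step, while a genuine
  ramp loses far more than 2% when narrowed, so this parsimony rule
  stabilizes abrupt widths at 0-2 bp without biasing gradual ones.

`call_terminal_repeat()` pairs up/down breakpoints. A pairing is plausible
when the in-repeat to out-of-repeat mean depth ratio falls in the band
[1.6, 2.6] (theory says 2.0; the band leaves room for biased libraries and
is configurable). Among plausible pairings the highest combined step fold
wins; near-ties (within 5%) are broken by the mean fold closest to 2.0, and
pairings that remain indistinguishable raise an ambiguity error listing the
candidates rather than choosing silently. A boundary whose transition width
exceeds 50 bp classifies the call as `gradual` — chosen so that exact
cleavage (widths of a couple of bases) and imprecise cleavage (widths of
hundreds of bases) separate with a wide margin on both sides.

## Tag-junction analysis

`find_tag_reads()` requires the *complete* tag (default 0 mismatches,
configurable to 2 for noisier chemistry); partial tags are rejected.
`map_junctions()` trims the tag, aligns the longer genomic flank (minimum
25 nt) to the circle on either strand, and reports the first genomic base
adjacent to the tag boundary — 0-based internally, 1-based in the TSV
output. End-repair blunting is treated as position-neutral; resection is
not modelled.

`call_hotspots()` clusters junctions within 5 bp (circularly) and tests
each cluster's support against a binomial tail with success probability
`cluster_window / unit_length` — uniform breakage over the genome, the
natural null for isolation damage — Bonferroni-corrected over the observed
clusters. With ~41 junctions on a ~205 kb genome any recurrence of two
reads at one site is already significant; the residual type-I rate is
dominated by the birthday probability of two uniform junctions colliding
within the cluster window (~4% under these conditions, kept below the 5%
contract and verified over 1,000 null replicates in the tests).

`reconcile_termini()` matches hotspots to the two repeat boundaries
(default tolerance 5 bp) and issues a verdict: `confirmed`, `partial`,
`discordant`, `coverage-only`, or `tag-only`.

## Reopening

`reopen_genome()` rotates the assembly so the left repeat boundary
(packaging initiation) is position 0 and appends one repeat copy:
the physical genome is `unit_length + repeat_length` long with bit-identical
terminal copies, and `collapse_genome()` inverts the operation exactly.
Whether a deposited genome record places base 1 exactly at the coverage
up-step cannot be established from coverage alone; the rotation convention
is this package's own and is recorded in the `rotation` attribute. For
gradual right ends the reported right terminus is the midpoint of the
transition (the step-fit cut) and the result is flagged approximate.
`locate_terminus_in_annotation()` places a terminus inside a CDS (with its
1-based codon index, counted from the annotated start codon — the
convention in which a terminus 1,953 bases into a gene lies "within codon
652"), inside a tRNA, or in an intergenic gap with both neighbours named.

## Sequence calculators

* `splice_intein(precursor, start, end)` — intein length `end - start + 1`,
  mature length `precursor - intein`; spans touching either terminus are
  rejected (inteins are internal). The worked examples: a 341-residue
  intein excised from a 909-residue terminase precursor leaves 568 aa, and
  a 307-residue intein from a 936-residue ribonucleoside reductase leaves
  629 aa.
* `tape_measure_tail_length()` — 0.15 nm of tail per residue of alpha
  helix, rounded to the nearest nm: 1,964 aa predicts 295 nm; 2,155 aa
  predicts 323 nm.
* `fiber_length_range()` — one nm per 12-20 aa. The lower bound is rounded
  to the nearest nm and the upper bound rounded up, the tightest convention
  consistent with published fiber ranges; looser roundings seen in the
  literature (e.g. 541 aa quoted as 27-48 nm where 541/12 is 45.1) are not
  reverse-engineered.
* `find_slippery_sites()` — canonical X XXY YYZ heptamer scan for
  programmed -1 frameshift sites (`AAAAAAC`, `GGGAAAC`, or a generic scan);
  positions are returned 1-based, like every human-facing coordinate here.
* `codon_trna_coverage()` — strict Watson-Crick decoding: each unique
  anticodon decodes exactly its reverse-complement codon, no wobble rules,
  duplicate-anticodon tRNAs collapse. Stop codons and N-containing codons
  are excluded. The fraction is weighted by codon instances, so it is
  invariant to CDS order and duplication.
* `genome_identity()` — aligned-length-weighted mean percent identity of
  BLASTN-style segments multiplied by the merged matched fraction of the
  genome. The statistic is direction-dependent; the default reports the
  subject axis, `axis = "both"` averages the two directions and flags
  asymmetry above 2 points. Terminal repeats should be excluded from the
  inputs before alignment (a repeat-bearing genome double-counts them).

## Numerical choices and degenerate inputs

Internal coordinates are 0-based half-open; FASTA/GFF3/TSV output is
1-based inclusive. N bases are allowed in assemblies but excluded from GC
and codon statistics, and reads containing N are counted as unmapped rather
than crashing the seed index. An all-zero coverage profile, an empty read
set, and a tag with non-ACGT characters are hard errors; a flat profile
(headful packaging) is a *valid empty result*, reported as "no terminal
repeat detected". Window arithmetic wraps everywhere; breakpoint positions
are rotation-equivariant, which the tests verify directly.

## Worked example

```{r example}
res <- run_pipeline(list(genome = list(unit_length = 30000L,
                                       repeat_length = 2500L),
                         reads = list(fold_coverage = 80)),
                    seed = 5)
res
res$repeat_call
head(res$hotspots)
```

## Problem sizes used in the test suite

The bundled tests run the full published dimensions (205,423 bp unit
genome, 10,287 bp repeat) at 50-fold error-free coverage over ten seeds for
the recovery and fold checks, a 60 kb genome at 100-fold for the
imprecise-cleavage classification, 1,000 replicates of the 41-junction
uniform null for the hotspot type-I rate, and 4-30 kb genomes for the unit
and property tests. These sizes were chosen as the smallest at which the
statistical contracts are comfortably identifiable; all of them run on a
single CPU.

## Known limitations

* Short (tens of bp) terminal repeats produce coverage steps closer than
  the scan window and are not the target here; cos-site overhangs, Mu-style
  host-DNA ends and protein-capped termini leave no coverage signature and
  are reported as no-calls ("unknown" packaging).
* The internal mapper is exact-seeded and substitution-only; heavily
  indel-laden reads should be mapped externally and supplied as SAM.
* The hotspot test assumes uniform breakage; libraries with strong
  fragile-site structure would need an empirical background.
* Identity and codon statistics consume alignments and annotations; no
  alignment engine or gene/tRNA predictor is included by design.
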
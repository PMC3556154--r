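# phagetermini

Mapping the physical termini of non-permuted bacteriophage genomes from
sequencing coverage and oligo tag ligation.

## The problem

Phages that package their DNA with long **direct terminal repeats (DTRs)**
— T5/SPO1-style non-permuted packaging — confound shotgun assembly: the
two identical repeat copies at the chromosome ends collapse into a single
region, and the assembler reports an apparently circular genome. The
physical architecture is still recoverable from two signals:

* **Coverage doubling.** Each packaged molecule carries the repeat twice
  but every unique region once, so per-base read depth over the collapsed
  repeat is ~2x the rest of the contig, with step discontinuities at the
  repeat boundaries. For a profile `d(x)` on the circular assembly of
  length `L`, a boundary is a position where the adjacent window ratio
  `mean(d[x, x+w)) / mean(d[x-w, x))` peaks above a fold threshold; the
  repeat call `[left, right]` must satisfy
  `mean(d in repeat) / mean(d outside)` ≈ 2.
* **Tag-ligation junctions.** Blunt-ligating a known 49-mer oligo to
  intact genomic DNA and resequencing marks free DNA ends. Reads carrying
  the complete tag place a junction at the first genomic base adjacent to
  the tag; true termini recur across molecules and form statistically
  enriched hotspots against a uniform-breakage background (binomial tail,
  Bonferroni over clusters), while isolation-damage breaks scatter.

`phagetermini` detects the coverage breakpoints, maps the tag junctions,
reconciles the two lines of evidence, and reopens the assembly as the
linear physical chromosome (unit genome + one extra repeat copy, bit-exact
terminal copies). It targets phage genomicists finishing genomes from
short-read data, and ships a mechanistic simulator (packaged molecules →
reads → tag ligations, with full ground truth) so the entire pipeline is
testable without any sequencing run. Auxiliary calculators cover intein
splicing arithmetic, tape-measure tail-length prediction (0.15 nm/residue),
tail-fiber length ranges (12-20 aa/nm), programmed -1 frameshift slippery
heptamers (X XXY YYZ), codon/tRNA coverage, GC content, and a
segment-based genome identity statistic.

## Worked example

```r
library(phagetermini)

res <- run_pipeline(list(genome = list(unit_length = 30000L,
                                       repeat_length = 2500L),
                         reads = list(fold_coverage = 80)),
                    seed = 5)
res
#> <pipeline_result>
#>   terminal repeat: 2,500 bp (abrupt), mean fold 2.12
#>   reconciliation: confirmed (3 hotspots)

res$repeat_call
#> <terminal_repeat_call> repeat 2,500 bp [18538..21037] on 30,000 bp circle
#>   mean fold 2.12, boundaries abrupt (widths 0 / 1 bp)

res$hotspots
#>   position support    expected      p_value
#> 1    21037      10 0.008666667 9.359083e-27
#> 2    18538       7 0.008666667 1.709227e-17
#> 3     1190       2 0.008666667 1.318656e-03
```

Reading the output: the simulator hid a 2,500 bp repeat on a 30 kb circle;
coverage analysis recovered its exact boundaries (positions 18538-21037,
0-based) with a 2.12-fold depth ratio (theoretical 2.0) and near-zero
transition widths (`abrupt` — an imprecise-cleavage phage would show a
ramp of hundreds of bases and class `gradual`). The two dominant
tag-ligation hotspots (support 10 and 7 of 52 tagged reads) fall exactly
on the two boundaries — verdict `confirmed` at distance 0 — while the
third, weaker cluster is the kind of coincidental double break the
uniform background occasionally produces. `res$physical` holds the
reopened 32,500 bp linear chromosome whose first and last 2,500 bases are
identical.

The calculators are one-liners:

```r
splice_intein(909, 131, 471)    # $intein_length 341, $mature_length 568
tape_measure_tail_length(1964)  # 295 (nm)
find_slippery_sites("GGAAAAAACTT")  # 3
```

A thin command-line front end with subcommands `simulate`, `coverage`,
`tagmap`, `reopen`, `features` and `run` is installed at
`system.file("scripts", "termini.R", package = "phagetermini")`.

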
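Package: phagetermini
Title: Mapping Physical Termini of Non-Permuted Phage Genomes from
    Sequencing Coverage and Tag Ligation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects direct terminal repeats (DTRs) of bacteriophage
    chromosomes from read-coverage discontinuities on a collapsed circular
    assembly, confirms physical termini by mapping oligonucleotide
    tag-ligation junctions, and rewrites the assembly as the packaged
    linear chromosome with the repeat duplicated at both ends.  Includes a
    mechanistic simulator of packaged DNA molecules (non-permuted,
    imprecise-end and headful styles), shotgun reads and tag-ligated
    fragments with full ground truth, plus small sequence calculators:
    intein splicing arithmetic, tape-measure tail-length and tail-fiber
    estimators, slippery-heptamer scanning, codon/tRNA coverage and a
    segment-based genome identity statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
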
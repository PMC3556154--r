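test_that("intein excision arithmetic reproduces the worked protein sizes", {
  terl <- splice_intein(909, 131, 471)
  expect_identical(terl$intein_length, 341L)
  expect_identical(terl$mature_length, 568L)
  rnr <- splice_intein(936, 278, 584)
  expect_identical(rnr$intein_length, 307L)
  expect_identical(rnr$mature_length, 629L)
  one <- splice_intein(100, 50, 50)
  expect_identical(one$intein_length, 1L)
  expect_identical(one$mature_length, 99L)
  expect_error(splice_intein(100, 1, 50), "internal")
  expect_error(splice_intein(100, 50, 100), "internal")
})

test_that("intein splicing conserves residues over random internal spans", {
  set.seed(121)
  for (i in 1:50) {
    n <- sample(50:2000, 1L)
    s <- sample(2:(n - 2L), 1L)
    e <- sample(s:(n - 1L), 1L)
    res <- splice_intein(n, s, e)
    expect_identical(res$intein_length + res$mature_length, n)
  }
  prec <- paste(sample(LETTERS[1:20], 200, replace = TRUE), collapse = "")
  mat <- splice_intein_sequence(prec, 50, 120)
  expect_identical(nchar(mat), 200L - 71L)
  expect_identical(substr(mat, 1, 49), substr(prec, 1, 49))
  expect_identical(substring(mat, 50), substring(prec, 121))
})

test_that("tape measure tail lengths match the helical rise model", {
  expect_identical(tape_measure_tail_length(1964), 295L)
  expect_identical(tape_measure_tail_length(2155), 323L)
  expect_error(tape_measure_tail_length(0), "positive")
  # linear and monotone
  lens <- seq(100, 3000, by = 100)
  nm <- tape_measure_tail_length(lens)
  expect_true(all(diff(nm) > 0))
  expect_equal(nm, as.integer(round(lens * 0.15)))
})

test_that("fiber length ranges follow the 12-20 aa per nm rule", {
  expect_equal(unname(fiber_length_range(1412)), c(71, 118))
  expect_equal(unname(fiber_length_range(1158)), c(58, 97))
  expect_equal(unname(fiber_length_range(541)), c(27, 46))
  expect_equal(unname(fiber_length_range(20)), c(1, 2))
})

test_that("slippery heptamers are found by motif and by generic X XXY YYZ scan", {
  expect_identical(find_slippery_sites("GGAAAAAACTT"), 3L)
  expect_identical(find_slippery_sites("ACGTACGTACG"), integer(0))
  expect_identical(find_slippery_sites("GGGAAAC", motifs = "GGGAAAC"), 1L)
  expect_identical(find_slippery_sites("GGGAAAC", motifs = NULL), 1L)
  # generic scan matches any X XXY YYZ heptamer, including X == Y runs
  hits <- find_slippery_sites("TTGGGAAACCAAAAAACT", motifs = NULL)
  expect_true(3L %in% hits)   # GGGAAAC
  expect_true(11L %in% hits)  # AAAAAAC
  expect_error(find_slippery_sites("ACGT", motifs = "GGAAAAC"), "heptamer")
  expect_identical(find_slippery_sites("ACGGAAAACGT", motifs = "GGAAAAC",
                                       literal = TRUE), 3L)
  # region restriction shifts positions back to genome coordinates
  expect_identical(
    find_slippery_sites("TTTTTTTTAAAAAACTT", motifs = "AAAAAAC",
                        region = genome_interval(5, 17)),
    find_slippery_sites("TTTTTTTTAAAAAACTT", motifs = "AAAAAAC"))
})

test_that("codon/tRNA coverage uses strict reverse-complement decoding", {
  # two CDSs; anticodon CAT decodes ATG, GAA decodes TTC
  cds <- c("ATGTTCTTCTAA", "ATGGGGTAA")  # codons: ATG TTC TTC / ATG GGG (stops dropped)
  res <- codon_trna_coverage(cds, c("CAT", "GAA"))
  expect_identical(res$n_codons_covered, 2L)
  expect_equal(res$fraction_residues, 4 / 5)
  # duplicate anticodons collapse; U tolerated
  res2 <- codon_trna_coverage(cds, c("CAU", "CAT", "GAA"))
  expect_identical(res2$n_codons_covered, 2L)
  expect_equal(res2$fraction_residues, res$fraction_residues)
  # no tRNAs and full coverage edge cases
  expect_equal(codon_trna_coverage(cds, character(0)),
               list(n_codons_covered = 0L, fraction_residues = 0))
  res3 <- codon_trna_coverage(cds, c("CAT", "GAA", "CCC"))
  expect_equal(res3$fraction_residues, 1)
  # invariant to CDS order and duplication-aware counting
  res4 <- codon_trna_coverage(rev(cds), c("GAA", "CAT"))
  expect_equal(res4$fraction_residues, res$fraction_residues)
  expect_error(codon_trna_coverage("ATGC", c("CAT")), "divisible")
  expect_error(codon_trna_coverage(cds, c("CAT", "XYZ")), "anticodon")
})

test_that("genome identity is the length-weighted identity times matched fraction", {
  seg <- data.frame(pident = c(90, 70), length = c(10000, 10000),
                    qstart = c(1, 20001), qend = c(10000, 30000),
                    sstart = c(1, 20001), send = c(10000, 30000))
  expect_equal(genome_identity(seg, 40000, 40000, axis = "subject"), 40)
  # full-length self match scores 100 and the statistic is bounded
  self <- data.frame(pident = 100, length = 5000, qstart = 1, qend = 5000,
                     sstart = 1, send = 5000)
  expect_equal(genome_identity(self, 5000, 5000), 100)
  expect_equal(genome_identity(self[0, ], 5000, 5000), 0)
  # overlapping segments are merged before measuring coverage
  ovl <- data.frame(pident = c(80, 80), length = c(600, 600),
                    qstart = c(1, 401), qend = c(600, 1000),
                    sstart = c(1, 401), send = c(600, 1000))
  expect_equal(genome_identity(ovl, 2000, 2000, axis = "subject"),
               80 * 1000 / 2000)
  # minus-strand subject coordinates (sstart > send) are handled
  minus <- data.frame(pident = 100, length = 500, qstart = 1, qend = 500,
                      sstart = 1000, send = 501)
  expect_equal(genome_identity(minus, 500, 1000, axis = "subject"), 50)
  # both directions averaged, asymmetry reported
  asym <- data.frame(pident = 100, length = 500, qstart = 1, qend = 500,
                     sstart = 1, send = 500)
  v <- suppressWarnings(genome_identity(asym, 500, 2000, axis = "both"))
  expect_equal(as.numeric(v), (100 + 25) / 2)
  expect_equal(attr(v, "asymmetry"), 75)
})

test_that("BLAST outfmt-6 tables feed the identity statistic", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("q\ts\t95.5\t1000\t45\t2\t1\t1000\t501\t1500\t0.0\t1800",
               "q\ts\t88.0\t500\t60\t1\t2001\t2500\t3001\t3500\t1e-50\t700"),
             f)
  seg <- read_blast6(f)
  expect_identical(nrow(seg), 2L)
  expect_identical(names(seg)[3:4], c("pident", "length"))
  val <- genome_identity(seg, 4000, 4000, axis = "subject")
  wmean <- (95.5 * 1000 + 88 * 500) / 1500
  expect_equal(val, wmean * 1500 / 4000)
})

test_that("GC content excludes ambiguous bases", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCATN"), 50)
  expect_error(gc_content("NNN"), "unambiguous")
  g <- build_genome(50000, 2000, 0.662, seed = 5)
  expect_lt(abs(gc_content(g) - 66.2), 1.5)
})
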
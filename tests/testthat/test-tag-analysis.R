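test_that("find_tag_reads recovers complete tags and matches a brute-force scan", {
  sim <- small_sim()
  tg <- ligate_tags(sim$molecules, n_reads = 52L, termini_fraction = 0.37,
                    seed = 61)
  pool <- rbind(sim$reads[1:300, ], tg)
  set.seed(60)
  pool <- pool[sample.int(nrow(pool)), ]
  found <- find_tag_reads(pool, max_mismatch = 0L)
  expect_identical(sort(found$read_id), sort(tg$id))
  # oracle: plain substring scan in both orientations
  tag <- phicbk_tag()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  brute <- pool$id[grepl(tag, pool$sequence, fixed = TRUE) |
                   grepl(rc, pool$sequence, fixed = TRUE)]
  expect_setequal(found$read_id, brute)
  expect_true(all(found$tag_mismatches == 0L))
  expect_error(find_tag_reads(pool, tag = "ACGTNACGTNACGTNACGTN"), "non-ACGT")
})

test_that("tag matching honors the mismatch budget and rejects partial tags", {
  tag <- phicbk_tag()
  genomic <- strrep("ACGGT", 60)
  reads <- c(ok = paste0(tag, genomic),
             onemm = paste0(sub("T", "A", tag), genomic),     # 1 substitution
             partial = paste0(substr(tag, 10, 49), genomic),  # truncated tag
             none = genomic)
  expect_identical(find_tag_reads(reads, max_mismatch = 0L)$read_id, "ok")
  expect_setequal(find_tag_reads(reads, max_mismatch = 1L)$read_id,
                  c("ok", "onemm"))
})

test_that("junctions report the first genomic base adjacent to the tag", {
  g <- build_genome(3000L, 300L, 0.5, seed = 71)
  tag <- phicbk_tag()
  p <- 1200L   # 0-based
  flank <- phagetermini:::circ_substr(g$sequence, p, 200L)
  reads <- data.frame(id = "r1", sequence = paste0(tag, flank),
                      stringsAsFactors = FALSE)
  tr <- find_tag_reads(reads)
  jn <- map_junctions(tr, g)$junctions
  expect_identical(jn$junction_pos, p)
  expect_identical(jn$genomic_side, "right-of-tag")
  # reverse-orientation read: same junction
  reads$sequence <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(reads$sequence)))
  jn2 <- map_junctions(find_tag_reads(reads), g)$junctions
  expect_identical(jn2$junction_pos, p)
  # flank spanning the assembly origin wraps correctly
  p0 <- 2950L
  reads3 <- data.frame(id = "r3",
                       sequence = paste0(tag, phagetermini:::circ_substr(g$sequence, p0, 150L)),
                       stringsAsFactors = FALSE)
  jn3 <- map_junctions(find_tag_reads(reads3), g)$junctions
  expect_identical(jn3$junction_pos, p0)
  # genomic-then-tag layout reports the base left of the tag
  reads4 <- data.frame(id = "r4",
                       sequence = paste0(phagetermini:::circ_substr(g$sequence, 500L, 120L), tag),
                       stringsAsFactors = FALSE)
  jn4 <- map_junctions(find_tag_reads(reads4), g)$junctions
  expect_identical(jn4$junction_pos, 619L)
  expect_identical(jn4$genomic_side, "left-of-tag")
  # too-short flank is skipped with a count
  reads5 <- data.frame(id = "r5",
                       sequence = paste0(tag, substr(g$sequence, 1, 10)),
                       stringsAsFactors = FALSE)
  res5 <- map_junctions(find_tag_reads(reads5), g)
  expect_identical(nrow(res5$junctions), 0L)
  expect_identical(res5$n_short, 1L)
})

test_that("simulated terminus ligations map back to the two molecule ends", {
  sim <- small_sim()
  tg <- ligate_tags(sim$molecules, n_reads = 30L, termini_fraction = 1,
                    seed = 81)
  jn <- map_junctions(find_tag_reads(tg), sim$genome)$junctions
  expect_identical(nrow(jn), 30L)
  expect_identical(sort(unique(jn$junction_pos)), sort(unique(tg$junction)))
  # recovered positions agree with truth read by read
  truth <- tg$junction[match(jn$read_id, tg$id)]
  expect_identical(jn$junction_pos, truth)
})

test_that("two enriched loci among uniform junctions are the only hotspots", {
  L <- 205423L
  set.seed(91)
  pos <- c(rep(40000L, 8L), rep(120000L, 7L),
           sample.int(L, 26L) - 1L)   # 15 reads at two loci + 26 background
  hs <- call_hotspots(pos, L)
  expect_identical(nrow(hs), 2L)
  expect_setequal(hs$position, c(40000L, 120000L))
  expect_identical(sort(hs$support, decreasing = TRUE), c(8L, 7L))
  expect_true(all(hs$p_value < 1e-6))
})

test_that("hotspot calling controls the null and needs support of two", {
  expect_identical(nrow(call_hotspots(c(5L), 1000L)), 0L)
  expect_error(call_hotspots(integer(0), 1000L), "at least one")
  # uniform junctions: no hotspot in the typical replicate
  set.seed(92)
  calls <- vapply(1:200, function(i) {
    nrow(call_hotspots(sample.int(205423L, 41L) - 1L, 205423L))
  }, integer(1L))
  expect_lte(mean(calls > 0L), 0.08)
  # clustering wraps the origin
  hs <- call_hotspots(c(0L, 999L, 998L, 1L), 1000L, cluster_window = 5L)
  expect_identical(nrow(hs), 1L)
  expect_identical(hs$support, 4L)
})

test_that("reconciliation verdicts cover confirmed, partial and one-sided evidence", {
  call <- structure(list(left = list(position = 100L),
                         right = list(position = 599L),
                         repeat_length = 500L, mean_fold = 2.0,
                         boundary_class = "abrupt", unit_length = 10000L),
                    class = "terminal_repeat_call")
  hs <- data.frame(position = c(100L, 599L), support = c(5L, 4L),
                   expected = 0.02, p_value = 1e-8)
  rep1 <- reconcile_termini(call, hs)
  expect_identical(rep1$verdict, "confirmed")
  expect_identical(rep1$sides$left$distance, 0L)
  expect_identical(rep1$sides$right$distance, 0L)
  hs2 <- data.frame(position = 103L, support = 5L, expected = 0.02,
                    p_value = 1e-8)
  expect_identical(reconcile_termini(call, hs2)$verdict, "partial")
  expect_identical(reconcile_termini(call, NULL)$verdict, "coverage-only")
  expect_identical(reconcile_termini(NULL, hs)$verdict, "tag-only")
  hs3 <- data.frame(position = 5000L, support = 5L, expected = 0.02,
                    p_value = 1e-8)
  expect_identical(reconcile_termini(call, hs3)$verdict, "discordant")
})
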
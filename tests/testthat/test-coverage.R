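test_that("mapped depth equals brute-force counting from ground truth", {
  # oracle: per-base arc counting from the simulator's truth fields
  g <- build_genome(4000L, 500L, 0.55, seed = 31)
  m <- package_molecules(g, 5L, seed = 32)
  rd <- shotgun_reads(m, fold_coverage = 40, seed = 33)  # ~400 reads
  expect_lte(nrow(rd), 500L)
  p <- map_reads(rd, g)
  expect_identical(p$n_unmapped, 0L)
  expect_identical(p$depths, truth_depth(rd, m))
  expect_identical(sum(p$depths), sum(p$placements$length))
})

test_that("reads with errors still map and depth stays near target", {
  g <- build_genome(4000L, 500L, 0.55, seed = 34)
  m <- package_molecules(g, 5L, seed = 35)
  rd <- shotgun_reads(m, fold_coverage = 40, error_rate = 0.002, seed = 36)
  p <- map_reads(rd, g)
  # reads with > max_mismatch substitutions are expected to drop out
  # (~5% at 0.002/base over 400 bp); the rest must still place
  expect_gt(p$n_mapped / p$total_reads, 0.9)
  expect_lt(abs(mean(p$depths) / 40 - 1), 0.15)
})

test_that("SAM placements are accepted as a mapper substitute", {
  g <- build_genome(500L, 50L, 0.5, seed = 37)
  sam <- c("@HD\tVN:1.6\tSO:unmapped",
           sprintf("@SQ\tSN:%s\tLN:%d", g$name, g$unit_length),
           sprintf("r1\t0\t%s\t11\t60\t20M\t*\t0\t0\t%s\t*", g$name,
                   substr(g$sequence, 11, 30)),
           sprintf("r2\t0\t%s\t11\t60\t10M5D10M\t*\t0\t0\t%s\t*", g$name,
                   paste0(substr(g$sequence, 11, 20), substr(g$sequence, 26, 35))),
           sprintf("r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*"))
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  p <- coverage_from_sam(f, g)
  expect_identical(p$n_mapped, 2L)
  expect_identical(p$n_unmapped, 1L)
  exp_depth <- integer(500L)
  exp_depth[11:30] <- exp_depth[11:30] + 1L   # 20M
  exp_depth[11:35] <- exp_depth[11:35] + 1L   # 10M5D10M spans 25 ref bases
  expect_identical(p$depths, exp_depth)
})

test_that("an ideal 170->360 step is called at the exact base with width <= 2", {
  L <- 8000L
  x <- rep(170L, L)
  hi <- ((2999L + seq_len(2000L) - 1L) %% L) + 1L
  x[hi] <- 360L
  prof <- structure(list(depths = x, unit_length = L),
                    class = "coverage_profile")
  bp <- detect_breakpoints(prof, window = 200)
  up <- bp[bp$direction == "up", ]
  dn <- bp[bp$direction == "down", ]
  expect_identical(nrow(up), 1L); expect_identical(nrow(dn), 1L)
  expect_identical(up$position, 2999L)            # first high base, 0-based
  expect_identical(dn$position, (2999L + 2000L - 1L) %% L)
  expect_equal(up$fold_change, 360 / 170, tolerance = 0.01)
  expect_lte(up$transition_width, 2)
  expect_lte(dn$transition_width, 2)
})

test_that("a constructed 200 bp linear ramp is measured as a ~200 bp gradual transition", {
  x <- c(rep(170L, 3000L),
         as.integer(round(seq(170, 360, length.out = 202)))[2:201],
         rep(360L, 3000L), rep(170L, 3000L))
  prof <- structure(list(depths = x, unit_length = length(x)),
                    class = "coverage_profile")
  bp <- detect_breakpoints(prof, window = 200)
  up <- bp[bp$direction == "up", ]
  expect_identical(nrow(up), 1L)
  expect_gt(up$transition_width, 150)
  expect_lt(up$transition_width, 250)
})

test_that("flat headful coverage yields no breakpoints and no repeat call", {
  g <- build_genome(20000L, 2000L, 0.6, seed = 41)
  m <- package_molecules(g, 150L, style = "headful_permuted", seed = 42)
  rd <- shotgun_reads(m, fold_coverage = 100, seed = 43)
  p <- map_reads(rd, g)
  bp <- detect_breakpoints(p)
  expect_identical(nrow(bp), 0L)
  expect_error(call_terminal_repeat(bp, p), "no terminal repeat")
  expect_error(detect_breakpoints(structure(
    list(depths = integer(1000), unit_length = 1000L),
    class = "coverage_profile")), "all-zero")
})

test_that("breakpoint detection is invariant to rotation of the assembly origin", {
  sim <- small_sim()
  p <- map_reads(sim$reads, sim$genome)
  bp0 <- detect_breakpoints(p, window = 100)
  for (rot in c(777L, 3100L)) {
    x <- p$depths
    xr <- c(x[(rot + 1L):length(x)], x[1:rot])
    profr <- structure(list(depths = xr, unit_length = length(x)),
                       class = "coverage_profile")
    bpr <- detect_breakpoints(profr, window = 100)
    expect_setequal((bpr$position + rot) %% length(x), bp0$position)
  }
})

test_that("boundaries are recovered within +/-5 bp over seeded small-scale replicates", {
  hits <- 0L
  for (seed in 1:6) {
    g <- build_genome(20000L, 2500L, 0.6, seed = 200 + seed)
    m <- package_molecules(g, 10L, seed = 300 + seed)
    rd <- shotgun_reads(m, fold_coverage = 100, seed = 400 + seed)
    p <- map_reads(rd, g)
    tr <- call_terminal_repeat(detect_breakpoints(p), p)
    a <- g$repeat_interval[1L]
    b1 <- (a + 2500L - 1L) %% 20000L
    if (circ_ok <- (min(abs(tr$left$position - a),
                        20000L - abs(tr$left$position - a)) <= 5L &&
                    min(abs(tr$right$position - b1),
                        20000L - abs(tr$right$position - b1)) <= 5L))
      hits <- hits + 1L
    expect_equal(tr$repeat_length, 2500L, tolerance = 0.005)
    expect_gt(tr$mean_fold, 1.8); expect_lt(tr$mean_fold, 2.2)
    expect_identical(tr$boundary_class, "abrupt")
  }
  expect_gte(hits, 6L * 0.95 - 1L)
})

test_that("Colossus-style imprecise right ends produce a gradual right boundary", {
  g <- build_genome(50000L, 5000L, 0.62, seed = 51)
  m <- package_molecules(g, 200L, style = "nonpermuted_imprecise",
                         imprecision_sd = 70, seed = 52)
  rd <- shotgun_reads(m, fold_coverage = 100, seed = 53)
  p <- map_reads(rd, g)
  tr <- call_terminal_repeat(detect_breakpoints(p), p)
  expect_identical(tr$boundary_class, "gradual")
  expect_lte(tr$left$transition_width, 50)
  expect_gt(tr$right$transition_width, 50)
  # right terminus is the transition midpoint: within ~2 sd of nominal
  b1 <- (g$repeat_interval[1L] + 5000L - 1L) %% 50000L
  expect_lte(min(abs(tr$right$position - b1), 50000L - abs(tr$right$position - b1)),
             140L)
})
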
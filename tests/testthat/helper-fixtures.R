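# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) assign(key, fn(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# One simulate -> map replicate at the full published genome dimensions
# (205,423 bp unit genome, 10,287 bp repeat).
phage_replicate <- function(seed, coverage = 50, n_molecules = 20L) {
  g <- build_genome(205423L, 10287L, 0.662, seed = seed)
  m <- package_molecules(g, n_molecules, seed = seed + 1L)
  rd <- shotgun_reads(m, fold_coverage = coverage, seed = seed + 2L)
  p <- map_reads(rd, g)
  bp <- detect_breakpoints(p)
  call <- call_terminal_repeat(bp, p)
  list(genome = g, molecules = m, profile = p, breakpoints = bp, call = call)
}

# Ten seeded replicates; the first keeps its full state for reuse.
full_scale_replicates <- function() {
  fixture("full_scale_replicates", function() {
    out <- vector("list", 10L)
    for (k in 1:10) {
      r <- phage_replicate(seed = 100L + 7L * k)
      out[[k]] <- if (k == 1L) r else list(
        call = r$call,
        truth_repeat = interval_width(r$genome$repeat_interval, 205423L))
      if (k == 1L)
        out[[k]]$truth_repeat <- interval_width(r$genome$repeat_interval, 205423L)
    }
    out
  })
}

# Small genome for fast unit tests.
small_sim <- function() {
  fixture("small_sim", function() {
    g <- build_genome(6000L, 600L, 0.6, seed = 42)
    m <- package_molecules(g, 8L, seed = 43)
    rd <- shotgun_reads(m, fold_coverage = 80, seed = 44)
    list(genome = g, molecules = m, reads = rd)
  })
}

# Brute-force per-base depth from the simulator's ground truth.
truth_depth <- function(reads, molecules) {
  L <- molecules$unit_length
  depth <- integer(L)
  for (i in seq_len(nrow(reads))) {
    circ0 <- (molecules$start[reads$molecule[i]] + reads$offset[i]) %% L
    idx <- ((circ0 + seq_len(reads$length[i]) - 1L) %% L) + 1L
    depth[idx] <- depth[idx] + 1L
  }
  depth
}
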
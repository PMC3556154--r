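# Internal helpers: circular-coordinate arithmetic, seeded RNG scoping,
# string-level DNA manipulation.  All internal coordinates are 0-based
# half-open; wrapping is always modulo the unit (circle) length.

# Extract `len` bases starting at 0-based position `start0` on a circular
# sequence given as a single character string.  `len` may exceed the circle
# length (packaged molecules are unit + repeat).
circ_substr <- function(seq, start0, len) {
  L <- nchar(seq)
  stopifnot(start0 >= 0L, start0 < L, len >= 1L)
  ncopies <- ceiling((start0 + len) / L)
  if (ncopies > 1L) seq <- strrep(seq, ncopies)
  substr(seq, start0 + 1L, start0 + len)
}

# Circular distance from a to b walking forward (a -> b), 0-based positions.
circ_fwd <- function(a, b, L) (b - a) %% L

# Shortest circular distance between two positions.
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Rolling window sums on a circle.  Returns, for each position i (1..L of x),
# the sum of the `w` values starting at i (align = "right": x[i..i+w-1]) or
# ending at i-1 (align = "left": x[i-w..i-1]), indices wrapped.
circ_roll_sum <- function(x, w, align = c("right", "left")) {
  align <- match.arg(align)
  L <- length(x)
  stopifnot(w >= 1L, w < L)
  y <- c(x, x[seq_len(w)])
  cs <- cumsum(c(0, y))
  right <- cs[seq_len(L) + w] - cs[seq_len(L)]
  if (align == "right") return(right)
  # left window ending just before i == right window starting at i - w
  idx <- ((seq_len(L) - 1L - w) %% L) + 1L
  right[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
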
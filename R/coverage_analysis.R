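# Read placement on the circular assembly and detection of the coverage
# discontinuities that bound a non-permuted terminal repeat.
#
# The internal mapper is exact 31-mer prefix seeding on the doubled circle
# with full-length verification (<= max_mismatch substitutions).  Because a
# packaged molecule is a contiguous arc of the circle, every read maps as a
# single circular arc; depth is deposited per base modulo the unit length,
# so coverage steps at repeat boundaries stay sharp at base resolution.
# Pre-computed placements (SAM) are accepted as an alternative.

#' Map reads to a circular assembly and compute per-base depth
#'
#' @param reads a `simulated_reads` data frame, a character vector of read
#'   sequences, a [Biostrings::DNAStringSet], or the path to a FASTQ file.
#' @param assembly a [phage_genome()] with topology `circular_assembly`.
#' @param seed_len exact seed length (read prefix), bp.
#' @param max_mismatch maximum substitutions allowed over the full read.
#' @return An object of class `coverage_profile`: integer `depths` of length
#'   `unit_length`, placement table, and mapping counts.  `sum(depths)`
#'   equals the total number of mapped bases.
#' @export
map_reads <- function(reads, assembly, seed_len = 31L, max_mismatch = 2L) {
  stopifnot(inherits(assembly, "phage_genome"))
  if (assembly$topology != "circular_assembly")
    stop("map_reads requires a circular_assembly genome")
  seqs <- read_sequences(reads)
  ids <- names(seqs) %||% sprintf("read_%06d", seq_along(seqs))
  if (length(seqs) == 0L) stop("empty read set")
  L <- assembly$unit_length
  if (grepl(strrep("N", seed_len), assembly$sequence, fixed = TRUE))
    warning("assembly contains an N-run longer than the seed; ",
            "reads over it will not map")

  lens <- nchar(seqs)
  mappable <- lens >= seed_len & !grepl("[^ACGT]", seqs)
  n <- length(seqs)
  doubled <- Biostrings::DNAString(strrep(assembly$sequence, 2L))

  idx <- which(mappable)
  fwd <- Biostrings::DNAStringSet(seqs[idx])
  rev <- Biostrings::reverseComplement(fwd)
  seeds <- c(Biostrings::subseq(fwd, 1L, seed_len),
             Biostrings::subseq(rev, 1L, seed_len))
  names(seeds) <- NULL
  pd <- Biostrings::PDict(seeds)
  hits <- Biostrings::startIndex(Biostrings::matchPDict(pd, doubled))
  nf <- length(idx)

  # candidate placements: (read, circle pos, orientation), deduplicated mod L
  cand_read <- integer(0); cand_pos <- integer(0); cand_rev <- logical(0)
  for (k in seq_len(nf)) {
    hf <- hits[[k]]; hr <- hits[[k + nf]]
    if (length(hf)) {
      p <- unique(((hf - 1L) %% L) + 1L)
      cand_read <- c(cand_read, rep.int(k, length(p)))
      cand_pos <- c(cand_pos, p)
      cand_rev <- c(cand_rev, rep.int(FALSE, length(p)))
    }
    if (length(hr)) {
      p <- unique(((hr - 1L) %% L) + 1L)
      cand_read <- c(cand_read, rep.int(k, length(p)))
      cand_pos <- c(cand_pos, p)
      cand_rev <- c(cand_rev, rep.int(TRUE, length(p)))
    }
  }

  placements <- NULL
  if (length(cand_read)) {
    clen <- lens[idx][cand_read]
    windows <- as.character(Biostrings::extractAt(
      doubled, IRanges::IRanges(cand_pos, width = clen)))
    qstr <- ifelse(cand_rev, as.character(rev)[cand_read],
                   as.character(fwd)[cand_read])
    mm <- vapply(seq_along(cand_read), function(j) {
      sum(charToRaw(windows[j]) != charToRaw(qstr[j]))
    }, integer(1L))
    ok <- mm <= max_mismatch
    if (any(ok)) {
      df <- data.frame(read = cand_read[ok], pos = cand_pos[ok],
                       revstrand = cand_rev[ok], mm = mm[ok])
      df <- df[order(df$read, df$mm, df$revstrand), ]
      df <- df[!duplicated(df$read), ]       # best (then forward-first) hit
      placements <- data.frame(
        read_id = ids[idx][df$read],
        pos = ((df$pos - 1L) %% L),          # 0-based circle position
        length = lens[idx][df$read],
        strand = ifelse(df$revstrand, "-", "+"),
        mismatches = df$mm,
        stringsAsFactors = FALSE)
    }
  }
  n_mapped <- if (is.null(placements)) 0L else nrow(placements)
  depths <- deposit_depth(placements, L)
  structure(list(depths = depths, unit_length = L, total_reads = n,
                 n_mapped = n_mapped, n_unmapped = n - n_mapped,
                 placements = placements,
                 mapper_params = list(seed_len = seed_len,
                                      max_mismatch = max_mismatch),
                 assembly_name = assembly$name),
            class = "coverage_profile")
}

# Accept the various read containers used across the package.
read_sequences <- function(reads) {
  if (inherits(reads, "data.frame")) {
    s <- reads$sequence
    names(s) <- reads$id
    return(s)
  }
  if (inherits(reads, "DNAStringSet")) {
    s <- as.character(reads)
    if (is.null(names(s))) names(s) <- sprintf("read_%06d", seq_along(s))
    return(s)
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    df <- read_reads_fastq(reads)
    s <- df$sequence; names(s) <- df$id
    return(s)
  }
  stopifnot(is.character(reads))
  reads
}

# Per-base depth on the circle from arc placements, each base counted once.
deposit_depth <- function(placements, L) {
  if (is.null(placements) || nrow(placements) == 0L) return(integer(L))
  maxlen <- max(placements$length)
  ext <- L + maxlen
  delta <- tabulate(placements$pos + 1L, nbins = ext) -
    tabulate(placements$pos + placements$length + 1L, nbins = ext)
  cum <- cumsum(delta)
  depths <- cum[seq_len(L)]
  tail <- cum[seq.int(L + 1L, ext)]
  depths[seq_along(tail)] <- depths[seq_along(tail)] + tail
  as.integer(depths)
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s bp, %d/%d reads mapped, mean depth %.1f\n",
              format(x$unit_length, big.mark = ","), x$n_mapped, x$total_reads,
              mean(x$depths)))
  invisible(x)
}

#' Build a coverage profile from pre-computed placements in a SAM file
#'
#' Skips the internal mapper and counts reference-consuming bases (CIGAR
#' `M`, `=`, `X`, `D`, `N`) of every mapped record, wrapped onto the
#' circular assembly.
#'
#' @param sam_path SAM file aligned against the unit assembly.
#' @param assembly a circular [phage_genome()].
#' @return A `coverage_profile`.
#' @export
coverage_from_sam <- function(sam_path, assembly) {
  stopifnot(inherits(assembly, "phage_genome"))
  L <- assembly$unit_length
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "pos", "cigar", "strand")))[[1L]]
  ok <- !is.na(rec$pos)
  rw <- cigar_ref_width(rec$cigar[ok])
  placements <- data.frame(read_id = rec$qname[ok],
                           pos = (rec$pos[ok] - 1L) %% L,
                           length = rw,
                           strand = as.character(rec$strand[ok]),
                           mismatches = NA_integer_,
                           stringsAsFactors = FALSE)
  structure(list(depths = deposit_depth(placements, L), unit_length = L,
                 total_reads = length(rec$pos), n_mapped = sum(ok),
                 n_unmapped = sum(!ok), placements = placements,
                 mapper_params = list(source = "sam"),
                 assembly_name = assembly$name),
            class = "coverage_profile")
}

# Reference-space width of CIGAR strings (M/=/X/D/N consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    w <- as.integer(sub("[A-Z=]$", "", toks))
    op <- substr(toks, nchar(toks), nchar(toks))
    sum(w[op %in% c("M", "=", "X", "D", "N")])
  }, integer(1L), USE.NAMES = FALSE)
}

# ---- breakpoint detection --------------------------------------------------

#' Detect coverage breakpoints on the circle
#'
#' Scans the ratio of adjacent window means `mean(depth[i, i+window)) /
#' mean(depth[i-window, i))` around the circle, keeps well-separated local
#' extrema whose fold exceeds `min_fold`, and refines each to single-base
#' resolution by a two-plateau least-squares step fit.  The transition width
#' is the span of the ramp in a plateau-ramp-plateau least-squares fit
#' (0 for an ideal step; approximately the full ramp length for a linear
#' ramp; about 3.5 standard deviations for a Gaussian-spread boundary).
#'
#' @param profile a `coverage_profile` (or a bare integer depth vector).
#' @param min_fold minimum plateau fold change to report.
#' @param window window half-width, bp; `unit_length` must be at least
#'   `4 * window`.
#' @param max_calls cap on reported breakpoints per direction.
#' @return A `data.frame` with columns `position` (0-based circle position:
#'   first base of the high plateau for `up` transitions, last base of the
#'   high plateau for `down` transitions), `direction`, `fold_change`,
#'   `transition_width`.  Empty when no fold exceeds `min_fold` (the
#'   expected outcome for permuted/headful genomes).
#' @export
detect_breakpoints <- function(profile, min_fold = 1.5, window = 200L,
                               max_calls = 10L) {
  x <- if (inherits(profile, "coverage_profile")) profile$depths else profile
  x <- as.numeric(x)
  L <- length(x)
  if (all(x == 0)) stop("all-zero coverage profile")
  if (L < 4L * window) stop("unit_length must be at least 4 * window")
  w <- as.integer(window)
  right <- circ_roll_sum(x, w, "right") / w
  left <- circ_roll_sum(x, w, "left") / w
  r <- (right + 0.5) / (left + 0.5)

  cand_up <- pick_separated_extrema(r, min_fold, w, max_calls)
  cand_dn <- pick_separated_extrema(1 / r, min_fold, w, max_calls)

  rows <- list()
  for (i0 in cand_up) {
    f <- refine_step(x, i0 - 1L, w)
    if (f$hi / max(f$lo, 0.5) >= min_fold)
      rows[[length(rows) + 1L]] <- data.frame(
        position = f$cut, direction = "up",
        fold_change = f$hi / max(f$lo, 0.5),
        transition_width = f$width)
  }
  for (i0 in cand_dn) {
    f <- refine_step(x, i0 - 1L, w)
    if (f$hi / max(f$lo, 0.5) >= min_fold)
      rows[[length(rows) + 1L]] <- data.frame(
        position = (f$cut - 1L) %% L, direction = "down",
        fold_change = f$hi / max(f$lo, 0.5),
        transition_width = f$width)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), direction = character(0),
               fold_change = numeric(0), transition_width = numeric(0))
  attr(out, "unit_length") <- L
  out[order(match(out$direction, c("up", "down")), -out$fold_change), ,
      drop = FALSE]
}

# 1-based indices of local maxima of `score` exceeding `thr`, greedily
# separated by at least `w` on the circle.
pick_separated_extrema <- function(score, thr, w, max_calls) {
  L <- length(score)
  idx <- which(score > thr)
  if (length(idx) == 0L) return(integer(0))
  idx <- idx[order(score[idx], decreasing = TRUE)]
  picked <- integer(0)
  for (i in idx) {
    if (length(picked) >= max_calls) break
    if (all(circ_dist(i, picked, L) >= w)) picked <- c(picked, i)
  }
  picked
}

# Two-plateau step fit around 0-based center.  Returns the 0-based cut
# (first base of the RIGHT segment, which is the high plateau for an up
# transition), plateau means oriented as lo/hi, and the ramp width from a
# plateau-ramp-plateau fit on a wider region.
refine_step <- function(x, center0, w) {
  L <- length(x)
  n <- 2L * w
  pos <- ((center0 - w + seq_len(n) - 1L) %% L) + 1L
  v <- x[pos]
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  cuts <- seq_len(n - 1L)
  sseL <- cs2[cuts] - cs[cuts]^2 / cuts
  nR <- n - cuts
  sR <- cs[n] - cs[cuts]; qR <- cs2[n] - cs2[cuts]
  sseR <- qR - sR^2 / nR
  c_best <- cuts[which.min(sseL + sseR)]
  mL <- cs[c_best] / c_best
  mR <- (cs[n] - cs[c_best]) / (n - c_best)
  cut0 <- (center0 - w + c_best) %% L        # first base of right segment
  width <- est_transition_width(x, cut0, w)
  list(cut = cut0, lo = min(mL, mR), hi = max(mL, mR), width = width)
}

# Plateau-ramp-plateau least-squares fit on a region of radius 2w around the
# refined cut; transition width = number of bases strictly between the two
# plateaus.  Coarse-to-fine grid over ramp endpoints.
est_transition_width <- function(x, cut0, w) {
  L <- length(x)
  rw <- min(2L * w, (L - 2L) %/% 2L)
  n <- 2L * rw
  pos <- ((cut0 - rw + seq_len(n) - 1L) %% L) + 1L
  v <- x[pos]
  cidx <- rw                                  # cut sits mid-region
  fit <- function(p1s, p2s) {
    g <- expand.grid(p1 = p1s, p2 = p2s)
    g <- g[g$p2 > g$p1 & g$p1 >= 3L & g$p2 <= n - 2L, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    cs <- cumsum(v); cs2 <- cumsum(v^2); csj <- cumsum(v * seq_len(n))
    p1 <- g$p1; p2 <- g$p2
    lo <- cs[p1] / p1
    sse_lo <- cs2[p1] - cs[p1]^2 / p1
    n3 <- n - p2 + 1L
    s3 <- cs[n] - cs[p2 - 1L]
    hi <- s3 / n3
    sse_hi <- (cs2[n] - cs2[p2 - 1L]) - s3^2 / n3
    m <- p2 - p1 - 1L
    sse_ramp <- numeric(nrow(g))
    has <- m > 0L
    if (any(has)) {
      a <- p1[has]; b <- p2[has]; mm <- m[has]
      svv <- cs2[b - 1L] - cs2[a]
      sv <- cs[b - 1L] - cs[a]
      svj <- csj[b - 1L] - csj[a]
      slope <- (hi[has] - lo[has]) / (b - a)
      sk <- mm * (mm + 1) / 2                     # sum of (j - p1)
      sk2 <- mm * (mm + 1) * (2 * mm + 1) / 6     # sum of (j - p1)^2
      svt <- lo[has] * sv + slope * (svj - a * sv)
      st2 <- mm * lo[has]^2 + 2 * lo[has] * slope * sk + slope^2 * sk2
      sse_ramp[has] <- svv - 2 * svt + st2
    }
    g$sse <- sse_lo + sse_hi + sse_ramp
    g
  }
  # parsimony: among models within 2% of the optimal SSE, take the
  # narrowest ramp, so plateau noise cannot inflate an abrupt step into a
  # spurious ramp while genuine ramps (whose narrow fits are far worse)
  # keep their full span
  narrowest <- function(g) {
    keep <- g$sse <= min(g$sse) * 1.02 + 1e-9
    min(g$p2[keep] - g$p1[keep] - 1L)
  }
  coarse <- fit(seq(3L, cidx, by = 4L), seq(cidx, n - 2L, by = 4L))
  if (is.null(coarse)) return(0)
  b <- coarse[which.min(coarse$sse), ]
  fine <- fit(seq(max(3L, b$p1 - 4L), min(cidx + 4L, b$p1 + 4L)),
              seq(max(cidx - 4L, b$p2 - 4L), min(n - 2L, b$p2 + 4L)))
  max(0L, min(narrowest(coarse), narrowest(fine)))
}

#' Call a terminal repeat from detected breakpoints
#'
#' Pairs an up transition (packaging initiation, left repeat boundary) with
#' a down transition (right boundary).  Among pairings whose in-repeat to
#' out-of-repeat mean depth ratio falls inside `fold_band`, the one closest
#' to the theoretical 2.0 (two repeat copies per molecule) wins; equally
#' plausible alternatives raise an ambiguity error rather than a silent
#' choice.
#'
#' @param breakpoints result of [detect_breakpoints()].
#' @param profile the `coverage_profile` the breakpoints came from.
#' @param fold_band plausibility band for the in/out mean depth ratio.
#' @param gradual_threshold transition widths above this (bp) classify the
#'   boundary as `gradual`.
#' @param tie_tol two pairings whose `|mean_fold - 2|` scores differ by less
#'   than this are considered equally plausible (ambiguity error).
#' @return An object of class `terminal_repeat_call` with elements `left`,
#'   `right` (breakpoint rows), `repeat_length`, `mean_fold`,
#'   `boundary_class`, `unit_length`.  `repeat_length` counts the bases from
#'   `left$position` to `right$position` inclusive on the circle.
#' @export
call_terminal_repeat <- function(breakpoints, profile, fold_band = c(1.6, 2.6),
                                 gradual_threshold = 50, tie_tol = 0.02) {
  x <- as.numeric(profile$depths)
  L <- profile$unit_length
  ups <- breakpoints[breakpoints$direction == "up", , drop = FALSE]
  dns <- breakpoints[breakpoints$direction == "down", , drop = FALSE]
  if (nrow(ups) == 0L || nrow(dns) == 0L)
    stop("no terminal repeat detected: need at least one up and one down ",
         "coverage breakpoint (flat coverage is consistent with ",
         "permuted/headful packaging)")
  total <- sum(x)
  cands <- list()
  for (i in seq_len(nrow(ups))) for (j in seq_len(nrow(dns))) {
    u <- ups$position[i]; d <- dns$position[j]
    rl <- circ_fwd(u, d, L) + 1L
    if (rl >= L - 1L) next
    sin <- circ_interval_sum(x, u, rl)
    mean_in <- sin / rl
    mean_out <- (total - sin) / (L - rl)
    mf <- mean_in / max(mean_out, 1e-9)
    cands[[length(cands) + 1L]] <-
      data.frame(up = i, dn = j, left = u, right = d, repeat_length = rl,
                 mean_fold = mf, score = abs(mf - 2),
                 combined = log(ups$fold_change[i]) + log(dns$fold_change[j]))
  }
  cands <- do.call(rbind, cands)
  plaus <- cands[cands$mean_fold >= fold_band[1L] &
                 cands$mean_fold <= fold_band[2L], , drop = FALSE]
  if (nrow(plaus) == 0L)
    stop(sprintf(paste0("no plausible up/down pairing: best mean fold %.2f ",
                        "outside [%.2f, %.2f]"),
                 cands$mean_fold[which.min(cands$score)],
                 fold_band[1L], fold_band[2L]))
  # primary criterion: highest combined step fold; near-ties (within 5%)
  # are broken by mean_fold closest to the theoretical 2.0
  plaus <- plaus[order(-plaus$combined), , drop = FALSE]
  near <- plaus[plaus$combined >= plaus$combined[1L] - log(1.05), ,
                drop = FALSE]
  near <- near[order(near$score), , drop = FALSE]
  if (nrow(near) > 1L && near$score[2L] - near$score[1L] < tie_tol)
    stop("ambiguous terminal-repeat call; candidate pairings:\n",
         paste(utils::capture.output(print(
           near[, c("left", "right", "repeat_length", "mean_fold")])),
           collapse = "\n"))
  best <- near[1L, ]
  lrow <- ups[best$up, ]; rrow <- dns[best$dn, ]
  bclass <- if (lrow$transition_width > gradual_threshold ||
                rrow$transition_width > gradual_threshold) "gradual" else "abrupt"
  structure(list(left = as.list(lrow), right = as.list(rrow),
                 repeat_length = best$repeat_length,
                 mean_fold = best$mean_fold, boundary_class = bclass,
                 unit_length = L),
            class = "terminal_repeat_call")
}

# Sum of depth over `len` bases starting at 0-based `start` on the circle.
circ_interval_sum <- function(x, start, len) {
  L <- length(x)
  idx <- ((start + seq_len(len) - 1L) %% L) + 1L
  sum(x[idx])
}

#' @export
print.terminal_repeat_call <- function(x, ...) {
  cat(sprintf(paste0("<terminal_repeat_call> repeat %s bp [%d..%d] on %s bp",
                     " circle\n  mean fold %.2f, boundaries %s ",
                     "(widths %g / %g bp)\n"),
              format(x$repeat_length, big.mark = ","), x$left$position,
              x$right$position, format(x$unit_length, big.mark = ","),
              x$mean_fold, x$boundary_class,
              x$left$transition_width, x$right$transition_width))
  invisible(x)
}

# ---- depth writers ---------------------------------------------------------

#' Write per-base depth as TSV (1-based position, depth)
#' @param profile a `coverage_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(position = seq_len(profile$unit_length),
               depth = profile$depths),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-base depth as bedGraph (runs of equal depth merged)
#' @param profile a `coverage_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(profile, path) {
  r <- rle(profile$depths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  writeLines(c(sprintf("track type=bedGraph name=%s", profile$assembly_name),
               sprintf("%s\t%d\t%d\t%d", profile$assembly_name, starts, ends,
                       r$values)),
             path)
  invisible(path)
}
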
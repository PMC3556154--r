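# Terminal-ligation confirmation: locate reads carrying the complete oligo
# tag, map the tag-genome junction onto the circular assembly, and test
# junction clusters against a uniform-breakage background.

#' Find reads containing the complete oligo tag
#'
#' The full tag must be present (either orientation) within `max_mismatch`
#' substitutions; partial tags are rejected.  The default `max_mismatch = 0`
#' matches the "complete oligo" rule; raise to 2 for noisier chemistry.
#'
#' @param reads a `simulated_reads` data frame, character vector of read
#'   sequences, [Biostrings::DNAStringSet], or FASTQ path.
#' @param tag tag sequence (>= 20 nt, plain ACGT).
#' @param max_mismatch maximum substitutions within the tag match.
#' @return A `data.frame` with one row per tagged read: `read_id`,
#'   `sequence`, `tag_start`, `tag_end` (1-based span in the read),
#'   `orientation` (`"forward"` if the tag matches as given, `"reverse"` if
#'   its reverse complement matches), `tag_mismatches`.
#' @export
find_tag_reads <- function(reads, tag = phicbk_tag(), max_mismatch = 0L) {
  tag <- toupper(tag)
  if (nchar(tag) < 20L) stop("tag must be at least 20 nt")
  if (grepl("[^ACGT]", tag)) stop("tag contains non-ACGT characters")
  seqs <- read_sequences(reads)
  ids <- names(seqs) %||% sprintf("read_%06d", seq_along(seqs))
  ss <- Biostrings::DNAStringSet(seqs)
  hit_rows <- function(pattern, orientation) {
    m <- Biostrings::vmatchPattern(pattern, ss, max.mismatch = max_mismatch)
    idx <- which(lengths(m) > 0L)
    if (length(idx) == 0L) return(NULL)
    first <- vapply(idx, function(i) BiocGenerics::start(m[[i]])[1L], integer(1L))
    data.frame(read = idx, tag_start = first,
               tag_end = first + nchar(pattern) - 1L,
               orientation = orientation, stringsAsFactors = FALSE)
  }
  rows <- rbind(hit_rows(tag, "forward"),
                hit_rows(revcomp_chr(tag), "reverse"))
  if (is.null(rows) || nrow(rows) == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      tag_start = integer(0), tag_end = integer(0),
                      orientation = character(0), tag_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  rows <- rows[!duplicated(rows$read), , drop = FALSE]  # one span per read
  mism <- vapply(seq_len(nrow(rows)), function(j) {
    found <- substr(seqs[rows$read[j]], rows$tag_start[j], rows$tag_end[j])
    patt <- if (rows$orientation[j] == "forward") tag else revcomp_chr(tag)
    sum(charToRaw(found) != charToRaw(patt))
  }, integer(1L))
  out <- data.frame(read_id = ids[rows$read], sequence = unname(seqs[rows$read]),
                    tag_start = rows$tag_start, tag_end = rows$tag_end,
                    orientation = rows$orientation, tag_mismatches = mism,
                    stringsAsFactors = FALSE)
  attr(out, "tag") <- tag
  out
}

#' Map tag-genome junctions onto the circular assembly
#'
#' For each tagged read the tag is trimmed, the longer genomic flank is
#' aligned to the assembly (exact match with up to `max_mismatch`
#' substitutions, either strand, wrapping the origin), and the junction is
#' reported as the first genomic base adjacent to the tag boundary.  Reads
#' whose flank is shorter than `min_flank` or maps ambiguously/nowhere are
#' counted, not fatal.
#'
#' @param tag_reads result of [find_tag_reads()].
#' @param assembly a circular [phage_genome()].
#' @param min_flank minimum genomic flank length to attempt mapping, nt.
#' @param max_mismatch substitutions tolerated in the flank alignment.
#' @return A list with `junctions` (data frame: `read_id`, `junction_pos`
#'   0-based circle position, `genomic_side` relative to the tag-forward
#'   orientation of the read, `strand`, `tag_mismatches`, `flank_length`),
#'   and counts `n_short`, `n_unmapped`, `n_ambiguous`.
#' @export
map_junctions <- function(tag_reads, assembly, min_flank = 25L,
                          max_mismatch = 2L) {
  stopifnot(inherits(assembly, "phage_genome"))
  L <- assembly$unit_length
  doubled <- Biostrings::DNAString(strrep(assembly$sequence, 2L))
  rows <- list(); n_short <- 0L; n_unmapped <- 0L; n_ambig <- 0L
  for (j in seq_len(nrow(tag_reads))) {
    seq <- tag_reads$sequence[j]
    ts <- tag_reads$tag_start[j]; te <- tag_reads$tag_end[j]
    if (tag_reads$orientation[j] == "reverse") {
      # normalize so the tag reads in its given orientation
      n <- nchar(seq)
      seq <- revcomp_chr(seq)
      new_ts <- n - te + 1L
      te <- n - ts + 1L
      ts <- new_ts
    }
    right_fl <- substring(seq, te + 1L)
    left_fl <- substr(seq, 1L, ts - 1L)
    use_right <- nchar(right_fl) >= nchar(left_fl)
    flank <- if (use_right) right_fl else left_fl
    side <- if (use_right) "right-of-tag" else "left-of-tag"
    if (nchar(flank) < min_flank) { n_short <- n_short + 1L; next }
    hit <- locate_flank(flank, doubled, L, max_mismatch)
    if (is.null(hit)) { n_unmapped <- n_unmapped + 1L; next }
    if (hit$ambiguous) { n_ambig <- n_ambig + 1L; next }
    fl <- nchar(flank)
    jpos <- if (use_right) {
      if (hit$strand == "+") hit$pos else (hit$pos + fl - 1L) %% L
    } else {
      if (hit$strand == "+") (hit$pos + fl - 1L) %% L else hit$pos
    }
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = tag_reads$read_id[j], junction_pos = jpos,
      genomic_side = side, strand = hit$strand,
      tag_mismatches = tag_reads$tag_mismatches[j], flank_length = fl,
      stringsAsFactors = FALSE)
  }
  junctions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), junction_pos = integer(0),
               genomic_side = character(0), strand = character(0),
               tag_mismatches = integer(0), flank_length = integer(0),
               stringsAsFactors = FALSE)
  attr(junctions, "unit_length") <- L
  list(junctions = junctions, n_short = n_short, n_unmapped = n_unmapped,
       n_ambiguous = n_ambig)
}

# Place one flank on the doubled circle; returns 0-based canonical position
# of the flank's leftmost genomic base, or NULL/ambiguous.
locate_flank <- function(flank, doubled, L, max_mismatch) {
  for (mm in 0:max_mismatch) {
    pf <- BiocGenerics::start(Biostrings::matchPattern(
      flank, doubled, max.mismatch = mm))
    pr <- BiocGenerics::start(Biostrings::matchPattern(
      revcomp_chr(flank), doubled, max.mismatch = mm))
    posf <- unique((pf - 1L) %% L)
    posr <- unique((pr - 1L) %% L)
    ntot <- length(posf) + length(posr)
    if (ntot == 1L)
      return(if (length(posf)) list(pos = posf, strand = "+", ambiguous = FALSE)
             else list(pos = posr, strand = "-", ambiguous = FALSE))
    if (ntot > 1L) return(list(pos = NA, strand = NA, ambiguous = TRUE))
  }
  NULL
}

#' Call tag-ligation hotspots against a uniform-breakage background
#'
#' Junctions within `cluster_window` bp of each other (circularly) are
#' clustered; each cluster's support is tested against the tail of a
#' binomial with success probability `cluster_window / unit_length`
#' (junctions falling uniformly on the circle), Bonferroni-corrected over
#' the observed clusters.  Clusters need support of at least 2.
#'
#' @param junctions junction data frame from [map_junctions()] (or a bare
#'   integer vector of 0-based positions).
#' @param unit_length circle length, bp.
#' @param cluster_window clustering distance, bp.
#' @param alpha significance threshold on the adjusted p-value.
#' @return A `data.frame` of hotspots sorted by support: `position` (cluster
#'   mode, 0-based), `support`, `expected`, `p_value` (Bonferroni-adjusted).
#' @export
call_hotspots <- function(junctions, unit_length = NULL, cluster_window = 5L,
                          alpha = 0.05) {
  pos <- if (is.data.frame(junctions)) junctions$junction_pos else junctions
  if (is.null(unit_length))
    unit_length <- attr(junctions, "unit_length") %||%
      stop("unit_length required")
  n <- length(pos)
  empty <- data.frame(position = integer(0), support = integer(0),
                      expected = numeric(0), p_value = numeric(0))
  if (n < 1L) stop("at least one junction required")
  if (n < 2L) return(empty)
  sp <- sort(pos)
  gap <- diff(sp)
  grp <- cumsum(c(1L, as.integer(gap > cluster_window)))
  # circular merge of first and last cluster
  if (max(grp) > 1L && (sp[1L] + unit_length - sp[n]) <= cluster_window)
    grp[grp == max(grp)] <- 1L
  clusters <- split(sp, grp)
  stat <- lapply(clusters, function(p) {
    tb <- table(p)
    data.frame(position = as.integer(names(tb)[which.max(tb)]),
               support = length(p))
  })
  stat <- do.call(rbind, stat)
  p0 <- cluster_window / unit_length
  p_raw <- stats::pbinom(stat$support - 1L, n, p0, lower.tail = FALSE)
  stat$expected <- n * p0
  stat$p_value <- pmin(1, p_raw * nrow(stat))
  out <- stat[stat$support >= 2L & stat$p_value <= alpha, , drop = FALSE]
  out <- out[order(-out$support, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconcile coverage-called repeat boundaries with tag-ligation hotspots
#'
#' Matches each repeat boundary to its nearest hotspot (circular distance).
#' Verdicts: `confirmed` (both boundaries have a hotspot within
#' `tolerance`), `partial` (one does), `discordant` (hotspots exist but
#' match neither boundary), `coverage-only` (no hotspots), `tag-only`
#' (hotspots but no repeat call), `none`.
#'
#' @param repeat_call a `terminal_repeat_call`, or `NULL`.
#' @param hotspots hotspot data frame from [call_hotspots()], or `NULL`.
#' @param tolerance maximum boundary-to-hotspot distance, bp.
#' @return An object of class `terminus_report`.
#' @export
reconcile_termini <- function(repeat_call, hotspots, tolerance = 5L) {
  has_call <- !is.null(repeat_call)
  has_hot <- !is.null(hotspots) && nrow(hotspots) > 0L
  sides <- NULL
  verdict <-
    if (!has_call && !has_hot) "none"
    else if (!has_call) "tag-only"
    else if (!has_hot) "coverage-only"
    else NA_character_
  if (has_call && has_hot) {
    L <- repeat_call$unit_length
    match_side <- function(boundary) {
      d <- circ_dist(boundary, hotspots$position, L)
      k <- which.min(d)
      list(boundary = boundary, hotspot = hotspots$position[k],
           distance = d[k], matched = d[k] <= tolerance)
    }
    sides <- list(left = match_side(repeat_call$left$position),
                  right = match_side(repeat_call$right$position))
    nm <- sum(vapply(sides, `[[`, logical(1L), "matched"))
    verdict <- c("discordant", "partial", "confirmed")[nm + 1L]
  } else if (has_call) {
    sides <- list(left = list(boundary = repeat_call$left$position,
                              hotspot = NA, distance = NA, matched = FALSE),
                  right = list(boundary = repeat_call$right$position,
                               hotspot = NA, distance = NA, matched = FALSE))
  }
  structure(list(verdict = verdict, sides = sides, hotspots = hotspots,
                 repeat_call = repeat_call, tolerance = tolerance),
            class = "terminus_report")
}

#' @export
print.terminus_report <- function(x, ...) {
  cat(sprintf("<terminus_report> verdict: %s\n", x$verdict))
  if (!is.null(x$sides)) {
    for (s in names(x$sides)) {
      si <- x$sides[[s]]
      cat(sprintf("  %s terminus at %s: nearest hotspot %s (distance %s)\n",
                  s, si$boundary,
                  ifelse(is.na(si$hotspot), "none", si$hotspot),
                  ifelse(is.na(si$distance), "-", si$distance)))
    }
  }
  invisible(x)
}

#' Write a junction table as TSV (1-based positions)
#' @param junctions junction data frame from [map_junctions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junctions_tsv <- function(junctions, path) {
  out <- junctions
  out$junction_pos <- out$junction_pos + 1L
  names(out)[names(out) == "junction_pos"] <- "junction_pos_1based"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
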
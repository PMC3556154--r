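# Mechanistic simulator: circular unit genome -> packaged linear molecules
# -> shotgun reads / tag-ligated reads, with full ground truth carried on
# every read.  Reads are sampled from molecules, never painted onto the
# assembly, so repeat coverage doubling and terminus effects emerge from the
# packaging architecture itself.

#' The 49-mer oligonucleotide ligation tag
#'
#' Default double-stranded oligo tag used for terminal labeling; ligated
#' blunt to free DNA ends, it marks physical chromosome termini in the
#' resequencing reads.
#'
#' @return A 49-character DNA string.
#' @export
phicbk_tag <- function() {
  "TTACTTACAATCCTTGGCGGTTTTGCTGCGCGCCCATGATGGACTGGAC"
}

#' Build a random circular unit genome with a declared terminal repeat
#'
#' Bases are i.i.d. with the requested GC fraction.  The repeat interval is
#' a declared region of the circle (present once in the assembly); its two
#' physical copies only materialize when molecules are packaged.  The
#' interval start is drawn uniformly on the circle, so it may wrap the
#' assembly origin, as real terminal repeats routinely do.
#'
#' @param unit_length unit (non-redundant) genome length, bp.
#' @param repeat_length terminal repeat length, bp (`0 < repeat_length <
#'   unit_length`).
#' @param gc_fraction proportion of G+C in `[0, 1]`.
#' @param seed integer seed; identical calls with the same seed return
#'   identical genomes.
#' @param name genome identifier.
#' @return A [phage_genome()] with topology `circular_assembly` and
#'   packaging `nonpermuted_repeat`.
#' @examples
#' g <- build_genome(1000, 100, 0.5, seed = 7)
#' interval_width(g$repeat_interval, g$unit_length)
#' @export
build_genome <- function(unit_length, repeat_length, gc_fraction = 0.662,
                         seed = 1L, name = "sim_genome") {
  unit_length <- as.integer(unit_length)
  repeat_length <- as.integer(repeat_length)
  if (repeat_length <= 0L || repeat_length >= unit_length)
    stop("repeat_length must satisfy 0 < repeat_length < unit_length")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    seq <- paste(sample(names(p), unit_length, replace = TRUE, prob = p),
                 collapse = "")
    rstart <- sample.int(unit_length, 1L) - 1L
    rend <- (rstart + repeat_length) %% unit_length
    phage_genome(seq, name = name, topology = "circular_assembly",
                 unit_length = unit_length,
                 repeat_interval = c(rstart, rend),
                 packaging = "nonpermuted_repeat")
  })
}

#' Package linear DNA molecules from a circular unit genome
#'
#' Three packaging architectures are modelled:
#' * `nonpermuted_repeat`: every molecule starts at the left repeat boundary,
#'   traverses the full circle and continues through the repeat again, so
#'   molecule length is exactly `unit_length + repeat_length` and both repeat
#'   copies are intact (T5/SPO1 style).
#' * `nonpermuted_imprecise`: as above, but the right-end cleavage position
#'   deviates from the nominal repeat end by a Gaussian draw with standard
#'   deviation `imprecision_sd` (imprecise headful-like termination on top of
#'   a fixed initiation site).
#' * `headful_permuted`: packaging starts uniformly on the circle and takes
#'   a fixed headful; coverage on the circle is flat (negative control).
#'
#' @param genome a [phage_genome()] (circular assembly).
#' @param n number of molecules.
#' @param style packaging style (see above).
#' @param imprecision_sd standard deviation, bp, of the right-end deviation
#'   (only for `nonpermuted_imprecise`; `0` degenerates to
#'   `nonpermuted_repeat` output).
#' @param headful_length molecule length for `headful_permuted`; defaults to
#'   `round(1.05 * unit_length)`.
#' @param seed integer seed.
#' @return An object of class `packaged_molecules`: sequences plus the
#'   circular origin coordinates of each molecule.
#' @export
package_molecules <- function(genome, n,
                              style = c("nonpermuted_repeat",
                                        "nonpermuted_imprecise",
                                        "headful_permuted"),
                              imprecision_sd = 0, headful_length = NULL,
                              seed = 1L) {
  style <- match.arg(style)
  stopifnot(inherits(genome, "phage_genome"), n >= 1L)
  L <- genome$unit_length
  if (style %in% c("nonpermuted_repeat", "nonpermuted_imprecise") &&
      is.null(genome$repeat_interval))
    stop("style '", style, "' requires a genome with a repeat_interval")
  with_seed(seed, {
    if (style == "headful_permuted") {
      hl <- as.integer(headful_length %||% round(1.05 * L))
      starts <- sample.int(L, n, replace = TRUE) - 1L
      lens <- rep.int(hl, n)
    } else {
      a <- genome$repeat_interval[1L]
      R <- interval_width(genome$repeat_interval, L)
      starts <- rep.int(a, n)
      lens <- rep.int(L + R, n)
      if (style == "nonpermuted_imprecise" && imprecision_sd > 0) {
        dev <- as.integer(round(stats::rnorm(n, 0, imprecision_sd)))
        dev <- pmax(dev, -(R - 1L))      # keep some second repeat copy
        dev <- pmin(dev, L - R - 1L)     # never wrap a second full turn
        lens <- lens + dev
      }
    }
    seqs <- vapply(seq_len(n),
                   function(i) circ_substr(genome$sequence, starts[i], lens[i]),
                   character(1L))
    structure(list(sequences = seqs, start = starts, length = lens,
                   style = style, unit_length = L,
                   repeat_interval = genome$repeat_interval,
                   genome_name = genome$name),
              class = "packaged_molecules")
  })
}

#' @export
print.packaged_molecules <- function(x, ...) {
  cat(sprintf("<packaged_molecules> %d molecules (%s), lengths %s-%s bp\n",
              length(x$sequences), x$style,
              format(min(x$length), big.mark = ","),
              format(max(x$length), big.mark = ",")))
  invisible(x)
}

# Truncated-normal read lengths (approximating FLX Titanium-like reads).
draw_read_lengths <- function(n, mean_len, len_sd, min_len) {
  d <- as.integer(round(stats::rnorm(n, mean_len, len_sd)))
  while (any(bad <- d < min_len))
    d[bad] <- as.integer(round(stats::rnorm(sum(bad), mean_len, len_sd)))
  d
}

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, error_rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(bases, b), 1L), character(1L))
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Simulate shotgun reads from packaged molecules
#'
#' Reads are uniform arcs over each molecule, clipped at the molecule's
#' physical ends: a fragment overlapping a terminus necessarily ends there,
#' so read ends pile up at the termini and per-base coverage stays uniform
#' across the whole molecule, including its first and last bases.  This is
#' what makes the coverage step at a repeat boundary sharp at base
#' resolution.  Clipped reads shorter than `min_len` are redrawn.
#'
#' @param molecules a [package_molecules()] result.
#' @param fold_coverage target mean depth over the unit genome.
#' @param mean_len,len_sd,min_len read length model (truncated normal).
#' @param error_rate per-base substitution rate (no indels).
#' @param seed integer seed.
#' @return A `data.frame` of class `simulated_reads` with columns `id`,
#'   `sequence`, `quality`, `molecule`, `offset` (0-based position on the
#'   molecule), `length`, `strand`, `tagged`, `tag_end`, `junction`
#'   (ground truth; `junction` is the circle position of the tag-genome
#'   junction for tagged reads, `NA` otherwise).
#' @export
shotgun_reads <- function(molecules, fold_coverage, mean_len = 400,
                          len_sd = 80, min_len = 50, error_rate = 0,
                          seed = 1L) {
  stopifnot(inherits(molecules, "packaged_molecules"))
  if (mean_len < 50) stop("mean_len must be >= 50")
  if (fold_coverage <= 0) stop("fold_coverage must be > 0")
  L <- molecules$unit_length
  nmol <- length(molecules$sequences)
  n_reads <- as.integer(round(fold_coverage * L / mean_len))
  with_seed(seed, {
    mol <- sample.int(nmol, n_reads, replace = TRUE)
    d <- draw_read_lengths(n_reads, mean_len, len_sd, min_len)
    M <- molecules$length[mol]
    # arc start uniform in [-(d-1), M-1]; clip to [0, M)
    s <- floor(stats::runif(n_reads, -(d - 1), M))
    from <- pmax(s, 0)
    to <- pmin(s + d, M)
    len <- as.integer(to - from)
    # redraw clipped fragments that fell below min_len (rare, edge-only)
    for (it in seq_len(20L)) {
      bad <- which(len < min_len)
      if (length(bad) == 0L) break
      d2 <- draw_read_lengths(length(bad), mean_len, len_sd, min_len)
      s2 <- floor(stats::runif(length(bad), -(d2 - 1), M[bad]))
      from[bad] <- pmax(s2, 0)
      to[bad] <- pmin(s2 + d2, M[bad])
      len[bad] <- as.integer(to[bad] - from[bad])
    }
    keep <- len >= min_len
    mol <- mol[keep]; from <- as.integer(from[keep]); len <- len[keep]
    strand <- sample(c("+", "-"), length(mol), replace = TRUE)
    seqs <- substring(molecules$sequences[mol], from + 1L, from + len)
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
    seqs <- apply_substitutions(seqs, error_rate)
    reads <- data.frame(
      id = sprintf("read_%06d", seq_along(mol)),
      sequence = seqs,
      quality = strrep("?", len),          # constant Q30 placeholder
      molecule = mol, offset = from, length = len, strand = strand,
      tagged = FALSE, tag_end = NA_character_, junction = NA_integer_,
      stringsAsFactors = FALSE)
    attr(reads, "unit_length") <- L
    attr(reads, "molecule_start") <- molecules$start
    class(reads) <- c("simulated_reads", "data.frame")
    reads
  })
}

#' Simulate tag-ligated reads
#'
#' Emulates blunt ligation of a known oligo tag to free DNA ends followed by
#' resequencing: each emitted read carries the complete tag followed by the
#' genomic sequence extending inward from the ligated end.  A fraction
#' `termini_fraction` of ligation events hit a true molecule terminus; the
#' rest are uniformly placed internal double-strand breaks (isolation
#' damage).  Read orientation is randomized, so downstream code must find
#' the tag in either orientation.
#'
#' @param molecules a [package_molecules()] result.
#' @param tag tag sequence (default the bundled 49-mer, [phicbk_tag()]).
#' @param n_reads number of tag-containing reads to emit.  If `NULL`,
#'   `random_break_rate` (expected breaks per bp of molecule sequence) sets
#'   the count of break-ligation events on top of the terminus events.
#' @param termini_fraction fraction of tag events at true molecule termini.
#' @param random_break_rate per-bp break rate, used only when `n_reads` is
#'   `NULL`.
#' @param flank_mean,flank_sd,min_flank genomic flank length model.
#' @param seed integer seed.
#' @return A `simulated_reads` data frame (see [shotgun_reads()]); `junction`
#'   holds the true circle position of the genomic base adjacent to the tag.
#' @export
ligate_tags <- function(molecules, tag = phicbk_tag(), n_reads = 52L,
                        termini_fraction = 0.37, random_break_rate = NULL,
                        flank_mean = 250, flank_sd = 60, min_flank = 60,
                        seed = 1L) {
  stopifnot(inherits(molecules, "packaged_molecules"))
  tag <- toupper(tag)
  if (nchar(tag) < 20L) stop("tag must be at least 20 nt")
  if (grepl("[^ACGT]", tag)) stop("tag must be plain ACGT")
  L <- molecules$unit_length
  nmol <- length(molecules$sequences)
  with_seed(seed, {
    if (is.null(n_reads)) {
      n_break <- stats::rpois(1L, random_break_rate * sum(molecules$length))
      n_reads <- max(1L, as.integer(round(n_break / max(1 - termini_fraction, 1e-9))))
    }
    n_reads <- as.integer(n_reads)
    mol <- sample.int(nmol, n_reads, replace = TRUE)
    at_term <- stats::runif(n_reads) < termini_fraction
    side <- sample(c("left", "right"), n_reads, replace = TRUE)
    fl <- pmax(as.integer(round(stats::rnorm(n_reads, flank_mean, flank_sd))),
               min_flank)
    M <- molecules$length[mol]
    fl <- pmin(fl, M - 2L)
    seqs <- character(n_reads)
    junction <- integer(n_reads)
    offset <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      ms <- molecules$sequences[mol[i]]; Mi <- M[i]
      if (at_term[i]) {
        if (side[i] == "left") {          # tag ligated to the left terminus
          g <- substr(ms, 1L, fl[i])
          jm <- 0L
        } else {                          # right terminus, read inward
          g <- revcomp_chr(substr(ms, Mi - fl[i] + 1L, Mi))
          jm <- Mi - 1L
        }
      } else {                            # internal break between u-1 and u
        u <- sample(seq.int(fl[i] + 1L, Mi - fl[i]), 1L)
        if (side[i] == "left") {          # ligate to the downstream fragment
          g <- substr(ms, u + 1L, u + fl[i])
          jm <- u
        } else {                          # ligate to the upstream fragment
          g <- revcomp_chr(substr(ms, u - fl[i] + 1L, u))
          jm <- u - 1L
        }
      }
      seqs[i] <- paste0(tag, g)
      junction[i] <- (molecules$start[mol[i]] + jm) %% L
      offset[i] <- jm
    }
    flip <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
    if (any(flip)) seqs[flip] <- revcomp_chr(seqs[flip])
    reads <- data.frame(
      id = sprintf("tag_%04d", seq_len(n_reads)),
      sequence = seqs,
      quality = strrep("?", nchar(seqs)),
      molecule = mol, offset = offset, length = nchar(seqs),
      strand = ifelse(flip, "-", "+"),
      tagged = TRUE,
      tag_end = ifelse(at_term, side, "break"),
      junction = junction,
      stringsAsFactors = FALSE)
    attr(reads, "unit_length") <- L
    attr(reads, "molecule_start") <- molecules$start
    attr(reads, "tag") <- tag
    class(reads) <- c("simulated_reads", "data.frame")
    reads
  })
}

# ---- read I/O --------------------------------------------------------------

#' Write simulated reads as FASTQ (Sanger Phred+33)
#' @param reads a `simulated_reads` data frame.
#' @param path output FASTQ file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  q <- Biostrings::PhredQuality(reads$quality)
  ss <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence), q)
  names(ss) <- reads$id
  Biostrings::writeQualityScaledXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file into the reads container used by the pipeline
#' @param path FASTQ file.
#' @return A data frame with columns `id`, `sequence`, `quality`.
#' @export
read_reads_fastq <- function(path) {
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(ss), sequence = as.character(ss),
             quality = as.character(Biostrings::quality(ss)),
             stringsAsFactors = FALSE)
}

#' Write the ground-truth table for simulated reads
#'
#' Tab-separated: read id, molecule index, 0-based molecule offset, strand,
#' tagged flag, tag end class and the 1-based circle position of the
#' tag-genome junction (for tagged reads).
#'
#' @param reads a `simulated_reads` data frame.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  out <- data.frame(read_id = reads$id, molecule = reads$molecule,
                    offset = reads$offset, strand = reads$strand,
                    tagged = reads$tagged, tag_end = reads$tag_end,
                    junction_1based = ifelse(is.na(reads$junction), NA,
                                             reads$junction + 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
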
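# Coordinate-aware data types shared by all stages.
#
# Internally every coordinate is 0-based half-open on the circular unit
# assembly; human-facing output (GFF3, TSV reports) is converted to 1-based
# inclusive at the I/O boundary.

#' Construct a phage genome object
#'
#' A `phage_genome` holds a DNA sequence together with its topology and
#' packaging metadata.  A `circular_assembly` is the collapsed contig an
#' assembler produces from shotgun reads (one copy of any terminal repeat);
#' a `linear_physical` genome is the packaged chromosome, which carries the
#' repeat at both ends and is therefore `unit_length + repeat_length` long.
#'
#' @param sequence DNA string over `A,C,G,T,N` (a single character string,
#'   a [Biostrings::DNAString] or a length-1 [Biostrings::DNAStringSet]).
#' @param name identifier for the genome.
#' @param topology `"circular_assembly"` or `"linear_physical"`.
#' @param unit_length non-redundant genome length in bp.  Defaults to
#'   `nchar(sequence)` for circular assemblies.
#' @param repeat_interval optional terminal-repeat interval `c(start, end)`
#'   in 0-based half-open assembly coordinates.  `start > end` denotes an
#'   interval wrapping the (arbitrary) assembly origin.
#' @param packaging packaging style: `"nonpermuted_repeat"`,
#'   `"nonpermuted_imprecise"`, `"headful_permuted"` or `"unknown"`.
#' @return An object of class `phage_genome`.
#' @examples
#' g <- phage_genome("ACGTACGTAA", name = "toy")
#' g$unit_length
#' @export
phage_genome <- function(sequence, name = "genome",
                         topology = c("circular_assembly", "linear_physical"),
                         unit_length = NULL, repeat_interval = NULL,
                         packaging = c("unknown", "nonpermuted_repeat",
                                       "nonpermuted_imprecise", "headful_permuted")) {
  topology <- match.arg(topology)
  packaging <- match.arg(packaging)
  if (inherits(sequence, "DNAStringSet")) sequence <- as.character(sequence[[1L]])
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  n <- nchar(sequence)
  if (is.null(unit_length)) {
    if (topology == "linear_physical")
      stop("unit_length is required for a linear_physical genome")
    unit_length <- n
  }
  unit_length <- as.integer(unit_length)
  if (!is.null(repeat_interval)) {
    repeat_interval <- as.integer(repeat_interval)
    stopifnot(length(repeat_interval) == 2L,
              all(repeat_interval >= 0L), all(repeat_interval <= unit_length))
  }
  if (topology == "circular_assembly" && n != unit_length)
    stop("circular assembly: length(sequence) must equal unit_length")
  if (topology == "linear_physical") {
    if (is.null(repeat_interval))
      stop("linear_physical genome requires a repeat_interval")
    rl <- interval_width(repeat_interval, unit_length)
    if (n != unit_length + rl)
      stop("linear_physical genome: length must be unit_length + repeat_length")
    if (substr(sequence, 1L, rl) != substr(sequence, n - rl + 1L, n))
      stop("linear_physical genome: terminal repeat copies differ")
  }
  structure(list(name = name, sequence = sequence, topology = topology,
                 unit_length = unit_length, repeat_interval = repeat_interval,
                 packaging = packaging),
            class = "phage_genome")
}

#' Width of a (possibly origin-wrapping) interval on a circle
#'
#' @param interval 0-based half-open `c(start, end)`; `start > end` wraps
#'   the origin, `start == end` is the full circle.
#' @param L circle length, bp.
#' @return Integer width.
#' @export
interval_width <- function(interval, L) {
  if (interval[2L] > interval[1L]) interval[2L] - interval[1L]
  else L - interval[1L] + interval[2L]
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome> %s: %s, %s bp unit genome",
              x$name, x$topology, format(x$unit_length, big.mark = ",")))
  if (!is.null(x$repeat_interval))
    cat(sprintf(", repeat [%d, %d) = %s bp",
                x$repeat_interval[1L], x$repeat_interval[2L],
                format(interval_width(x$repeat_interval, x$unit_length),
                       big.mark = ",")))
  cat(sprintf("\n  packaging: %s\n", x$packaging))
  invisible(x)
}

#' Construct a genomic interval
#'
#' 0-based half-open interval, optionally stranded.  On circular topology an
#' interval with `start > end` wraps the assembly origin and is normalized
#' lazily by [normalize_wraparound()].
#'
#' @param start,end 0-based start (inclusive) and end (exclusive).
#' @param strand `"+"`, `"-"` or `"."`.
#' @return A list of class `genome_interval`.
#' @export
genome_interval <- function(start, end, strand = ".") {
  stopifnot(strand %in% c("+", "-", "."), start >= 0L, end >= 0L)
  structure(list(start = as.integer(start), end = as.integer(end),
                 strand = strand),
            class = "genome_interval")
}

#' Split an origin-wrapping interval into linear pieces
#'
#' On a circle of length `unit_length`, an interval stored with
#' `start > end` covers `[start, unit_length)` then `[0, end)`.  This
#' returns the equivalent list of non-wrapping intervals (a single interval
#' is returned unchanged; `start == end` denotes the full circle).
#'
#' @param interval a [genome_interval()].
#' @param unit_length circle length in bp.
#' @return List of `genome_interval` objects with `start < end`.
#' @examples
#' normalize_wraparound(genome_interval(90, 10), 100)
#' @export
normalize_wraparound <- function(interval, unit_length) {
  stopifnot(inherits(interval, "genome_interval"))
  s <- interval$start; e <- interval$end
  if (s < e) return(list(interval))
  if (s == e) return(list(genome_interval(0L, unit_length, interval$strand)))
  list(genome_interval(s, unit_length, interval$strand),
       genome_interval(0L, e, interval$strand))
}

#' Construct a gene feature
#'
#' @param start,end 0-based half-open genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @param kind `"CDS"`, `"tRNA"` or `"other"`.
#' @param frame reading-frame offset (0, 1 or 2) of the first in-frame base
#'   relative to the feature start (GFF3 phase).
#' @param attributes named list (e.g. `ID`, `product`, `anticodon`).
#' @return A list of class `gene_feature`.
#' @export
gene_feature <- function(start, end, strand = "+", kind = c("CDS", "tRNA", "other"),
                         frame = 0L, attributes = list()) {
  kind <- match.arg(kind)
  stopifnot(strand %in% c("+", "-"), frame %in% 0:2)
  if (kind == "tRNA" && !is.null(attributes$anticodon)) {
    ac <- toupper(attributes$anticodon)
    if (!grepl("^[ACGTU]{3}$", ac)) stop("tRNA anticodon must be a triplet")
    attributes$anticodon <- ac
  }
  structure(list(interval = genome_interval(start, end, strand), kind = kind,
                 frame = as.integer(frame), attributes = attributes),
            class = "gene_feature")
}

#' Codon index of a genomic position within a CDS
#'
#' Returns the 1-based codon ordinal containing `genomic_pos`, counted from
#' the annotated start codon and strand-aware, i.e. the convention in which
#' a terminus falling 1,953 bases into a plus-strand CDS lies "within codon
#' 652".
#'
#' @param gene a [gene_feature()] of kind `"CDS"`.
#' @param genomic_pos 0-based genomic position inside the gene.
#' @return Integer codon index (1-based).
#' @examples
#' g <- gene_feature(0, 3000, "+", "CDS")
#' reading_frame_codon_at(g, 1953)  # codon 652
#' @export
reading_frame_codon_at <- function(gene, genomic_pos) {
  stopifnot(inherits(gene, "gene_feature"))
  if (gene$kind != "CDS") stop("codon indexing requires a CDS feature")
  iv <- gene$interval
  if (genomic_pos < iv$start || genomic_pos >= iv$end)
    stop(sprintf("position %d outside feature [%d, %d)",
                 genomic_pos, iv$start, iv$end))
  offset <- if (iv$strand == "+") genomic_pos - iv$start
            else (iv$end - 1L) - genomic_pos
  offset <- offset - gene$frame
  if (offset < 0L) stop("position lies in the out-of-frame prefix of the CDS")
  as.integer(offset %/% 3L + 1L)
}

# ---- FASTA / GFF3 I/O ------------------------------------------------------

#' Read a genome from a FASTA file
#'
#' The first record is used.  The genome is returned as a circular assembly
#' unless `topology` says otherwise.
#'
#' @param path FASTA file.
#' @inheritParams phage_genome
#' @return A [phage_genome()].
#' @export
read_genome_fasta <- function(path, topology = "circular_assembly",
                              unit_length = NULL, repeat_interval = NULL,
                              packaging = "unknown") {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  phage_genome(as.character(ss[[1L]]), name = names(ss)[1L], topology = topology,
               unit_length = unit_length, repeat_interval = repeat_interval,
               packaging = packaging)
}

#' Write a genome to FASTA (70-column wrapping)
#'
#' @param genome a [phage_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$name
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read CDS and tRNA features from a GFF3 file
#'
#' Only `CDS` and `tRNA` records are consumed (annotation is an input, never
#' created here).  Coordinates are converted from GFF3 1-based inclusive to
#' the package-internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return List of [gene_feature()] objects sorted by start.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "tRNA")
  gr <- gr[keep]
  if (length(gr) == 0L) return(list())
  meta <- as.data.frame(S4Vectors::mcols(gr))
  feats <- lapply(seq_along(gr), function(i) {
    kind <- as.character(gr$type[i])
    attrs <- as.list(meta[i, setdiff(names(meta), c("type", "score", "phase")),
                          drop = FALSE])
    attrs <- attrs[!vapply(attrs, function(v) all(is.na(unlist(v))), logical(1L))]
    attrs <- lapply(attrs, function(v) if (is.list(v)) unlist(v) else v)
    ph <- gr$phase[i]
    gene_feature(start = BiocGenerics::start(gr)[i] - 1L,
                 end = BiocGenerics::end(gr)[i],
                 strand = if (as.character(BiocGenerics::strand(gr)[i]) == "-") "-" else "+",
                 kind = if (kind %in% c("CDS", "tRNA")) kind else "other",
                 frame = if (!is.null(ph) && !is.na(ph) && is.numeric(ph)) ph else 0L,
                 attributes = attrs)
  })
  feats[order(vapply(feats, function(f) f$interval$start, integer(1L)))]
}

# GC content lives in seq_features.R; codon statistics consume gene_feature
# records produced here.
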
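# Small, exactly specified sequence calculators: intein splicing
# arithmetic, tail-length estimators, slippery-heptamer scanning, codon/tRNA
# coverage, GC content, and the segment-based genome identity statistic.

#' Intein excision arithmetic
#'
#' Given a precursor protein length and the inclusive residue span of an
#' internal self-splicing intein, returns the intein length and the mature
#' (spliced) protein length.  Inteins are internal by definition: a span
#' touching residue 1 or the final residue is an error.
#'
#' @param precursor_length precursor length, residues.
#' @param start_res,end_res 1-based inclusive intein span.
#' @return List with `intein_length` and `mature_length`
#'   (`intein_length + mature_length == precursor_length`).
#' @examples
#' splice_intein(909, 131, 471)   # 341-residue intein, 568 aa mature protein
#' splice_intein(936, 278, 584)   # 307-residue intein, 629 aa mature protein
#' @export
splice_intein <- function(precursor_length, start_res, end_res) {
  precursor_length <- as.integer(precursor_length)
  start_res <- as.integer(start_res); end_res <- as.integer(end_res)
  if (start_res > end_res) stop("intein span start must not exceed end")
  if (start_res <= 1L || end_res >= precursor_length)
    stop("intein span must be internal (not touching residue 1 or the ",
         "C-terminal residue)")
  intein <- end_res - start_res + 1L
  list(intein_length = intein, mature_length = precursor_length - intein)
}

#' Splice an intein out of a precursor sequence
#'
#' Sequence variant of [splice_intein()]: concatenates the N-extein and
#' C-extein.
#'
#' @param precursor amino-acid sequence (single string).
#' @param start_res,end_res 1-based inclusive intein span.
#' @return The mature protein sequence.
#' @export
splice_intein_sequence <- function(precursor, start_res, end_res) {
  n <- nchar(precursor)
  splice_intein(n, start_res, end_res)   # validates span
  paste0(substr(precursor, 1L, start_res - 1L),
         substring(precursor, end_res + 1L))
}

#' Predicted tail length from a tape measure protein
#'
#' Tail tape measure proteins set phage tail length at about 0.15 nm of
#' tail per residue of alpha helix; 1,964 residues predict a 295 nm tail
#' and 2,155 residues a 323 nm tail.
#'
#' @param length_aa tape measure protein length, residues.
#' @param rise_per_residue helical rise, nm per residue.
#' @return Predicted tail length in nm, rounded to the nearest integer.
#' @examples
#' tape_measure_tail_length(1964)  # 295
#' @export
tape_measure_tail_length <- function(length_aa, rise_per_residue = 0.15) {
  if (any(length_aa <= 0)) stop("length_aa must be positive")
  as.integer(round(length_aa * rise_per_residue))
}

#' Tail-fiber length range from protein length
#'
#' Phage tail fibers yield roughly one nm of length per 12-20 amino acid
#' residues, so a protein of `length_aa` residues predicts a fiber between
#' `length_aa / 20` and `length_aa / 12` nm.  The lower bound is rounded to
#' the nearest nm, the upper bound rounded up.
#'
#' @param length_aa fiber protein length, residues.
#' @param aa_per_nm two-element range of residues per nm (densest first).
#' @return Named numeric `c(min, max)` in nm.
#' @examples
#' fiber_length_range(1412)  # about 71-118 nm
#' @export
fiber_length_range <- function(length_aa, aa_per_nm = c(12, 20)) {
  if (length_aa <= 0) stop("length_aa must be positive")
  c(min = round(length_aa / max(aa_per_nm)),
    max = ceiling(length_aa / min(aa_per_nm)))
}

#' Find programmed -1 frameshift slippery heptamers
#'
#' Scans a DNA string for slippery sequences of the canonical `X XXY YYZ`
#' form (three identical bases, three identical bases, any base), as in
#' `AAAAAAC` or `GGGAAAC`.  Supplied motifs must be heptamers of that form
#' unless `literal = TRUE`.  With `motifs = NULL` a generic `X XXY YYZ`
#' scan is performed.
#'
#' @param dna DNA string.
#' @param motifs character vector of heptamer motifs, or `NULL` for the
#'   generic scan.
#' @param region optional [genome_interval()] restricting the scan.
#' @param literal skip the heptamer-form validation of the motifs.
#' @return Sorted integer vector of 1-based match start positions.
#' @examples
#' find_slippery_sites("GGAAAAAACTT")            # position 3
#' find_slippery_sites("GGGAAAC", motifs = NULL) # generic scan: position 1
#' @export
find_slippery_sites <- function(dna, motifs = "AAAAAAC", region = NULL,
                                literal = FALSE) {
  dna <- toupper(dna)
  off <- 0L
  if (!is.null(region)) {
    dna <- substr(dna, region$start + 1L, region$end)
    off <- region$start
  }
  is_heptamer <- function(m) {
    nchar(m) == 7L &&
      length(unique(strsplit(substr(m, 1, 3), "")[[1L]])) == 1L &&
      length(unique(strsplit(substr(m, 4, 6), "")[[1L]])) == 1L
  }
  if (!is.null(motifs)) {
    motifs <- toupper(motifs)
    if (!literal && !all(vapply(motifs, is_heptamer, logical(1L))))
      stop("motifs must be heptamers of the X XXY YYZ form ",
           "(use literal = TRUE to search arbitrary strings)")
  }
  n <- nchar(dna)
  if (n < 7L) return(integer(0))
  ch <- strsplit(dna, "", fixed = TRUE)[[1L]]
  if (is.null(motifs)) {
    i <- seq_len(n - 6L)
    hit <- ch[i] == ch[i + 1L] & ch[i + 1L] == ch[i + 2L] &
      ch[i + 3L] == ch[i + 4L] & ch[i + 4L] == ch[i + 5L]
    return(sort(i[hit]) + off)
  }
  pos <- unlist(lapply(motifs, function(m) {
    hits <- gregexpr(m, dna, fixed = TRUE)[[1L]]
    hits[hits > 0L]
  }))
  sort(unique(pos)) + off
}

#' Codon/tRNA coverage statistic
#'
#' Fraction of codon instances across a set of CDS sequences that are
#' decoded by a phage-encoded tRNA complement, under strict Watson-Crick
#' decoding: each unique anticodon decodes exactly the codon that is its
#' reverse complement (no wobble), and duplicate-anticodon tRNAs collapse.
#' Stop codons and codons containing N are excluded from the denominator.
#'
#' @param cds_set character vector of in-frame CDS nucleotide sequences
#'   (lengths divisible by 3).
#' @param anticodons character vector of tRNA anticodon triplets (5'->3',
#'   `U` or `T` accepted).
#' @return List with `n_codons_covered` (unique codons decoded by the tRNA
#'   set) and `fraction_residues` (fraction of codon instances decoded).
#' @export
codon_trna_coverage <- function(cds_set, anticodons) {
  stop_codons <- c("TAA", "TAG", "TGA")
  cds_set <- toupper(cds_set)
  if (any(nchar(cds_set) %% 3L != 0L))
    stop("all CDS lengths must be divisible by 3")
  if (any(grepl("[^ACGTN]", cds_set)))
    stop("CDS sequences contain invalid characters")
  codons <- unlist(lapply(cds_set, function(s) {
    substring(s, seq(1L, nchar(s) - 2L, by = 3L), seq(3L, nchar(s), by = 3L))
  }))
  codons <- codons[!codons %in% stop_codons & !grepl("N", codons)]
  if (length(anticodons) == 0L)
    return(list(n_codons_covered = 0L, fraction_residues = 0))
  ac <- unique(chartr("U", "T", toupper(anticodons)))
  if (any(!grepl("^[ACGT]{3}$", ac))) stop("invalid anticodon triplet")
  decoded <- revcomp_chr(ac)
  frac <- if (length(codons)) mean(codons %in% decoded) else 0
  list(n_codons_covered = length(decoded), fraction_residues = frac)
}

#' Segment-based genome identity statistic
#'
#' Overall DNA relatedness of two genomes from local alignment segments
#' (BLASTN-style): the aligned-length-weighted mean percent identity of the
#' matched segments multiplied by the fraction of the genome covered by
#' matches (segments merged on the chosen axis before measuring coverage).
#' The result is on a 0-100 scale; a full-length self-match at 100%
#' identity scores 100.
#'
#' @param segments data frame of alignment segments with columns `pident`,
#'   `length`, `qstart`, `qend`, `sstart`, `send` (1-based inclusive, as in
#'   BLAST tabular output; `sstart > send` denotes a minus-strand match).
#'   See [read_blast6()].
#' @param query_length,subject_length genome lengths, bp.
#' @param axis `"subject"`, `"query"`, or `"both"` (the mean of the two
#'   directions; an attribute `asymmetry` records their absolute
#'   difference, which can exceed 2 points for asymmetric segment sets).
#' @return Percent identity-coverage product in `[0, 100]`.
#' @examples
#' seg <- data.frame(pident = c(90, 70), length = c(10000, 10000),
#'                   qstart = c(1, 20001), qend = c(10000, 30000),
#'                   sstart = c(1, 20001), send = c(10000, 30000))
#' genome_identity(seg, 40000, 40000)  # 80 * 0.5 = 40
#' @export
genome_identity <- function(segments, query_length, subject_length,
                            axis = c("subject", "query", "both")) {
  axis <- match.arg(axis)
  if (is.null(segments) || nrow(segments) == 0L) return(0)
  stopifnot(all(c("pident", "length", "qstart", "qend", "sstart", "send")
                %in% names(segments)))
  if (any(segments$length <= 0)) stop("aligned_length must be positive")
  if (any(segments$pident < 0 | segments$pident > 100))
    stop("percent_identity must be in [0, 100]")
  one_axis <- function(s1, s2, glen) {
    ir <- IRanges::IRanges(pmin(s1, s2), pmax(s1, s2))
    matched <- sum(IRanges::width(IRanges::reduce(ir)))
    wmean <- sum(segments$pident * segments$length) / sum(segments$length)
    wmean * min(matched / glen, 1)
  }
  val_s <- one_axis(segments$sstart, segments$send, subject_length)
  val_q <- one_axis(segments$qstart, segments$qend, query_length)
  out <- switch(axis, subject = val_s, query = val_q,
                both = (val_s + val_q) / 2)
  if (axis == "both") {
    attr(out, "asymmetry") <- abs(val_s - val_q)
    if (abs(val_s - val_q) > 2)
      warning(sprintf("identity is direction-dependent: subject %.1f vs query %.1f",
                      val_s, val_q))
  }
  out
}

#' Read tabular alignment segments (BLAST outfmt 6)
#'
#' Standard 12-column order: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore.
#'
#' @param path tab-separated file.
#' @return Data frame with the 12 standard columns.
#' @export
read_blast6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 tab-separated columns")
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' GC content of a DNA sequence
#'
#' `(G + C) / (A + C + G + T) * 100`; `N` bases are excluded from both
#' numerator and denominator.
#'
#' @param dna DNA string, [Biostrings::DNAString], or a [phage_genome()].
#' @return GC percentage.
#' @examples
#' gc_content("GGCC")  # 100
#' @export
gc_content <- function(dna) {
  if (inherits(dna, "phage_genome")) dna <- dna$sequence
  s <- Biostrings::DNAString(as.character(dna))
  if (length(s) == 0L) stop("empty sequence")
  f <- Biostrings::alphabetFrequency(s, baseOnly = TRUE)
  denom <- sum(f[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence has no unambiguous bases")
  unname(100 * sum(f[c("G", "C")]) / denom)
}
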
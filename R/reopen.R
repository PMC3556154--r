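# Rewrite the collapsed circular assembly as the packaged linear chromosome
# implied by a terminal-repeat call, and localize termini against supplied
# annotations.

#' Reopen a circular assembly as the physical linear chromosome
#'
#' The left repeat boundary (coverage up-step, packaging initiation) becomes
#' position 0 of the physical genome; the assembly is rotated there and one
#' extra copy of the repeat is appended, so the output is
#' `unit_length + repeat_length` long with bit-identical terminal copies.
#' For a `gradual` right boundary the right terminus is the midpoint of the
#' transition (the step-fit cut), and the result is flagged approximate.
#'
#' @param assembly a circular [phage_genome()].
#' @param call a `terminal_repeat_call` from [call_terminal_repeat()].
#' @return A [phage_genome()] with topology `linear_physical`.  Attributes:
#'   `rotation` (0-based assembly position now at physical position 0) and
#'   `right_end_approximate`.
#' @export
reopen_genome <- function(assembly, call) {
  stopifnot(inherits(assembly, "phage_genome"),
            inherits(call, "terminal_repeat_call"))
  if (assembly$topology != "circular_assembly")
    stop("reopen_genome expects a circular assembly")
  L <- assembly$unit_length
  if (call$unit_length != L)
    stop("terminal_repeat_call and assembly disagree on unit length")
  a <- call$left$position
  R <- call$repeat_length
  phys_seq <- circ_substr(assembly$sequence, a, L + R)
  phys <- phage_genome(phys_seq, name = paste0(assembly$name, "_physical"),
                       topology = "linear_physical", unit_length = L,
                       repeat_interval = c(0L, R),
                       packaging = assembly$packaging)
  attr(phys, "rotation") <- a
  attr(phys, "right_end_approximate") <- call$boundary_class == "gradual"
  if (call$boundary_class == "gradual")
    warning("gradual right boundary: right terminus is the transition ",
            "midpoint and is approximate")
  phys
}

#' Collapse a physical linear genome back to its circular assembly
#'
#' Removes the terminal repeat copy at the right end and undoes the rotation
#' recorded by [reopen_genome()], reproducing the original assembly exactly.
#'
#' @param physical a `linear_physical` [phage_genome()].
#' @param rotation assembly position that was placed at physical position 0;
#'   defaults to the `rotation` attribute.
#' @param name name for the collapsed assembly.
#' @return A circular [phage_genome()].
#' @export
collapse_genome <- function(physical, rotation = NULL, name = NULL) {
  stopifnot(inherits(physical, "phage_genome"))
  if (physical$topology != "linear_physical")
    stop("collapse_genome expects a linear_physical genome")
  rotation <- rotation %||% attr(physical, "rotation") %||% 0L
  L <- physical$unit_length
  unit <- substr(physical$sequence, 1L, L)
  back <- circ_substr(unit, (L - rotation) %% L, L)
  R <- interval_width(physical$repeat_interval, L)
  phage_genome(back, name = name %||% sub("_physical$", "", physical$name),
               topology = "circular_assembly", unit_length = L,
               repeat_interval = c(rotation, (rotation + R) %% L),
               packaging = physical$packaging)
}

#' Localize a terminus position against gene annotations
#'
#' @param pos 0-based genomic position.
#' @param features list of [gene_feature()] records (as from
#'   [read_features_gff3()]).
#' @param unit_length circle length for circular neighbor lookup; when
#'   `NULL` neighbors are linear only.
#' @return A list of class `terminus_localization`: for a position inside a
#'   CDS, the feature and its 1-based codon index; inside a tRNA/other
#'   feature, the feature; otherwise `"intergenic"` with both flanking
#'   feature ids.
#' @export
locate_terminus_in_annotation <- function(pos, features, unit_length = NULL) {
  feat_id <- function(f) {
    f$attributes$ID %||% f$attributes$Name %||% f$attributes$product %||%
      sprintf("feature_%d_%d", f$interval$start, f$interval$end)
  }
  inside <- Filter(function(f) pos >= f$interval$start && pos < f$interval$end,
                   features)
  if (length(inside) > 0L) {
    f <- inside[[1L]]
    codon <- if (f$kind == "CDS") reading_frame_codon_at(f, pos) else NA_integer_
    return(structure(list(status = "genic", kind = f$kind, feature = f,
                          feature_id = feat_id(f), codon = codon,
                          position = pos),
                     class = "terminus_localization"))
  }
  starts <- vapply(features, function(f) f$interval$start, integer(1L))
  ends <- vapply(features, function(f) f$interval$end, integer(1L))
  up <- which(ends <= pos)
  dn <- which(starts > pos)
  if (!is.null(unit_length)) {
    upstream <- if (length(up)) which.max(ends[up]) else which.max(ends)
    upstream <- if (length(up)) up[upstream] else upstream
    downstream <- if (length(dn)) dn[which.min(starts[dn])] else which.min(starts)
  } else {
    upstream <- if (length(up)) up[which.max(ends[up])] else NA_integer_
    downstream <- if (length(dn)) dn[which.min(starts[dn])] else NA_integer_
  }
  structure(list(status = "intergenic", kind = "intergenic", position = pos,
                 upstream_id = if (!is.na(upstream))
                   feat_id(features[[upstream]]) else NA_character_,
                 downstream_id = if (!is.na(downstream))
                   feat_id(features[[downstream]]) else NA_character_),
            class = "terminus_localization")
}

#' @export
print.terminus_localization <- function(x, ...) {
  if (x$status == "genic") {
    cat(sprintf("position %d lies within %s %s", x$position, x$kind,
                x$feature_id))
    if (!is.na(x$codon)) cat(sprintf(" (codon %d)", x$codon))
    cat("\n")
  } else {
    cat(sprintf("position %d is intergenic, between %s and %s\n",
                x$position, x$upstream_id, x$downstream_id))
  }
  invisible(x)
}

#' Write the physical genome as FASTA plus a GFF3 of its repeat regions
#'
#' The GFF3 carries two `repeat_region` features (1-based inclusive), one at
#' each end of the physical chromosome.
#'
#' @param physical a `linear_physical` [phage_genome()].
#' @param fasta_path,gff3_path output files.
#' @return Invisibly, the two paths.
#' @export
write_physical_genome <- function(physical, fasta_path, gff3_path) {
  stopifnot(physical$topology == "linear_physical")
  write_genome_fasta(physical, fasta_path)
  L <- physical$unit_length
  R <- interval_width(physical$repeat_interval, L)
  n <- nchar(physical$sequence)
  gr <- GenomicRanges::GRanges(
    seqnames = physical$name,
    ranges = IRanges::IRanges(start = c(1L, n - R + 1L), width = R),
    strand = "+")
  gr$type <- "repeat_region"
  gr$ID <- c("terminal_repeat_left", "terminal_repeat_right")
  gr$Note <- "direct terminal repeat copy"
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}
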
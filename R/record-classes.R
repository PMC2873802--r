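# Constructors for the two-layer record model.  These are deliberately thin
# S3 builders: they normalise types and reject obviously malformed input,
# while the full cross-field consistency rules live in validate_record() so
# that a structurally complete but inconsistent record can still be loaded,
# inspected and reported on.

int1 <- function(x, what) {
  v <- suppressWarnings(as.integer(x))
  if (length(v) != 1L || is.na(v)) stop(what, " must be a single integer", call. = FALSE)
  v
}

chr1 <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single string", call. = FALSE)
  }
  x
}

#' Exon with coordinates in up to three systems
#'
#' All coordinates are 1-based and inclusive.  `lrg_*` addresses the LRG
#' genomic sequence, `cdna_*` the spliced transcript, and `peptide_*` the
#' protein product (absent for UTR-only exons).
#'
#' @param lrg_start,lrg_end Exon interval on the LRG sequence.
#' @param cdna_start,cdna_end Exon interval on the cDNA (optional at build
#'   time; filled in by [build_record()]).
#' @param peptide_start,peptide_end Residue interval, or `NULL`.
#' @return An object of class `lrg_exon`.
#' @export
new_exon <- function(lrg_start, lrg_end, cdna_start = NULL, cdna_end = NULL,
                     peptide_start = NULL, peptide_end = NULL) {
  ex <- list(
    lrg_start = int1(lrg_start, "lrg_start"),
    lrg_end = int1(lrg_end, "lrg_end"),
    cdna_start = if (!is.null(cdna_start)) int1(cdna_start, "cdna_start"),
    cdna_end = if (!is.null(cdna_end)) int1(cdna_end, "cdna_end"),
    peptide_start = if (!is.null(peptide_start)) int1(peptide_start, "peptide_start"),
    peptide_end = if (!is.null(peptide_end)) int1(peptide_end, "peptide_end")
  )
  structure(ex, class = "lrg_exon")
}

#' Coding region bounds
#'
#' `cds_start` is the LRG position of the first base of the start codon and
#' `cds_end` the last base of the stop codon; the stored protein excludes
#' the stop residue.
#'
#' @param cds_start,cds_end 1-based inclusive LRG positions.
#' @return An object of class `lrg_coding_region`.
#' @export
new_coding_region <- function(cds_start, cds_end) {
  structure(list(cds_start = int1(cds_start, "cds_start"),
                 cds_end = int1(cds_end, "cds_end")),
            class = "lrg_coding_region")
}

#' Protein product of a transcript
#'
#' @param name Product name `"p<k>"` matching the owning transcript `"t<k>"`.
#' @param sequence One-letter amino-acid string without the terminal stop.
#' @return An object of class `lrg_protein`.
#' @export
new_protein <- function(name, sequence) {
  structure(list(name = chr1(name, "name"),
                 sequence = chr1(sequence, "sequence")),
            class = "lrg_protein")
}

#' Transcript of the fixed layer
#'
#' @param name Transcript name, `"t1"`, `"t2"`, ...
#' @param exons List of [new_exon()] objects, 5' to 3' on the LRG forward
#'   strand.
#' @param coding_region [new_coding_region()] or `NULL` for non-coding loci.
#' @param cdna_sequence Spliced cDNA string.
#' @param protein [new_protein()] or `NULL`; present iff `coding_region` is.
#' @return An object of class `lrg_transcript`.
#' @export
new_transcript <- function(name, exons, coding_region = NULL,
                           cdna_sequence = "", protein = NULL) {
  structure(list(name = chr1(name, "name"),
                 exons = lapply(exons, as_exon),
                 coding_region = coding_region,
                 cdna_sequence = chr1(cdna_sequence, "cdna_sequence"),
                 protein = protein),
            class = "lrg_transcript")
}

as_exon <- function(x) {
  if (inherits(x, "lrg_exon")) return(x)
  do.call(new_exon, x[!vapply(x, is.null, logical(1))])
}

#' Fixed-annotation layer
#'
#' The immutable core of a record: organism, genomic sequence and the
#' transcripts (with their cDNA, protein and exon markup) that define the
#' locus.  Nothing in this layer may change once a record is issued; see
#' [fixed_layer_digest()] and [check_new_id_policy()].
#'
#' @param sequence Genomic DNA over `A,C,G,T,N`.
#' @param transcripts List of [new_transcript()], named `t1`, `t2`, ...
#'   consecutively.  May be empty for a pure regulatory region (flagged as a
#'   warning by the validator).
#' @param organism Organism name; any organism is permitted.
#' @param taxon_id NCBI taxon id.
#' @return An object of class `lrg_fixed_annotation`.
#' @export
new_fixed_annotation <- function(sequence, transcripts = list(),
                                 organism = "Homo sapiens", taxon_id = 9606L) {
  structure(list(organism = chr1(organism, "organism"),
                 taxon_id = int1(taxon_id, "taxon_id"),
                 sequence = chr1(sequence, "sequence"),
                 transcripts = lapply(transcripts, function(t) {
                   if (!inherits(t, "lrg_transcript")) stop("transcripts must be lrg_transcript objects", call. = FALSE)
                   t
                 })),
            class = "lrg_fixed_annotation")
}

#' Sequence difference inside a mapping span
#'
#' Describes where the LRG and the mapped assembly/contig sequence disagree,
#' so that a mapping can represent a composite reference faithfully.
#' Intervals are in the forward orientation of each sequence; the empty side
#' of an insertion is encoded with `end = start - 1` at the insertion point.
#'
#' @param kind `"mismatch"`, `"lrg_insertion"` (bases present only in the
#'   LRG) or `"other_insertion"` (bases present only in the other sequence).
#' @param lrg_start,lrg_end Interval on the LRG.
#' @param other_start,other_end Interval on the other sequence.
#' @param lrg_sequence,other_sequence The differing bases (may be `""` on
#'   the empty side).
#' @return An object of class `lrg_seq_diff`.
#' @export
new_seq_diff <- function(kind, lrg_start, lrg_end, other_start, other_end,
                         lrg_sequence = "", other_sequence = "") {
  kind <- match.arg(kind, c("mismatch", "lrg_insertion", "other_insertion"))
  structure(list(kind = kind,
                 lrg_start = int1(lrg_start, "lrg_start"),
                 lrg_end = int1(lrg_end, "lrg_end"),
                 other_start = int1(other_start, "other_start"),
                 other_end = int1(other_end, "other_end"),
                 lrg_sequence = chr1(lrg_sequence, "lrg_sequence"),
                 other_sequence = chr1(other_sequence, "other_sequence")),
            class = "lrg_seq_diff")
}

#' Strand-aware mapping span
#'
#' One contiguous aligned block between the LRG and another sequence.  With
#' no diffs the two intervals have equal length; diffs account for composite
#' reference sequences.
#'
#' @param lrg_start,lrg_end LRG interval (1-based inclusive).
#' @param other_start,other_end Interval on the other sequence, always in
#'   its forward orientation (`other_start <= other_end`).
#' @param strand `+1` or `-1`.
#' @param diffs List of [new_seq_diff()].
#' @return An object of class `lrg_mapping_span`.
#' @export
new_mapping_span <- function(lrg_start, lrg_end, other_start, other_end,
                             strand = 1L, diffs = list()) {
  strand <- int1(strand, "strand")
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1", call. = FALSE)
  structure(list(lrg_start = int1(lrg_start, "lrg_start"),
                 lrg_end = int1(lrg_end, "lrg_end"),
                 other_start = int1(other_start, "other_start"),
                 other_end = int1(other_end, "other_end"),
                 strand = strand,
                 diffs = diffs),
            class = "lrg_mapping_span")
}

#' Mapping of the LRG onto an assembly or contig
#'
#' @param assembly_name Assembly label, e.g. `"GRCh37"` or `"NCBI36"`.
#' @param other_accession Versioned accession of the target sequence.
#' @param spans List of [new_mapping_span()], non-overlapping in LRG
#'   coordinates.
#' @return An object of class `lrg_assembly_mapping`.
#' @export
new_assembly_mapping <- function(assembly_name, other_accession, spans) {
  structure(list(assembly_name = chr1(assembly_name, "assembly_name"),
                 other_accession = chr1(other_accession, "other_accession"),
                 spans = spans),
            class = "lrg_assembly_mapping")
}

#' Cross-reference to an external record
#'
#' `identical_to_lrg = TRUE` asserts that the named version of the external
#' record (a matching RefSeqGene, mRNA or protein) is sequence-identical to
#' the corresponding LRG content, so coordinates carry over unchanged.
#'
#' @param source_db Source database name.
#' @param accession Unversioned accession string.
#' @param version Integer version, or `NULL`.  Required when
#'   `identical_to_lrg` is `TRUE` (identity is only meaningful for one
#'   specific version).
#' @param identical_to_lrg Logical flag.
#' @return An object of class `lrg_xref`.
#' @export
new_xref <- function(source_db, accession, version = NULL,
                     identical_to_lrg = FALSE) {
  structure(list(source_db = chr1(source_db, "source_db"),
                 accession = chr1(accession, "accession"),
                 version = if (!is.null(version)) int1(version, "version"),
                 identical_to_lrg = isTRUE(identical_to_lrg)),
            class = "lrg_xref")
}

#' Legacy numbering map
#'
#' Carries historical exon labels and legacy residue numbering (for example
#' mature-protein numbering offset by a cleaved propeptide) keyed to the
#' systematic fixed-layer coordinates: `legacy = systematic - shift`.
#'
#' @param scheme_name Name of the legacy scheme.
#' @param exon_labels Named list/vector: fixed-layer exon ordinal (as name)
#'   to legacy label string (labels may be non-numeric, e.g. `"2B"`).
#' @param residue_shifts Data frame with columns `start`, `end`, `shift`
#'   (systematic residue range, integer shift); ranges must not overlap.
#' @return An object of class `lrg_legacy_map`.
#' @export
new_legacy_map <- function(scheme_name, exon_labels = list(),
                           residue_shifts = data.frame(start = integer(),
                                                       end = integer(),
                                                       shift = integer())) {
  stopifnot(all(c("start", "end", "shift") %in% names(residue_shifts)))
  labels <- lapply(exon_labels, function(x) chr1(as.character(x), "exon label"))
  structure(list(scheme_name = chr1(scheme_name, "scheme_name"),
                 exon_labels = labels,
                 residue_shifts = residue_shifts[, c("start", "end", "shift"),
                                                 drop = FALSE]),
            class = "lrg_legacy_map")
}

#' Report of an overlapping locus
#'
#' @param id Identifier of the overlapping LRG or gene.
#' @param strand `+1` (same strand) or `-1` (antisense), relative to the LRG.
#' @return An object of class `lrg_overlap`.
#' @export
new_overlap <- function(id, strand = 1L) {
  strand <- int1(strand, "strand")
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1", call. = FALSE)
  structure(list(id = chr1(id, "id"), strand = strand),
            class = "lrg_overlap")
}

#' Date-stamped annotation set of the updatable layer
#'
#' @param source Name of the annotating source.
#' @param modification_date ISO 8601 date string (`YYYY-MM-DD`).
#' @param mappings List of [new_assembly_mapping()].
#' @param xrefs List of [new_xref()].
#' @param legacy_maps List of [new_legacy_map()].
#' @param overlaps List of [new_overlap()].
#' @param notes Character vector of free-text notes.
#' @param extras Character vector of opaque XML fragments preserved verbatim
#'   from files written by other tools (forward compatibility).
#' @return An object of class `lrg_annotation_set`.
#' @export
new_annotation_set <- function(source, modification_date,
                               mappings = list(), xrefs = list(),
                               legacy_maps = list(), overlaps = list(),
                               notes = character(), extras = character()) {
  structure(list(source = chr1(source, "source"),
                 modification_date = chr1(modification_date, "modification_date"),
                 mappings = mappings, xrefs = xrefs,
                 legacy_maps = legacy_maps, overlaps = overlaps,
                 notes = as.character(notes),
                 extras = as.character(extras)),
            class = "lrg_annotation_set")
}

#' Updatable-annotation layer
#'
#' @param annotation_sets List of [new_annotation_set()].
#' @return An object of class `lrg_updatable_annotation`.
#' @export
new_updatable_annotation <- function(annotation_sets = list()) {
  structure(list(annotation_sets = annotation_sets),
            class = "lrg_updatable_annotation")
}

#' A complete two-layer LRG record
#'
#' @param lrg_id Identifier of the form `"LRG_<positive integer>"`; never
#'   versioned — essential changes to fixed content require a new id (see
#'   [check_new_id_policy()]).
#' @param fixed [new_fixed_annotation()].
#' @param updatable [new_updatable_annotation()]; defaults to empty.
#' @return An object of class `lrg_record`.
#' @export
#' @examples
#' t <- new_transcript("t1",
#'   exons = list(new_exon(1, 9, 1, 9, 1, 2)),
#'   coding_region = new_coding_region(1, 9),
#'   cdna_sequence = "ATGGGCTGA",
#'   protein = new_protein("p1", "MG"))
#' r <- lrg_record("LRG_1", new_fixed_annotation("ATGGGCTGA", list(t)))
#' validate_record(r)
lrg_record <- function(lrg_id, fixed, updatable = new_updatable_annotation()) {
  structure(list(lrg_id = chr1(lrg_id, "lrg_id"),
                 fixed = fixed,
                 updatable = updatable),
            class = "lrg_record")
}

#' @export
print.lrg_record <- function(x, ...) {
  cat(sprintf("<lrg_record %s>\n", x$lrg_id))
  cat(sprintf("  fixed layer: %d nt genomic sequence, %d transcript(s)\n",
              nchar(x$fixed$sequence), length(x$fixed$transcripts)))
  for (t in x$fixed$transcripts) {
    cds <- if (is.null(t$coding_region)) "non-coding" else
      sprintf("CDS %d..%d", t$coding_region$cds_start, t$coding_region$cds_end)
    cat(sprintf("    %s: %d exon(s), %s\n", t$name, length(t$exons), cds))
  }
  cat(sprintf("  updatable layer: %d annotation set(s)\n",
              length(x$updatable$annotation_sets)))
  invisible(x)
}

#' @export
print.lrg_transcript <- function(x, ...) {
  cat(sprintf("<lrg_transcript %s: %d exon(s), cDNA %d nt%s>\n",
              x$name, length(x$exons), nchar(x$cdna_sequence),
              if (is.null(x$coding_region)) ", non-coding" else ""))
  invisible(x)
}

# exon length helpers used across modules
exon_len <- function(ex) ex$lrg_end - ex$lrg_start + 1L

transcript_span <- function(transcript) {
  exs <- transcript$exons
  c(exs[[1]]$lrg_start, exs[[length(exs)]]$lrg_end)
}
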
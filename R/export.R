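# Human-readable rendering and interchange-format export.  Everything
# internal stays 1-based inclusive; the BED writer converts to 0-based
# half-open at this boundary only.

#' Plain-text summary of a record
#'
#' Deterministic report in the spirit of a style-sheet transform of the
#' XML: identifier, sequence length, per-transcript exon tables in all
#' three coordinate systems, CDS bounds, mappings (with explicit strand
#' markers), cross-references and legacy maps.
#'
#' @param record A valid [lrg_record()].
#' @return A single string (embedded newlines).
#' @export
render_text <- function(record) {
  out <- character()
  push <- function(...) out <<- c(out, sprintf(...))
  push("record %s", record$lrg_id)
  push("organism %s (taxon %d)", record$fixed$organism, record$fixed$taxon_id)
  push("sequence_length %d", nchar(record$fixed$sequence))
  push("fixed_digest %s", fixed_layer_digest(record))
  for (t in record$fixed$transcripts) {
    cr <- t$coding_region
    push("transcript %s exons %d cdna_length %d %s", t$name, length(t$exons),
         nchar(t$cdna_sequence),
         if (is.null(cr)) "non-coding" else
           sprintf("cds %d..%d protein %s (%d aa)", cr$cds_start, cr$cds_end,
                   t$protein$name, nchar(t$protein$sequence)))
    push("  exon\tlrg_start\tlrg_end\tcdna_start\tcdna_end\tpeptide_start\tpeptide_end")
    for (i in seq_along(t$exons)) {
      ex <- t$exons[[i]]
      push("  %d\t%d\t%d\t%d\t%d\t%s\t%s", i, ex$lrg_start, ex$lrg_end,
           ex$cdna_start, ex$cdna_end,
           ex$peptide_start %||% ".", ex$peptide_end %||% ".")
    }
  }
  for (s in record$updatable$annotation_sets) {
    push("annotation_set source=%s date=%s", s$source, s$modification_date)
    for (m in s$mappings) {
      for (sp in m$spans) {
        push("  mapping %s %s lrg %d..%d -> %d..%d strand %s diffs %d",
             m$assembly_name, m$other_accession, sp$lrg_start, sp$lrg_end,
             sp$other_start, sp$other_end,
             if (sp$strand > 0) "+" else "-", length(sp$diffs))
      }
    }
    for (x in s$xrefs) {
      push("  xref %s %s%s%s", x$source_db, x$accession,
           if (is.null(x$version)) "" else sprintf(".%d", x$version),
           if (x$identical_to_lrg) " identical_to_lrg" else "")
    }
    for (lm in s$legacy_maps) {
      push("  legacy_map %s exon_labels %d residue_ranges %d",
           lm$scheme_name, length(lm$exon_labels), nrow(lm$residue_shifts))
    }
    for (o in s$overlaps) {
      push("  overlap %s strand %s", o$id, if (o$strand > 0) "+" else "-")
    }
  }
  paste(out, collapse = "\n")
}

wrap60 <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = 60L)
  substring(seq, starts, pmin(starts + 59L, n))
}

#' Export record sequences as FASTA
#'
#' Headers are `<lrg_id>` for the genomic sequence, `<lrg_id>t<k>` for a
#' cDNA and `<lrg_id>p<k>` for a protein; lines wrap at 60 columns.
#'
#' @param record An [lrg_record()].
#' @param what `"genomic"`, `"cdna"` or `"protein"`.
#' @param transcript Transcript name (required for `cdna`/`protein`);
#'   `NULL` exports all transcripts.
#' @return FASTA text (single string).
#' @export
export_fasta <- function(record, what = c("genomic", "cdna", "protein"),
                         transcript = NULL) {
  what <- match.arg(what)
  if (what == "genomic") {
    return(paste(c(paste0(">", record$lrg_id),
                   wrap60(record$fixed$sequence)), collapse = "\n"))
  }
  trs <- record$fixed$transcripts
  if (!is.null(transcript)) {
    trs <- list(get_transcript(record, transcript))
  }
  blocks <- lapply(trs, function(t) {
    if (what == "cdna") {
      c(paste0(">", record$lrg_id, t$name), wrap60(t$cdna_sequence))
    } else {
      if (is.null(t$protein)) {
        stop(sprintf("transcript %s is non-coding: no protein to export",
                     t$name), call. = FALSE)
      }
      c(paste0(">", record$lrg_id, t$protein$name), wrap60(t$protein$sequence))
    }
  })
  paste(unlist(blocks), collapse = "\n")
}

# map an exon through a mapping, requiring a collinear (uninterrupted)
# projection; returns c(lo, hi) on the target
project_exon <- function(mapping, ex) {
  a <- map_lrg_to_other(mapping, ex$lrg_start)
  b <- map_lrg_to_other(mapping, ex$lrg_end)
  lo <- min(a$position, b$position)
  hi <- max(a$position, b$position)
  if (hi - lo != ex$lrg_end - ex$lrg_start) {
    stop(sprintf("exon %d..%d is interrupted by mapping diffs; cannot project as one block",
                 ex$lrg_start, ex$lrg_end), call. = FALSE)
  }
  c(lo, hi)
}

#' Export transcripts as BED12 through an assembly mapping
#'
#' One line per transcript, in the target frame of the mapping.  BED is
#' 0-based half-open; the conversion from the package's 1-based inclusive
#' coordinates happens here and only here.  On a minus-strand mapping the
#' exon blocks come out in target order (reversed relative to the
#' transcript).  A transcript with an exon interrupted by an insertion
#' diff is skipped; its error is reported in the `errors` attribute of the
#' result.
#'
#' @param record An [lrg_record()].
#' @param mapping An [new_assembly_mapping()] of the record.
#' @return BED12 text; attribute `errors` carries one message per skipped
#'   transcript (empty when all exported).
#' @export
export_bed <- function(record, mapping) {
  lines <- character()
  errors <- character()
  for (t in record$fixed$transcripts) {
    res <- tryCatch(bed_line(record, mapping, t), error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", t$name, conditionMessage(res)))
    } else {
      lines <- c(lines, res)
    }
  }
  structure(paste(lines, collapse = "\n"), errors = errors)
}

bed_line <- function(record, mapping, t) {
  blocks <- lapply(t$exons, function(ex) project_exon(mapping, ex))
  los <- vapply(blocks, `[`, integer(1), 1L)
  his <- vapply(blocks, `[`, integer(1), 2L)
  o <- order(los)
  los <- los[o]; his <- his[o]
  chrom_start <- los[1] - 1L          # 0-based
  chrom_end <- his[length(his)]       # half-open
  strand <- map_lrg_to_other(mapping, t$exons[[1]]$lrg_start)$strand
  if (is.null(t$coding_region)) {
    thick <- c(chrom_start, chrom_start)
  } else {
    ca <- map_lrg_to_other(mapping, t$coding_region$cds_start)$position
    cb <- map_lrg_to_other(mapping, t$coding_region$cds_end)$position
    thick <- c(min(ca, cb) - 1L, max(ca, cb))
  }
  paste(c(mapping$other_accession, chrom_start, chrom_end,
          paste0(record$lrg_id, t$name), 0L,
          if (strand > 0) "+" else "-",
          thick[1], thick[2], "0", length(los),
          paste0(paste(his - los + 1L, collapse = ","), ","),
          paste0(paste(los - 1L - chrom_start, collapse = ","), ",")),
        collapse = "\t")
}

#' Export the gene model as GFF3 in LRG coordinates
#'
#' Emits gene, mRNA, exon and CDS features on the record's own sequence
#' (seqid = the LRG id), 1-based inclusive per the GFF3 standard, with
#' `ID`/`Parent` attributes linking the hierarchy and CDS phase computed
#' from the reading frame.
#'
#' @param record An [lrg_record()].
#' @return GFF3 text (single string, with `##gff-version 3` header).
#' @export
export_gff3 <- function(record) {
  id <- record$lrg_id
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", id,
                     nchar(record$fixed$sequence)))
  trs <- record$fixed$transcripts
  if (length(trs) > 0L) {
    spans <- vapply(trs, transcript_span, integer(2))
    gene_id <- paste0(id, ".gene")
    lines <- c(lines, paste(c(id, "lrgkit", "gene", min(spans[1, ]),
                              max(spans[2, ]), ".", "+", ".",
                              paste0("ID=", gene_id)), collapse = "\t"))
    for (t in trs) {
      sp <- transcript_span(t)
      t_id <- paste0(id, t$name)
      lines <- c(lines, paste(c(id, "lrgkit", "mRNA", sp[1], sp[2], ".", "+",
                                ".", sprintf("ID=%s;Parent=%s", t_id, gene_id)),
                              collapse = "\t"))
      for (i in seq_along(t$exons)) {
        ex <- t$exons[[i]]
        lines <- c(lines, paste(c(id, "lrgkit", "exon", ex$lrg_start,
                                  ex$lrg_end, ".", "+", ".",
                                  sprintf("ID=%s.exon%d;Parent=%s", t_id, i, t_id)),
                                collapse = "\t"))
      }
      if (!is.null(t$coding_region)) {
        cr <- t$coding_region
        consumed <- 0L
        for (i in seq_along(t$exons)) {
          ex <- t$exons[[i]]
          lo <- max(ex$lrg_start, cr$cds_start)
          hi <- min(ex$lrg_end, cr$cds_end)
          if (lo > hi) next
          phase <- (3L - consumed %% 3L) %% 3L
          lines <- c(lines, paste(c(id, "lrgkit", "CDS", lo, hi, ".", "+",
                                    phase,
                                    sprintf("ID=%s.cds;Parent=%s", t_id, t_id)),
                                  collapse = "\t"))
          consumed <- consumed + (hi - lo + 1L)
        }
      }
    }
  }
  paste(lines, collapse = "\n")
}
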
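# The coordinate algebra: g. <-> c. with intron offsets and UTR numbering,
# c. -> p. codon arithmetic, strand-aware LRG <-> assembly mapping, and
# legacy renumbering.
#
# Conventions (documented once, used everywhere):
#   * all positions 1-based inclusive;
#   * c. anchors: CDS bases are 1..cds_len (stop codon included); the base
#     immediately 5' of c.1 is c.-1 (no zero); the base immediately 3' of
#     the stop codon is c.*1;
#   * intron offsets: positions in the proximal half of an intron anchor to
#     the upstream exon's last base with "+k"; the distal half anchors to
#     the downstream exon's first base with "-k"; an equidistant middle
#     base belongs to the "+" side;
#   * positions 5' of the first exon or 3' of the last exon are errors, not
#     extended UTR labels.

#' Coding-DNA (c.) position
#'
#' @param region `"CDS"`, `"UTR5"` or `"UTR3"`.
#' @param anchor Anchor coordinate: `1..cds_len` for CDS, negative for the
#'   5' UTR (counting away from c.1), positive for the 3' UTR (rendered
#'   `*n`, counting away from the stop codon).  Never zero.
#' @param intron_offset Signed offset into an intron from the anchored
#'   exon-boundary base; `0` for exonic positions.
#' @return An object of class `lrg_coding_position`.
#' @export
#' @examples
#' new_coding_position("CDS", 2451, 77)   # c.2451+77
#' new_coding_position("UTR3", 46)        # c.*46
new_coding_position <- function(region, anchor, intron_offset = 0L) {
  region <- match.arg(region, c("CDS", "UTR5", "UTR3"))
  anchor <- int1(anchor, "anchor")
  intron_offset <- int1(intron_offset, "intron_offset")
  if (anchor == 0L) stop("anchor must be non-zero (there is no position 0)", call. = FALSE)
  if (region == "UTR5" && anchor > 0L) stop("UTR5 anchors are negative", call. = FALSE)
  if (region != "UTR5" && anchor < 0L) stop("only UTR5 anchors are negative", call. = FALSE)
  structure(list(region = region, anchor = anchor,
                 intron_offset = intron_offset),
            class = "lrg_coding_position")
}

#' @export
print.lrg_coding_position <- function(x, ...) {
  cat(sprintf("<c.%s>\n", format_coding_position(x)))
  invisible(x)
}

#' Render a coding position as HGVS location text
#'
#' @param c A [new_coding_position()].
#' @return A string such as `"2451+77"`, `"-12"`, `"*46"`.
#' @export
format_coding_position <- function(c) {
  anchor_txt <- switch(c$region,
    CDS = as.character(c$anchor),
    UTR5 = as.character(c$anchor),      # already carries its minus sign
    UTR3 = paste0("*", c$anchor))
  if (c$intron_offset == 0L) return(anchor_txt)
  paste0(anchor_txt, sprintf("%+d", c$intron_offset))
}

# cDNA coordinates of the CDS bounds; shared by the conversions below
cds_cdna_bounds <- function(transcript) {
  cr <- transcript$coding_region
  if (is.null(cr)) {
    stop(sprintf("transcript %s is non-coding; c. coordinates are undefined (n. numbering is not implemented)",
                 transcript$name), call. = FALSE)
  }
  c(lrg_to_cdna_pos(transcript$exons, cr$cds_start),
    lrg_to_cdna_pos(transcript$exons, cr$cds_end))
}

# label an exonic cDNA position relative to the CDS
cdna_pos_to_coding <- function(j, bounds) {
  if (j < bounds[1]) {
    new_coding_position("UTR5", j - bounds[1])
  } else if (j <= bounds[2]) {
    new_coding_position("CDS", j - bounds[1] + 1L)
  } else {
    new_coding_position("UTR3", j - bounds[2])
  }
}

coding_to_cdna_pos <- function(c, bounds) {
  switch(c$region,
    UTR5 = bounds[1] + c$anchor,
    CDS = bounds[1] + c$anchor - 1L,
    UTR3 = bounds[2] + c$anchor)
}

#' Convert an LRG genomic position to a coding-DNA position
#'
#' Exonic positions get an offset of zero; intronic positions anchor to the
#' nearest exon boundary under the midpoint convention (`+k` after a donor,
#' `-k` before an acceptor).  Exonic positions 5' of the start codon and 3'
#' of the stop codon are numbered as UTR positions.
#'
#' @param transcript A coding [new_transcript()].
#' @param g_pos LRG position within the transcript span
#'   (first exon start .. last exon end).
#' @return A [new_coding_position()].
#' @export
g_to_c <- function(transcript, g_pos) {
  g_pos <- int1(g_pos, "g_pos")
  bounds <- cds_cdna_bounds(transcript)
  span <- transcript_span(transcript)
  if (g_pos < span[1] || g_pos > span[2]) {
    stop(sprintf("position %d is outside the span of transcript %s (%d..%d)",
                 g_pos, transcript$name, span[1], span[2]), call. = FALSE)
  }
  exs <- transcript$exons
  ei <- exon_index_at(exs, g_pos)
  if (!is.na(ei)) {
    j <- lrg_to_cdna_pos(exs, g_pos)
    return(cdna_pos_to_coding(j, bounds))
  }
  # intronic: locate the surrounding exon pair
  for (i in seq_len(length(exs) - 1L)) {
    donor_end <- exs[[i]]$lrg_end
    acceptor_start <- exs[[i + 1L]]$lrg_start
    if (g_pos > donor_end && g_pos < acceptor_start) {
      intron_len <- acceptor_start - donor_end - 1L
      d <- g_pos - donor_end
      if (d <= ceiling(intron_len / 2)) {
        anchor <- cdna_pos_to_coding(lrg_to_cdna_pos(exs, donor_end), bounds)
        anchor$intron_offset <- d
      } else {
        anchor <- cdna_pos_to_coding(lrg_to_cdna_pos(exs, acceptor_start), bounds)
        anchor$intron_offset <- -(acceptor_start - g_pos)
      }
      return(anchor)
    }
  }
  stop(sprintf("position %d could not be classified", g_pos), call. = FALSE) # nocov
}

#' Convert a coding-DNA position to an LRG genomic position
#'
#' Exact inverse of [g_to_c()] on its domain.  An intron offset that walks
#' past the midpoint convention into territory labelled from the opposite
#' boundary is rejected, so every accepted description has exactly one
#' genomic meaning.
#'
#' @param transcript A coding [new_transcript()].
#' @param c A [new_coding_position()].
#' @return Integer LRG position.
#' @export
c_to_g <- function(transcript, c) {
  stopifnot(inherits(c, "lrg_coding_position"))
  bounds <- cds_cdna_bounds(transcript)
  exs <- transcript$exons
  cdna_len <- nchar(transcript$cdna_sequence)
  j <- coding_to_cdna_pos(c, bounds)
  if (j < 1L || j > cdna_len) {
    stop(sprintf("anchor c.%s lies outside the transcript (cDNA length %d)",
                 format_coding_position(new_coding_position(c$region, c$anchor)),
                 cdna_len), call. = FALSE)
  }
  g_anchor <- cdna_to_lrg_pos(exs, j)
  off <- c$intron_offset
  if (off == 0L) return(g_anchor)
  if (off > 0L) {
    ei <- exon_index_at(exs, g_anchor)
    if (is.na(ei) || g_anchor != exs[[ei]]$lrg_end || ei == length(exs)) {
      stop(sprintf("'+%d' offset requires the anchor to be an exon's last base (a donor site)",
                   off), call. = FALSE)
    }
    intron_len <- exs[[ei + 1L]]$lrg_start - exs[[ei]]$lrg_end - 1L
    if (off > ceiling(intron_len / 2)) {
      stop(sprintf("offset +%d walks past the midpoint of the %d nt intron; that territory is labelled '-k' from the downstream exon",
                   off, intron_len), call. = FALSE)
    }
    return(g_anchor + off)
  }
  ei <- exon_index_at(exs, g_anchor)
  if (is.na(ei) || g_anchor != exs[[ei]]$lrg_start || ei == 1L) {
    stop(sprintf("'%d' offset requires the anchor to be an exon's first base (an acceptor site)",
                 off), call. = FALSE)
  }
  intron_len <- exs[[ei]]$lrg_start - exs[[ei - 1L]]$lrg_end - 1L
  if (-off > intron_len - ceiling(intron_len / 2)) {
    stop(sprintf("offset %d walks past the midpoint of the %d nt intron; that territory is labelled '+k' from the upstream exon",
                 off, intron_len), call. = FALSE)
  }
  g_anchor + off
}

#' Protein residue index of a CDS position
#'
#' Codon arithmetic: residue `floor((anchor - 1)/3) + 1`.  Only exonic CDS
#' positions have a residue; UTR or intronic positions are errors.
#'
#' @param c A [new_coding_position()] with `region == "CDS"` and zero
#'   intron offset.
#' @return Integer residue index (the stop codon maps to one past the last
#'   residue of the stored protein).
#' @export
#' @examples
#' c_to_p(new_coding_position("CDS", 572))  # 191
c_to_p <- function(c) {
  stopifnot(inherits(c, "lrg_coding_position"))
  if (c$region != "CDS") {
    stop(sprintf("c.%s is in the %s; no protein residue exists there",
                 format_coding_position(c),
                 if (c$region == "UTR5") "5' UTR" else "3' UTR"), call. = FALSE)
  }
  if (c$intron_offset != 0L) {
    stop(sprintf("c.%s is intronic; no protein residue exists there",
                 format_coding_position(c)), call. = FALSE)
  }
  (c$anchor - 1L) %/% 3L + 1L
}

## ---- assembly mapping ----------------------------------------------------

#' Position mapped into another reference frame
#'
#' @param accession Target sequence identifier.
#' @param position 1-based coordinate on the target.
#' @param strand `+1` or `-1`.
#' @return An object of class `lrg_mapped_position`.
#' @export
new_mapped_position <- function(accession, position, strand) {
  structure(list(accession = chr1(accession, "accession"),
                 position = int1(position, "position"),
                 strand = int1(strand, "strand")),
            class = "lrg_mapped_position")
}

#' @export
print.lrg_mapped_position <- function(x, ...) {
  cat(sprintf("<%s:%d (%s)>\n", x$accession, x$position,
              if (x$strand > 0) "+" else "-"))
  invisible(x)
}

# Compile a span into aligned blocks.  Each block is one row:
#   kind       "match" (collinear; mismatch diffs stay collinear),
#              "lrg_ins" (bases only in the LRG), or
#              "other_ins" (bases only in the other sequence)
#   lrg_start, lrg_end     LRG interval (empty for other_ins: end < start)
#   other_first            other coordinate of the block's first LRG base
#                          (for match blocks; NA otherwise)
#   other_lo, other_hi     other-forward interval covered (match/other_ins)
# Walking is LRG-forward; with strand -1 the other cursor runs downward.
# Also verifies the span geometry: after accounting for every diff, the two
# declared intervals must close exactly.
compile_span <- function(span) {
  diffs <- span$diffs
  if (length(diffs) > 0L) {
    o <- order(vapply(diffs, function(d) d$lrg_start, integer(1)))
    diffs <- diffs[o]
  }
  dirn <- span$strand
  cur_l <- span$lrg_start
  cur_o <- if (dirn > 0L) span$other_start else span$other_end
  blocks <- list()
  emit_match <- function(len) {
    if (len <= 0L) return()
    blk <- list(kind = "match", lrg_start = cur_l, lrg_end = cur_l + len - 1L,
                other_first = cur_o,
                other_lo = min(cur_o, cur_o + dirn * (len - 1L)),
                other_hi = max(cur_o, cur_o + dirn * (len - 1L)))
    blocks[[length(blocks) + 1L]] <<- blk
    cur_l <<- cur_l + len
    cur_o <<- cur_o + dirn * len
  }
  for (d in diffs) {
    llen <- max(0L, d$lrg_end - d$lrg_start + 1L)
    olen <- max(0L, d$other_end - d$other_start + 1L)
    ok_shape <- switch(d$kind,
      mismatch = llen > 0L && llen == olen,
      lrg_insertion = llen > 0L && olen == 0L,
      other_insertion = llen == 0L && olen > 0L)
    if (!ok_shape) {
      stop(sprintf("diff of kind %s has inconsistent interval lengths (%d vs %d)",
                   d$kind, llen, olen), call. = FALSE)
    }
    gap <- d$lrg_start - cur_l
    if (gap < 0L) stop("diffs overlap or are outside the span", call. = FALSE)
    emit_match(gap)
    if (d$kind == "mismatch") {
      emit_match(llen)                     # collinear in coordinates
    } else if (d$kind == "lrg_insertion") {
      blocks[[length(blocks) + 1L]] <- list(
        kind = "lrg_ins", lrg_start = cur_l, lrg_end = cur_l + llen - 1L,
        other_first = NA_integer_, other_lo = NA_integer_, other_hi = NA_integer_)
      cur_l <- cur_l + llen
    } else {                               # other_insertion
      lo <- if (dirn > 0L) cur_o else cur_o - olen + 1L
      blocks[[length(blocks) + 1L]] <- list(
        kind = "other_ins", lrg_start = cur_l, lrg_end = cur_l - 1L,
        other_first = NA_integer_, other_lo = lo, other_hi = lo + olen - 1L)
      cur_o <- cur_o + dirn * olen
    }
  }
  emit_match(span$lrg_end - cur_l + 1L)
  end_expected <- if (dirn > 0L) span$other_end + 1L else span$other_start - 1L
  if (cur_l != span$lrg_end + 1L || cur_o != end_expected) {
    stop(sprintf("span geometry does not close: LRG %d..%d vs other %d..%d with the declared diffs",
                 span$lrg_start, span$lrg_end, span$other_start, span$other_end),
         call. = FALSE)
  }
  blocks
}

#' Map an LRG position into an assembly/contig frame
#'
#' Forward spans map collinearly (`other_start + (lrg_pos - lrg_start)`,
#' shifted by any preceding insertion diffs); reverse spans count downward
#' from `other_end`.  Positions falling inside bases present only in the
#' LRG (an `lrg_insertion` diff) are unmappable; the error names the
#' nearest flanking mapped positions.
#'
#' @param mapping An [new_assembly_mapping()].
#' @param lrg_pos LRG position covered by one of the mapping's spans.
#' @return A [new_mapped_position()].
#' @export
map_lrg_to_other <- function(mapping, lrg_pos) {
  lrg_pos <- int1(lrg_pos, "lrg_pos")
  for (span in mapping$spans) {
    if (lrg_pos < span$lrg_start || lrg_pos > span$lrg_end) next
    blocks <- compile_span(span)
    for (b in blocks) {
      if (b$kind == "other_ins") next
      if (lrg_pos >= b$lrg_start && lrg_pos <= b$lrg_end) {
        if (b$kind == "lrg_ins") {
          fl <- insertion_flanks(blocks, lrg_pos)
          stop(sprintf("LRG position %d lies in bases absent from %s; nearest mapped flanks are LRG %s and %s",
                       lrg_pos, mapping$other_accession, fl[1], fl[2]),
               call. = FALSE)
        }
        pos <- b$other_first + span$strand * (lrg_pos - b$lrg_start)
        return(new_mapped_position(mapping$other_accession, pos, span$strand))
      }
    }
  }
  stop(sprintf("LRG position %d is not covered by any mapping span of %s (gap in the mapping)",
               lrg_pos, mapping$other_accession), call. = FALSE)
}

insertion_flanks <- function(blocks, lrg_pos) {
  left <- NA_integer_; right <- NA_integer_
  for (b in blocks) {
    if (b$kind != "match") next
    if (b$lrg_end < lrg_pos) left <- b$lrg_end
    if (b$lrg_start > lrg_pos && is.na(right)) right <- b$lrg_start
  }
  c(ifelse(is.na(left), "none", left), ifelse(is.na(right), "none", right))
}

#' Map an assembly/contig position back onto the LRG
#'
#' Exact inverse of [map_lrg_to_other()] on mapped bases.  Positions inside
#' bases present only in the other sequence (an `other_insertion` diff) are
#' unmappable and reported with their flanks; positions outside every span
#' are errors.
#'
#' @param mapping An [new_assembly_mapping()].
#' @param accession Target accession; must equal the mapping's.
#' @param pos 1-based position on the target sequence.
#' @return Integer LRG position.
#' @export
map_other_to_lrg <- function(mapping, accession, pos) {
  pos <- int1(pos, "pos")
  if (!identical(accession, mapping$other_accession)) {
    stop(sprintf("mapping targets %s, not %s",
                 mapping$other_accession, accession), call. = FALSE)
  }
  for (span in mapping$spans) {
    lo <- min(span$other_start, span$other_end)
    hi <- max(span$other_start, span$other_end)
    if (pos < lo || pos > hi) next
    blocks <- compile_span(span)
    for (b in blocks) {
      if (b$kind == "lrg_ins") next
      if (!is.na(b$other_lo) && pos >= b$other_lo && pos <= b$other_hi) {
        if (b$kind == "other_ins") {
          stop(sprintf("%s position %d lies in bases absent from the LRG; flanking LRG positions are %d and %d",
                       accession, pos, b$lrg_end, b$lrg_start), call. = FALSE)
        }
        return(b$lrg_start + span$strand * (pos - b$other_first))
      }
    }
  }
  stop(sprintf("%s position %d is not covered by the mapping", accession, pos),
       call. = FALSE)
}

## ---- legacy numbering ----------------------------------------------------

#' Legacy label of an exon
#'
#' @param map A [new_legacy_map()].
#' @param exon_ordinal Systematic (fixed-layer) exon ordinal.
#' @return A list with `label` (string), `scheme` and `systematic` — the
#'   latter `TRUE` when the scheme lacks the ordinal and the systematic
#'   number is returned as a fallback.
#' @export
legacy_exon_label <- function(map, exon_ordinal) {
  exon_ordinal <- int1(exon_ordinal, "exon_ordinal")
  key <- as.character(exon_ordinal)
  if (key %in% names(map$exon_labels)) {
    list(label = map$exon_labels[[key]], scheme = map$scheme_name,
         systematic = FALSE)
  } else {
    list(label = key, scheme = map$scheme_name, systematic = TRUE)
  }
}

#' Legacy number of a protein residue
#'
#' Applies `legacy = systematic - shift` for the declared range covering
#' the residue (for example mature-protein numbering that discounts a
#' cleaved signal peptide or propeptide).
#'
#' @param map A [new_legacy_map()].
#' @param residue Systematic residue index.
#' @return A list with `legacy` (integer) and `scheme`.
#' @export
legacy_residue_number <- function(map, residue) {
  residue <- int1(residue, "residue")
  rs <- map$residue_shifts
  hit <- which(residue >= rs$start & residue <= rs$end)
  if (length(hit) == 0L) {
    ranges <- paste(sprintf("%d..%d", rs$start, rs$end), collapse = ", ")
    stop(sprintf("residue %d is outside every declared legacy range of scheme '%s' (%s)",
                 residue, map$scheme_name,
                 if (nzchar(ranges)) ranges else "no ranges declared"),
         call. = FALSE)
  }
  list(legacy = residue - rs$shift[hit[1]], scheme = map$scheme_name)
}
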
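# Parse, format and translate HGVS-style variant descriptions between
# coordinate systems (g., c., p.) and reference frames.  Single-nucleotide
# substitutions (and their protein consequences) are the supported core;
# del/dup/ins descriptions parse to a structured "unsupported" edit that
# formats back losslessly but cannot be converted between frames.

#' Variant description bound to a reference frame
#'
#' @param system `"g"`, `"c"` or `"p"`.
#' @param location For `g`: integer LRG/contig position; for `c`: a
#'   [new_coding_position()]; for `p`: integer residue index.
#' @param edit For `g`/`c`: `list(type = "sub", ref =, alt =)` with single
#'   bases, or `list(type = "unsupported", text =)`; for `p`:
#'   `list(type = "sub", ref =, alt =)` with 3-letter residue codes
#'   (`"Ter"` for a stop) or `list(type = "synonymous")`.
#' @param reference Reference identifier (`"LRG_1"`, `"LRG_1t1"`,
#'   `"NM_000088.3"`, ...) or `NULL`.
#' @return An object of class `lrg_variant`.
#' @export
new_variant <- function(system, location, edit, reference = NULL) {
  system <- match.arg(system, c("g", "c", "p"))
  if (system == "c" && !inherits(location, "lrg_coding_position")) {
    stop("c-system variants need an lrg_coding_position location", call. = FALSE)
  }
  if (system != "c") location <- int1(location, "location")
  structure(list(reference = if (!is.null(reference)) chr1(reference, "reference"),
                 system = system, location = location, edit = edit),
            class = "lrg_variant")
}

#' @export
print.lrg_variant <- function(x, ...) {
  cat(sprintf("<variant %s>\n", format_hgvs(x)))
  invisible(x)
}

hgvs_error <- function(message, offset = NA_integer_, class = "lrg_hgvs_error") {
  stop(errorCondition(
    if (is.na(offset)) message else
      sprintf("%s (at character %d)", message, offset),
    offset = offset, class = c(class, "lrg_error", "error", "condition")))
}

REF_RE <- "^(LRG_[1-9][0-9]*(?:[tp][1-9][0-9]*)?|[A-Za-z][A-Za-z0-9_]*\\.[0-9]+)$"

# expected system letter implied by a reference id, NA if unconstrained
implied_system <- function(reference) {
  if (grepl("^LRG_[0-9]+t[0-9]+$", reference)) return("c")
  if (grepl("^LRG_[0-9]+p[0-9]+$", reference)) return("p")
  if (grepl("^LRG_[0-9]+$", reference)) return("g")
  if (grepl("^NM_", reference)) return("c")
  if (grepl("^NP_", reference)) return("p")
  if (grepl("^(NG_|NT_|NC_)", reference)) return("g")
  NA_character_
}

#' Parse an HGVS-style variant description
#'
#' Grammar: `[reference ":"] system "." location edit`, where `system` is
#' `g`, `c` or `p`; `c` locations support `n`, `-n`, `*n` anchors with
#' optional `+k`/`-k` intron offsets; edits are single-base substitutions
#' (`C>A`), 3-letter protein substitutions (`Gly191Ala`), `(=)`
#' (synonymous), or del/dup/ins text retained verbatim as an unsupported
#' edit.  The deprecated IVS intron notation is refused with a dedicated
#' error directing callers to [ivs_to_c()].
#'
#' @param text One description.
#' @return An [new_variant()].
#' @export
#' @examples
#' parse_hgvs("LRG_13:g.8290C>A")
#' parse_hgvs("c.2451+77C>T")
parse_hgvs <- function(text) {
  text <- chr1(text, "text")
  reference <- NULL
  body <- text
  body_off <- 0L
  colon <- regexpr(":", text, fixed = TRUE)
  if (colon > 0L) {
    reference <- substr(text, 1L, colon - 1L)
    if (!grepl(REF_RE, reference)) {
      hgvs_error(sprintf("malformed reference identifier '%s'", reference), 1L)
    }
    body <- substr(text, colon + 1L, nchar(text))
    body_off <- colon
  }
  if (grepl("^IVS", body)) {
    hgvs_error(paste0("'", body, "' uses the deprecated IVS intron notation; ",
                      "convert it with ivs_to_c() against the transcript's exon structure"),
               body_off + 1L, class = "lrg_hgvs_deprecated_ivs")
  }
  m <- regexec("^([gcp])\\.(.*)$", body)[[1]]
  if (m[1] == -1L) {
    hgvs_error("expected coordinate system prefix 'g.', 'c.' or 'p.'",
               body_off + 1L)
  }
  system <- substr(body, m[2], m[2] + attr(m, "match.length")[2] - 1L)
  rest <- substr(body, m[3], nchar(body))
  rest_off <- body_off + 2L
  if (!is.null(reference)) {
    want <- implied_system(reference)
    if (!is.na(want) && want != system) {
      hgvs_error(sprintf("reference '%s' implies the '%s.' system, not '%s.'",
                         reference, want, system), body_off + 1L)
    }
  }
  v <- switch(system,
    g = parse_g_body(rest, rest_off),
    c = parse_c_body(rest, rest_off),
    p = parse_p_body(rest, rest_off))
  if (!is.null(reference)) v$reference <- reference
  v
}

parse_g_body <- function(rest, off) {
  m <- regexec("^([0-9]+)(.*)$", rest)[[1]]
  if (m[1] == -1L) hgvs_error("expected a genomic position", off + 1L)
  pos <- as.integer(substr(rest, m[2], m[2] + attr(m, "match.length")[2] - 1L))
  edit <- parse_nt_edit(substr(rest, m[3], nchar(rest)),
                        off + attr(m, "match.length")[2])
  new_variant("g", pos, edit)
}

parse_c_body <- function(rest, off) {
  m <- regexec("^(\\*?)(-?[0-9]+)([+-][0-9]+)?(.*)$", rest)[[1]]
  if (m[1] == -1L) hgvs_error("expected a coding-DNA position", off + 1L)
  pick <- function(i) substr(rest, m[i], m[i] + attr(m, "match.length")[i] - 1L)
  star <- pick(2); anchor <- as.integer(pick(3)); off_txt <- pick(4)
  if (anchor == 0L) hgvs_error("there is no position c.0", off + 1L)
  region <- if (star == "*") "UTR3" else if (anchor < 0L) "UTR5" else "CDS"
  if (star == "*" && anchor < 0L) {
    hgvs_error("a '*' anchor cannot be negative", off + 1L)
  }
  intron_offset <- if (nzchar(off_txt)) as.integer(off_txt) else 0L
  if (nzchar(off_txt) && intron_offset == 0L) {
    hgvs_error("an intron offset of 0 is not a position", off + 1L)
  }
  loc <- new_coding_position(region, anchor, intron_offset)
  consumed <- sum(attr(m, "match.length")[2:4], na.rm = TRUE)
  edit <- parse_nt_edit(pick(5), off + consumed)
  new_variant("c", loc, edit)
}

parse_nt_edit <- function(rest, off) {
  m <- regexec("^([ACGT])>([ACGT])$", rest)[[1]]
  if (m[1] != -1L) {
    pick <- function(i) substr(rest, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    return(list(type = "sub", ref = pick(2), alt = pick(3)))
  }
  if (grepl("^(_[0-9]+)?(del|dup|ins)[ACGT]*$", rest)) {
    return(list(type = "unsupported", text = rest))
  }
  hgvs_error(sprintf("malformed edit '%s' (expected e.g. 'C>A', or del/dup/ins)",
                     rest), off + 1L)
}

parse_p_body <- function(rest, off) {
  if (identical(rest, "(=)")) {
    return(new_variant("p", 0L, list(type = "synonymous")))
  }
  m <- regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", rest)[[1]]
  if (m[1] == -1L) {
    hgvs_error("expected a protein substitution like 'Gly191Ala' or '(=)'",
               off + 1L)
  }
  pick <- function(i) substr(rest, m[i], m[i] + attr(m, "match.length")[i] - 1L)
  ref3 <- pick(2); residue <- as.integer(pick(3)); alt3 <- pick(4)
  for (code in c(ref3, alt3)) {
    if (!code %in% AA_THREE) {
      hgvs_error(sprintf("unknown residue code '%s'", code), off + 1L)
    }
  }
  new_variant("p", residue, list(type = "sub", ref = ref3, alt = alt3))
}

#' Format a variant description as canonical HGVS-style text
#'
#' `parse_hgvs(format_hgvs(v))` recovers `v` for every supported
#' description.
#'
#' @param v An [new_variant()].
#' @return A single string.
#' @export
format_hgvs <- function(v) {
  stopifnot(inherits(v, "lrg_variant"))
  prefix <- if (is.null(v$reference)) "" else paste0(v$reference, ":")
  body <- switch(v$system,
    g = paste0(v$location, format_edit_nt(v$edit)),
    c = paste0(format_coding_position(v$location), format_edit_nt(v$edit)),
    p = if (identical(v$edit$type, "synonymous")) "(=)" else
        paste0(v$edit$ref, v$location, v$edit$alt))
  paste0(prefix, v$system, ".", body)
}

format_edit_nt <- function(edit) {
  switch(edit$type,
    sub = paste0(edit$ref, ">", edit$alt),
    unsupported = edit$text,
    stop("unknown edit type: ", edit$type, call. = FALSE))
}

#' Convert a deprecated IVS intron description to c. notation
#'
#' `IVS<k>+<n>` anchors to the last base of exon `k` (the donor side);
#' `IVS<k>-<n>` anchors to the first base of exon `k+1` (the acceptor
#' side); the offset is preserved.
#'
#' @param transcript A coding [new_transcript()] with at least `k + 1`
#'   exons.
#' @param ivs_text A description like `"IVS36+77C>T"`.
#' @return A c-system [new_variant()] with no reference id.
#' @export
ivs_to_c <- function(transcript, ivs_text) {
  ivs_text <- chr1(ivs_text, "ivs_text")
  m <- regexec("^IVS([0-9]+)([+-][0-9]+)(.*)$", ivs_text)[[1]]
  if (m[1] == -1L) {
    hgvs_error(sprintf("'%s' is not an IVS intron description", ivs_text), 1L)
  }
  pick <- function(i) substr(ivs_text, m[i], m[i] + attr(m, "match.length")[i] - 1L)
  k <- as.integer(pick(2)); offset <- as.integer(pick(3))
  edit <- parse_nt_edit(pick(4), sum(attr(m, "match.length")[2:3]) + 3L)
  exs <- transcript$exons
  if (k < 1L || k + 1L > length(exs)) {
    stop(sprintf("intron %d does not exist: transcript %s has %d exons (%d introns)",
                 k, transcript$name, length(exs), length(exs) - 1L),
         call. = FALSE)
  }
  bounds <- cds_cdna_bounds(transcript)
  anchor_g <- if (offset > 0L) exs[[k]]$lrg_end else exs[[k + 1L]]$lrg_start
  loc <- cdna_pos_to_coding(lrg_to_cdna_pos(exs, anchor_g), bounds)
  loc$intron_offset <- offset
  new_variant("c", loc, edit)
}

ref_mismatch_error <- function(stated, actual, where) {
  stop(errorCondition(
    sprintf("REF_MISMATCH: description states reference base %s at %s but the record carries %s (check which reference sequence the description was written against)",
            stated, where, actual),
    class = c("lrg_ref_mismatch", "lrg_error", "error", "condition")))
}

get_transcript <- function(record, transcript_name) {
  for (t in record$fixed$transcripts) {
    if (identical(t$name, transcript_name)) return(t)
  }
  stop(sprintf("record %s has no transcript named '%s'",
               record$lrg_id, transcript_name), call. = FALSE)
}

#' Convert a genomic variant description to coding-DNA coordinates
#'
#' The position is converted with [g_to_c()]; the stated reference base is
#' checked against the record's genomic sequence (a mismatch is a
#' `REF_MISMATCH` error, never auto-corrected — the stated base is exactly
#' what makes descriptions checkable across reference versions); the
#' reference id is rewritten from `"LRG_n"` to `"LRG_nt<k>"`.
#'
#' @param record An [lrg_record()].
#' @param transcript_name Transcript to express the variant against.
#' @param v A g-system [new_variant()] with a substitution edit.
#' @return A c-system [new_variant()].
#' @export
g_variant_to_c <- function(record, transcript_name, v) {
  stopifnot(inherits(v, "lrg_variant"))
  if (v$system != "g") stop("expected a g-system variant", call. = FALSE)
  if (!identical(v$edit$type, "sub")) {
    stop("only substitution edits can be converted between systems",
         call. = FALSE)
  }
  t <- get_transcript(record, transcript_name)
  actual <- substr(record$fixed$sequence, v$location, v$location)
  if (!identical(actual, v$edit$ref)) {
    ref_mismatch_error(v$edit$ref, actual, sprintf("g.%d", v$location))
  }
  loc <- g_to_c(t, v$location)
  new_variant("c", loc, v$edit,
              reference = paste0(record$lrg_id, t$name))
}

#' Compute the protein consequence of a coding substitution
#'
#' The residue index comes from [c_to_p()]; the affected codon is mutated
#' and re-translated.  A synonymous change renders as `p.(=)`; a stop gain
#' uses the `Ter` residue code.  UTR or intronic input has no computable
#' protein consequence and is an error, as is a substitution destroying
#' the stop codon (protein extension is out of scope).
#'
#' @param record An [lrg_record()].
#' @param transcript_name Coding transcript name.
#' @param v A c-system [new_variant()] with a substitution edit, exonic and
#'   within the CDS (stop codon included).
#' @return A p-system [new_variant()].
#' @export
c_variant_to_p <- function(record, transcript_name, v) {
  stopifnot(inherits(v, "lrg_variant"))
  if (v$system != "c") stop("expected a c-system variant", call. = FALSE)
  if (!identical(v$edit$type, "sub")) {
    stop("only substitution edits can be converted between systems",
         call. = FALSE)
  }
  t <- get_transcript(record, transcript_name)
  loc <- v$location
  if (loc$region != "CDS" || loc$intron_offset != 0L) {
    stop(sprintf("c.%s is outside the CDS; no protein consequence is computed",
                 format_coding_position(loc)), call. = FALSE)
  }
  bounds <- cds_cdna_bounds(t)
  cds_seq <- substr(t$cdna_sequence, bounds[1], bounds[2])
  if (loc$anchor > nchar(cds_seq)) {
    stop(sprintf("c.%d is beyond the CDS (length %d)", loc$anchor,
                 nchar(cds_seq)), call. = FALSE)
  }
  actual <- substr(cds_seq, loc$anchor, loc$anchor)
  if (!identical(actual, v$edit$ref)) {
    ref_mismatch_error(v$edit$ref, actual,
                       sprintf("c.%d of %s", loc$anchor, t$name))
  }
  residue <- c_to_p(loc)
  codon_start <- 3L * (residue - 1L) + 1L
  codon <- substr(cds_seq, codon_start, codon_start + 2L)
  within <- loc$anchor - codon_start + 1L
  mutated <- codon
  substr(mutated, within, within) <- v$edit$alt
  table <- standard_codon_table()
  ref_aa <- unname(table[codon]); alt_aa <- unname(table[mutated])
  pref <- paste0(record$lrg_id, sub("^t", "p", sub(".*t", "t", t$name)))
  if (identical(ref_aa, alt_aa)) {
    return(new_variant("p", 0L, list(type = "synonymous"), reference = pref))
  }
  if (identical(ref_aa, "*")) {
    stop("substitution destroys the stop codon; protein extension is not supported",
         call. = FALSE)
  }
  new_variant("p", residue,
              list(type = "sub", ref = aa_one_to_three(ref_aa),
                   alt = aa_one_to_three(alt_aa)),
              reference = pref)
}

#' Re-express a variant description in another reference frame
#'
#' Two routes are supported.  Through a cross-reference flagged
#' `identical_to_lrg` (the matching RefSeqGene/mRNA/protein set), the
#' coordinates and edit carry over unchanged — only the reference id is
#' rewritten.  Through an assembly mapping, a g-system position is run
#' through [map_lrg_to_other()], and on a minus-strand mapping the edit
#' bases are complemented.
#'
#' @param record An [lrg_record()].
#' @param v An [new_variant()].
#' @param target_accession Versioned accession of the target frame.
#' @return An [new_variant()] in the target frame.
#' @export
translate_reference_frame <- function(record, v, target_accession) {
  stopifnot(inherits(v, "lrg_variant"))
  target_accession <- chr1(target_accession, "target_accession")
  identical_frames <- character()
  mapping_frames <- character()
  for (s in record$updatable$annotation_sets) {
    for (x in s$xrefs) {
      if (!isTRUE(x$identical_to_lrg)) next
      acc <- paste0(x$accession, ".", x$version)
      identical_frames <- c(identical_frames, acc)
      if (identical(acc, target_accession)) {
        out <- v
        out$reference <- target_accession
        return(out)
      }
    }
    for (m in s$mappings) {
      mapping_frames <- c(mapping_frames, m$other_accession)
      if (!identical(m$other_accession, target_accession)) next
      if (v$system != "g") {
        stop("only g-system descriptions can be projected through an assembly mapping",
             call. = FALSE)
      }
      if (!identical(v$edit$type, "sub")) {
        stop("only substitution edits can be projected through an assembly mapping",
             call. = FALSE)
      }
      mp <- map_lrg_to_other(m, v$location)
      edit <- v$edit
      if (mp$strand < 0L) {
        edit$ref <- complement_base(edit$ref)
        edit$alt <- complement_base(edit$alt)
      }
      return(new_variant("g", mp$position, edit,
                         reference = target_accession))
    }
  }
  avail <- unique(c(identical_frames, mapping_frames))
  stop(sprintf("no frame '%s' is declared by record %s; available frames: %s",
               target_accession, record$lrg_id,
               if (length(avail)) paste(avail, collapse = ", ") else "none"),
       call. = FALSE)
}
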
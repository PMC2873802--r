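# Record-level consistency validation.  Everything is reported as a
# finding, never thrown: the immutability guarantee of the fixed layer is
# only meaningful if a record's internal consistency can be checked
# mechanically, including on records that fail the check.

finding <- function(severity, code, location, message) {
  data.frame(severity = severity, code = code, location = location,
             message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(severity = character(), code = character(),
             location = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate an LRG record
#'
#' Checks every structural invariant of the two-layer model: identifier
#' format, sequence alphabet, exon ordering and bounds, cDNA/exon-markup
#' agreement (the stored cDNA must equal the spliced genomic slices),
#' coding-region frame and placement, protein/translation agreement,
#' annotation-set date stamps, mapping-span geometry, cross-reference
#' version rules and legacy-map ranges.
#'
#' Problems are returned as findings, never raised as conditions, and the
#' record is never mutated.  `N` bases are allowed in the genomic sequence
#' (warning) but are an error inside any CDS, since translation must be
#' deterministic.  A fixed layer with zero transcripts (pure regulatory
#' region) is permitted with a warning.
#'
#' @param record An [lrg_record()].
#' @return A data frame of findings with columns `severity` (`"error"` or
#'   `"warning"`), `code` (machine-readable), `location` (path into the
#'   record) and `message`.  Zero rows iff the record satisfies every
#'   invariant.
#' @export
validate_record <- function(record) {
  f <- no_findings()
  add <- function(severity, code, location, message) {
    f <<- rbind(f, finding(severity, code, location, message))
  }

  if (!grepl("^LRG_[1-9][0-9]*$", record$lrg_id)) {
    add("error", "LRG_ID_FORMAT", "lrg_id",
        sprintf("id '%s' does not match LRG_<positive integer>", record$lrg_id))
  }

  fx <- record$fixed
  seq <- fx$sequence
  n <- nchar(seq)
  if (n < 1L) {
    add("error", "SEQ_EMPTY", "fixed/sequence", "genomic sequence is empty")
  } else if (grepl("[^ACGTN]", seq)) {
    bad <- regexpr("[^ACGTN]", seq)
    add("error", "SEQ_ALPHABET", "fixed/sequence",
        sprintf("invalid character '%s' at position %d",
                substr(seq, bad, bad), bad))
  } else if (grepl("N", seq, fixed = TRUE)) {
    add("warning", "SEQ_N", "fixed/sequence",
        "genomic sequence contains N bases")
  }

  trs <- fx$transcripts
  if (length(trs) == 0L) {
    add("warning", "NO_TRANSCRIPTS", "fixed/transcripts",
        "fixed layer has no transcripts (pure regulatory region?)")
  }
  expected_names <- paste0("t", seq_along(trs))
  actual_names <- vapply(trs, function(t) t$name, character(1))
  if (length(trs) > 0L && !identical(actual_names, expected_names)) {
    add("error", "TRANSCRIPT_NAMES", "fixed/transcripts",
        sprintf("transcript names must be consecutive t1..t%d, got: %s",
                length(trs), paste(actual_names, collapse = ",")))
  }

  seq_ok <- n >= 1L && !grepl("[^ACGTN]", seq)
  for (ti in seq_along(trs)) {
    f <- rbind(f, validate_transcript(trs[[ti]], seq, ti, seq_ok))
  }

  f <- rbind(f, validate_updatable(record$updatable, record))
  rownames(f) <- NULL
  f
}

validate_transcript <- function(t, genomic, ti, seq_ok = TRUE) {
  f <- no_findings()
  add <- function(severity, code, location, message) {
    f <<- rbind(f, finding(severity, code, location, message))
  }
  loc <- sprintf("fixed/transcript[%d]", ti)
  n <- nchar(genomic)
  exs <- t$exons

  if (length(exs) == 0L) {
    add("error", "EXON_MISSING", loc, "transcript has no exons")
    return(f)
  }

  ok_geometry <- TRUE
  expected_cdna <- 0L
  for (ei in seq_along(exs)) {
    ex <- exs[[ei]]
    eloc <- sprintf("%s/exon[%d]", loc, ei)
    if (ex$lrg_end < ex$lrg_start) {
      add("error", "EXON_ORDER", eloc,
          sprintf("exon end %d < start %d", ex$lrg_end, ex$lrg_start))
      ok_geometry <- FALSE
      next
    }
    if (ex$lrg_start < 1L || ex$lrg_end > n) {
      add("error", "EXON_BOUNDS", eloc,
          sprintf("exon [%d,%d] outside sequence 1..%d",
                  ex$lrg_start, ex$lrg_end, n))
      ok_geometry <- FALSE
    }
    if (ei > 1L && ex$lrg_start <= exs[[ei - 1L]]$lrg_end) {
      add("error", "EXON_ORDER", eloc,
          "exons must be strictly increasing and non-overlapping in LRG coordinates")
      ok_geometry <- FALSE
    }
    if (is.null(ex$cdna_start) || is.null(ex$cdna_end)) {
      add("error", "CDNA_MARKUP_MISSING", eloc, "exon lacks cDNA coordinates")
      ok_geometry <- FALSE
    } else {
      if ((ex$cdna_end - ex$cdna_start) != (ex$lrg_end - ex$lrg_start)) {
        add("error", "EXON_LENGTH_MISMATCH", eloc,
            "cDNA interval length differs from LRG interval length")
      }
      if (ex$cdna_start != expected_cdna + 1L) {
        add("error", "CDNA_GAP", eloc,
            sprintf("cDNA interval starts at %d, expected %d (intervals must abut)",
                    ex$cdna_start, expected_cdna + 1L))
      }
      expected_cdna <- ex$cdna_end
    }
  }

  # sequence-level checks only make sense over a clean alphabet and
  # geometry; structural findings above already cover the broken cases
  ok_geometry <- ok_geometry && seq_ok
  if (ok_geometry) {
    spliced <- splice_exons(genomic, exs)
    if (!identical(spliced, t$cdna_sequence)) {
      add("error", "CDNA_MISMATCH", sprintf("%s/cdna", loc),
          "stored cDNA differs from splice of exon intervals")
    }
  }

  cr <- t$coding_region
  if (is.null(cr) && !is.null(t$protein)) {
    add("error", "PROTEIN_WITHOUT_CDS", loc,
        "protein present but no coding region declared")
  }
  if (!is.null(cr) && is.null(t$protein)) {
    add("error", "CDS_WITHOUT_PROTEIN", loc,
        "coding region declared but no protein present")
  }
  if (!is.null(cr) && ok_geometry) {
    cloc <- sprintf("%s/coding_region", loc)
    s_ex <- exon_index_at(exs, cr$cds_start)
    e_ex <- exon_index_at(exs, cr$cds_end)
    if (is.na(s_ex) || is.na(e_ex) || cr$cds_end < cr$cds_start) {
      add("error", "CDS_OUTSIDE_EXON", cloc,
          "CDS bounds must fall inside exons of the owning transcript")
    } else {
      cds_c1 <- lrg_to_cdna_pos(exs, cr$cds_start)
      cds_c2 <- lrg_to_cdna_pos(exs, cr$cds_end)
      cds_len <- cds_c2 - cds_c1 + 1L
      if (cds_len %% 3L != 0L || cds_len < 6L) {
        add("error", "CDS_FRAME", cloc,
            sprintf("exonic CDS length %d is not a usable multiple of 3", cds_len))
      } else {
        cds_seq <- substr(t$cdna_sequence, cds_c1, cds_c2)
        if (grepl("N", cds_seq, fixed = TRUE)) {
          add("error", "CDS_N", cloc, "CDS contains N bases")
        } else if (!is.null(t$protein)) {
          prot <- tryCatch(translate_cds(cds_seq), error = function(e) e)
          ploc <- sprintf("%s/protein", loc)
          if (inherits(prot, "error")) {
            add("error", "CDS_TRANSLATION", cloc, conditionMessage(prot))
          } else {
            if (!identical(prot, t$protein$sequence)) {
              add("error", "PROTEIN_MISMATCH", ploc,
                  "stored protein differs from translation of the CDS")
            }
            expected_pname <- sub("^t", "p", t$name)
            if (!identical(t$protein$name, expected_pname)) {
              add("error", "PROTEIN_NAME", ploc,
                  sprintf("protein name '%s' does not match transcript (expected '%s')",
                          t$protein$name, expected_pname))
            }
          }
        }
      }
    }
  }
  f
}

validate_updatable <- function(up, record) {
  f <- no_findings()
  add <- function(severity, code, location, message) {
    f <<- rbind(f, finding(severity, code, location, message))
  }
  for (si in seq_along(up$annotation_sets)) {
    s <- up$annotation_sets[[si]]
    sloc <- sprintf("updatable/annotation_set[%d]", si)
    if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", s$modification_date)) {
      add("error", "ANNSET_DATE", sloc,
          sprintf("modification_date '%s' is not an ISO 8601 date",
                  s$modification_date))
    }
    for (mi in seq_along(s$mappings)) {
      m <- s$mappings[[mi]]
      mloc <- sprintf("%s/mapping[%d]", sloc, mi)
      ivs <- t(vapply(m$spans, function(sp) c(sp$lrg_start, sp$lrg_end),
                      integer(2)))
      if (nrow(ivs) > 1L) {
        o <- order(ivs[, 1])
        if (any(ivs[o, 1][-1] <= ivs[o, 2][-nrow(ivs)])) {
          add("error", "MAPPING_SPAN_OVERLAP", mloc,
              "mapping spans overlap in LRG coordinates")
        }
      }
      for (pi in seq_along(m$spans)) {
        sp <- m$spans[[pi]]
        ploc <- sprintf("%s/span[%d]", mloc, pi)
        chk <- tryCatch({ compile_span(sp); NULL }, error = function(e) e)
        if (!is.null(chk)) {
          add("error", "SPAN_GEOMETRY", ploc, conditionMessage(chk))
        }
      }
    }
    for (xi in seq_along(s$xrefs)) {
      x <- s$xrefs[[xi]]
      if (isTRUE(x$identical_to_lrg) && is.null(x$version)) {
        add("error", "XREF_VERSION", sprintf("%s/xref[%d]", sloc, xi),
            "identical_to_lrg requires an explicit version")
      }
    }
    for (li in seq_along(s$legacy_maps)) {
      lm <- s$legacy_maps[[li]]
      lloc <- sprintf("%s/legacy_map[%d]", sloc, li)
      rs <- lm$residue_shifts
      if (nrow(rs) > 1L) {
        o <- order(rs$start)
        if (any(rs$start[o][-1] <= rs$end[o][-nrow(rs)])) {
          add("error", "LEGACY_RANGES", lloc,
              "legacy residue ranges overlap")
        }
      }
      if (length(lm$exon_labels) > 0L) {
        ords <- suppressWarnings(as.integer(names(lm$exon_labels)))
        max_exons <- max(c(0L, vapply(record$fixed$transcripts,
                                      function(t) length(t$exons), integer(1))))
        if (anyNA(ords) || any(ords < 1L) || any(ords > max_exons)) {
          add("error", "LEGACY_EXON_ORDINAL", lloc,
              "legacy exon labels reference non-existent exon ordinals")
        }
      }
    }
    for (oi in seq_along(s$overlaps)) {
      ov <- s$overlaps[[oi]]
      if (!grepl("^[A-Za-z0-9_.-]+$", ov$id)) {
        add("error", "OVERLAP_ID", sprintf("%s/overlap[%d]", sloc, oi),
            sprintf("malformed overlap identifier '%s'", ov$id))
      }
    }
  }
  f
}

# index of the exon containing an LRG position, NA if intronic/outside
exon_index_at <- function(exons, pos) {
  for (i in seq_along(exons)) {
    if (pos >= exons[[i]]$lrg_start && pos <= exons[[i]]$lrg_end) return(i)
  }
  NA_integer_
}

# cDNA coordinate of an exonic LRG position (1-based), computed from the
# LRG intervals alone
lrg_to_cdna_pos <- function(exons, pos) {
  acc <- 0L
  for (ex in exons) {
    if (pos >= ex$lrg_start && pos <= ex$lrg_end) {
      return(acc + (pos - ex$lrg_start) + 1L)
    }
    acc <- acc + exon_len(ex)
  }
  stop(sprintf("position %d is not exonic", pos), call. = FALSE)
}

cdna_to_lrg_pos <- function(exons, cpos) {
  acc <- 0L
  for (ex in exons) {
    len <- exon_len(ex)
    if (cpos <= acc + len) return(ex$lrg_start + (cpos - acc - 1L))
    acc <- acc + len
  }
  stop(sprintf("cDNA position %d beyond transcript", cpos), call. = FALSE)
}
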
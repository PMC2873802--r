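# XML serialization of the record dialect.  The file has two sections,
# mirroring the two layers: <fixed_annotation> carries the sequence,
# transcripts, exon markup in all three coordinate systems, CDS bounds and
# translations; <updatable_annotation> carries date-stamped annotation
# sets.  The fixed section is strict (unknown elements are errors: fixed
# content is a contract); the updatable section is forward-compatible
# (unknown elements are preserved verbatim and re-emitted).

LRG_DIALECT_VERSION <- "lrgkit-1.0"

xml_child_names <- function(node) {
  xml2::xml_name(xml2::xml_children(node))
}

need_child <- function(node, name, path) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing")) {
    stop(sprintf("missing mandatory element %s/%s", path, name), call. = FALSE)
  }
  ch
}

attr_int <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) return(default)
  as.integer(v)
}

#' Read a record from its XML serialization
#'
#' @param xml_text A single string of XML, a file path, or anything
#'   [xml2::read_xml()] accepts.
#' @return An [lrg_record()].  Unknown elements inside annotation sets are
#'   preserved as opaque fragments and survive a write round trip
#'   byte-identically; unknown elements in the fixed section are errors.
#' @export
read_lrg <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  if (xml2::xml_name(doc) != "lrg") {
    stop("root element must be <lrg>", call. = FALSE)
  }
  fx_node <- need_child(doc, "fixed_annotation", "/lrg")
  known_fixed <- c("id", "organism", "sequence", "transcript")
  unknown <- setdiff(xml_child_names(fx_node), known_fixed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element(s) in fixed section: %s (fixed-layer content is a closed contract)",
                 paste0("/lrg/fixed_annotation/", unknown, collapse = ", ")),
         call. = FALSE)
  }
  lrg_id <- xml2::xml_text(need_child(fx_node, "id", "/lrg/fixed_annotation"))
  seq_node <- need_child(fx_node, "sequence", "/lrg/fixed_annotation")
  org_node <- xml2::xml_find_first(fx_node, "organism")
  organism <- if (inherits(org_node, "xml_missing")) "Homo sapiens" else
    xml2::xml_text(org_node)
  taxon_id <- if (inherits(org_node, "xml_missing")) 9606L else
    attr_int(org_node, "taxon_id", 9606L)

  transcripts <- lapply(xml2::xml_find_all(fx_node, "transcript"), read_transcript)
  fixed <- new_fixed_annotation(xml2::xml_text(seq_node), transcripts,
                                organism = organism, taxon_id = taxon_id)

  up_node <- xml2::xml_find_first(doc, "updatable_annotation")
  sets <- if (inherits(up_node, "xml_missing")) list() else
    lapply(xml2::xml_find_all(up_node, "annotation_set"), read_annotation_set)
  lrg_record(lrg_id, fixed, new_updatable_annotation(sets))
}

read_transcript <- function(node) {
  known <- c("exon", "coding_region", "cdna_sequence", "translation")
  unknown <- setdiff(xml_child_names(node), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element(s) in fixed section: transcript/%s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  exons <- lapply(xml2::xml_find_all(node, "exon"), function(e) {
    new_exon(attr_int(e, "lrg_start"), attr_int(e, "lrg_end"),
             attr_int(e, "cdna_start"), attr_int(e, "cdna_end"),
             attr_int(e, "peptide_start"), attr_int(e, "peptide_end"))
  })
  cr_node <- xml2::xml_find_first(node, "coding_region")
  coding_region <- if (inherits(cr_node, "xml_missing")) NULL else
    new_coding_region(attr_int(cr_node, "cds_start"),
                      attr_int(cr_node, "cds_end"))
  tr_node <- xml2::xml_find_first(node, "translation")
  protein <- if (inherits(tr_node, "xml_missing")) NULL else
    new_protein(xml2::xml_attr(tr_node, "name"),
                xml2::xml_text(xml2::xml_find_first(tr_node, "sequence")))
  new_transcript(xml2::xml_attr(node, "name"), exons,
                 coding_region = coding_region,
                 cdna_sequence = xml2::xml_text(
                   need_child(node, "cdna_sequence", "transcript")),
                 protein = protein)
}

read_annotation_set <- function(node) {
  known <- c("source", "modification_date", "mapping", "xref", "legacy_map",
             "overlap", "note")
  mappings <- lapply(xml2::xml_find_all(node, "mapping"), function(m) {
    spans <- lapply(xml2::xml_find_all(m, "mapping_span"), function(sp) {
      diffs <- lapply(xml2::xml_find_all(sp, "diff"), function(d) {
        new_seq_diff(xml2::xml_attr(d, "kind"),
                     attr_int(d, "lrg_start"), attr_int(d, "lrg_end"),
                     attr_int(d, "other_start"), attr_int(d, "other_end"),
                     xml2::xml_attr(d, "lrg_sequence") %||na% "",
                     xml2::xml_attr(d, "other_sequence") %||na% "")
      })
      new_mapping_span(attr_int(sp, "lrg_start"), attr_int(sp, "lrg_end"),
                       attr_int(sp, "other_start"), attr_int(sp, "other_end"),
                       attr_int(sp, "strand"), diffs)
    })
    new_assembly_mapping(xml2::xml_attr(m, "assembly_name"),
                         xml2::xml_attr(m, "other_accession"), spans)
  })
  xrefs <- lapply(xml2::xml_find_all(node, "xref"), function(x) {
    new_xref(xml2::xml_attr(x, "source_db"), xml2::xml_attr(x, "accession"),
             attr_int(x, "version"),
             identical(xml2::xml_attr(x, "identical_to_lrg"), "true"))
  })
  legacy_maps <- lapply(xml2::xml_find_all(node, "legacy_map"), function(lm) {
    labs <- xml2::xml_find_all(lm, "exon_label")
    exon_labels <- stats::setNames(
      as.list(xml2::xml_attr(labs, "label")),
      xml2::xml_attr(labs, "ordinal"))
    shifts <- xml2::xml_find_all(lm, "residue_shift")
    new_legacy_map(xml2::xml_attr(lm, "scheme_name"), exon_labels,
                   data.frame(start = as.integer(xml2::xml_attr(shifts, "start")),
                              end = as.integer(xml2::xml_attr(shifts, "end")),
                              shift = as.integer(xml2::xml_attr(shifts, "shift"))))
  })
  overlaps <- lapply(xml2::xml_find_all(node, "overlap"), function(o) {
    new_overlap(xml2::xml_attr(o, "id"), attr_int(o, "strand", 1L))
  })
  notes <- xml2::xml_text(xml2::xml_find_all(node, "note"))
  extra_nodes <- xml2::xml_children(node)
  extras <- vapply(extra_nodes[!xml2::xml_name(extra_nodes) %in% known],
                   function(n) as.character(n), character(1))
  new_annotation_set(
    xml2::xml_text(need_child(node, "source", "annotation_set")),
    xml2::xml_text(need_child(node, "modification_date", "annotation_set")),
    mappings = mappings, xrefs = xrefs, legacy_maps = legacy_maps,
    overlaps = overlaps, notes = notes, extras = extras)
}

`%||na%` <- function(a, b) if (is.na(a)) b else a

#' Serialize a record to XML
#'
#' Output is deterministic: element order is fixed, attributes are written
#' in a stable order, the encoding is UTF-8, and two writes of the same
#' record are byte-identical.  The record must validate with no errors.
#'
#' @param record An [lrg_record()].
#' @return A single string of XML.
#' @export
write_lrg <- function(record) {
  f <- validate_record(record)
  errs <- f[f$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    stop(sprintf("refusing to serialize an invalid record: %s at %s (%s)%s",
                 errs$code[1], errs$location[1], errs$message[1],
                 if (nrow(errs) > 1L)
                   sprintf(" and %d further error(s)", nrow(errs) - 1L) else ""),
         call. = FALSE)
  }
  doc <- xml2::xml_new_root("lrg", schema_dialect = LRG_DIALECT_VERSION)
  fx <- xml2::xml_add_child(doc, "fixed_annotation")
  xml2::xml_add_child(fx, "id", record$lrg_id)
  xml2::xml_add_child(fx, "organism", record$fixed$organism,
                      taxon_id = as.character(record$fixed$taxon_id))
  xml2::xml_add_child(fx, "sequence", record$fixed$sequence)
  for (t in record$fixed$transcripts) {
    tn <- xml2::xml_add_child(fx, "transcript", name = t$name)
    for (ex in t$exons) {
      attrs <- c(lrg_start = ex$lrg_start, lrg_end = ex$lrg_end,
                 cdna_start = ex$cdna_start, cdna_end = ex$cdna_end,
                 peptide_start = ex$peptide_start, peptide_end = ex$peptide_end)
      en <- xml2::xml_add_child(tn, "exon")
      xml2::xml_set_attrs(en, vapply(attrs, as.character, character(1)))
    }
    if (!is.null(t$coding_region)) {
      xml2::xml_add_child(tn, "coding_region",
                          cds_start = as.character(t$coding_region$cds_start),
                          cds_end = as.character(t$coding_region$cds_end))
    }
    xml2::xml_add_child(tn, "cdna_sequence", t$cdna_sequence)
    if (!is.null(t$protein)) {
      pn <- xml2::xml_add_child(tn, "translation", name = t$protein$name)
      xml2::xml_add_child(pn, "sequence", t$protein$sequence)
    }
  }
  up <- xml2::xml_add_child(doc, "updatable_annotation")
  for (s in record$updatable$annotation_sets) {
    sn <- xml2::xml_add_child(up, "annotation_set")
    xml2::xml_add_child(sn, "source", s$source)
    xml2::xml_add_child(sn, "modification_date", s$modification_date)
    for (m in s$mappings) {
      mn <- xml2::xml_add_child(sn, "mapping",
                                assembly_name = m$assembly_name,
                                other_accession = m$other_accession)
      for (sp in m$spans) {
        spn <- xml2::xml_add_child(mn, "mapping_span",
          lrg_start = as.character(sp$lrg_start),
          lrg_end = as.character(sp$lrg_end),
          other_start = as.character(sp$other_start),
          other_end = as.character(sp$other_end),
          strand = as.character(sp$strand))
        for (d in sp$diffs) {
          xml2::xml_add_child(spn, "diff", kind = d$kind,
            lrg_start = as.character(d$lrg_start),
            lrg_end = as.character(d$lrg_end),
            other_start = as.character(d$other_start),
            other_end = as.character(d$other_end),
            lrg_sequence = d$lrg_sequence,
            other_sequence = d$other_sequence)
        }
      }
    }
    for (x in s$xrefs) {
      xn <- xml2::xml_add_child(sn, "xref", source_db = x$source_db,
                                accession = x$accession)
      if (!is.null(x$version)) {
        xml2::xml_set_attr(xn, "version", as.character(x$version))
      }
      xml2::xml_set_attr(xn, "identical_to_lrg",
                         if (x$identical_to_lrg) "true" else "false")
    }
    for (lm in s$legacy_maps) {
      ln <- xml2::xml_add_child(sn, "legacy_map", scheme_name = lm$scheme_name)
      for (ord in names(lm$exon_labels)) {
        xml2::xml_add_child(ln, "exon_label", ordinal = ord,
                            label = lm$exon_labels[[ord]])
      }
      rs <- lm$residue_shifts
      for (i in seq_len(nrow(rs))) {
        xml2::xml_add_child(ln, "residue_shift",
                            start = as.character(rs$start[i]),
                            end = as.character(rs$end[i]),
                            shift = as.character(rs$shift[i]))
      }
    }
    for (o in s$overlaps) {
      xml2::xml_add_child(sn, "overlap", id = o$id,
                          strand = as.character(o$strand))
    }
    for (note in s$notes) xml2::xml_add_child(sn, "note", note)
    for (fragment in s$extras) {
      xml2::xml_add_child(sn, xml2::read_xml(fragment))
    }
  }
  as.character(doc)
}

lrgkit_schema_path <- function() {
  system.file("schema", "lrg-dialect-1.0.xsd", package = "lrgkit",
              mustWork = TRUE)
}

#' Validate XML against the shipped schema dialect
#'
#' Three stages, all reported (never thrown): XML well-formedness, XSD
#' validation against the shipped dialect schema (strict for the fixed
#' section, lax for the forward-compatible updatable section), and
#' semantic checks the XSD cannot express (interval orientation, strand
#' values, coordinate-system agreement of exon markup).
#'
#' @param xml_text XML string or file path.
#' @return A list of class `lrg_schema_report`: `valid` (logical) and
#'   `violations` (data frame with `path`, `message`); `valid` iff zero
#'   violations.
#' @export
validate_xml <- function(xml_text) {
  violations <- data.frame(path = character(), message = character(),
                           stringsAsFactors = FALSE)
  add <- function(path, message) {
    violations <<- rbind(violations,
                         data.frame(path = path, message = message,
                                    stringsAsFactors = FALSE))
  }
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) e)
  if (inherits(doc, "error")) {
    add("/", paste("XML syntax error:", conditionMessage(doc)))
    return(structure(list(valid = FALSE, violations = violations),
                     class = "lrg_schema_report"))
  }
  schema <- xml2::read_xml(lrgkit_schema_path())
  ok <- xml2::xml_validate(doc, schema)
  if (!isTRUE(ok)) {
    for (msg in attr(ok, "errors")) add("(schema)", msg)
  }
  # semantic checks beyond XSD expressiveness
  exons <- xml2::xml_find_all(doc, "/lrg/fixed_annotation/transcript/exon")
  for (i in seq_along(exons)) {
    e <- exons[[i]]
    if (attr_int(e, "lrg_end", 0L) < attr_int(e, "lrg_start", 0L)) {
      add(xml2::xml_path(e), "exon lrg_end < lrg_start")
    }
    cs <- attr_int(e, "cdna_start"); ce <- attr_int(e, "cdna_end")
    if (!is.null(cs) && !is.null(ce) &&
        (ce - cs) != (attr_int(e, "lrg_end", 0L) - attr_int(e, "lrg_start", 0L))) {
      add(xml2::xml_path(e), "cDNA interval length differs from LRG interval length")
    }
  }
  spans <- xml2::xml_find_all(doc, "//mapping_span")
  for (sp in spans) {
    if (!attr_int(sp, "strand", 0L) %in% c(1L, -1L)) {
      add(xml2::xml_path(sp), "strand must be 1 or -1")
    }
  }
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "lrg_schema_report")
}

#' @export
print.lrg_schema_report <- function(x, ...) {
  cat(sprintf("<schema report: %s, %d violation(s)>\n",
              if (x$valid) "valid" else "INVALID", nrow(x$violations)))
  if (nrow(x$violations) > 0L) {
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  %s: %s\n", x$violations$path[i], x$violations$message[i]))
    }
  }
  invisible(x)
}
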
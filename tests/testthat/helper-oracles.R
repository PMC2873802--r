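# Shared fixtures and independent oracles.  Every oracle here is a naive
# re-implementation (per-base walks, whole-sequence re-translation,
# third-party parsers) deliberately distinct from the code paths it checks.

# -- small deterministic records -------------------------------------------

# two-exon toy: exon1 carries c.1..100 (CDS starts at its first base),
# exon2 carries the rest of the CDS plus a 3' UTR
toy_two_exon <- function() {
  with_seed_local(101, {
    e1_len <- 100L; intron <- 50L; e2_cds <- 53L; utr3 <- 30L
    total <- 10L + e1_len + intron + e2_cds + utr3 + 10L
    chars <- strsplit(paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                            collapse = ""), "")[[1]]
    e1 <- c(11L, 10L + e1_len)
    e2 <- c(e1[2] + intron + 1L, e1[2] + intron + e2_cds + utr3)
    cds_pos <- c(e1[1]:e1[2], e2[1]:(e2[1] + e2_cds - 1L))
    # scrub stops, then force ATG start and TAA stop
    for (ci in seq_len(length(cds_pos) %/% 3L - 1L)) {
      idx <- cds_pos[(3L * ci - 2L):(3L * ci)]
      if (paste(chars[idx], collapse = "") %in% c("TAA", "TAG", "TGA")) {
        chars[idx[3]] <- "C"
      }
    }
    chars[cds_pos[1:3]] <- c("A", "T", "G")
    chars[cds_pos[(length(cds_pos) - 2L):length(cds_pos)]] <- c("T", "A", "A")
    build_record("LRG_500", paste(chars, collapse = ""),
                 list(list(exons = list(e1, e2),
                           cds = c(cds_pos[1], cds_pos[length(cds_pos)]))))
  })
}

# compact coding fixture for exhaustive substitution scans (~150 nt CDS)
small_cds_fixture <- function(seed = 11L) {
  make_synthetic_gene(gene_model_spec(
    seed = seed, n_exons = 4L, exon_length_range = c(40L, 60L),
    intron_length_range = c(30L, 80L), utr5_len = 30L, utr3_len = 20L,
    flank5 = 40L, flank3 = 40L))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# -- per-base mapping-span oracle ------------------------------------------

# expand a mapping span base by base: returns data.frame(lrg, other) over
# the mapped (collinear) bases only, walking each LRG base individually
expand_span_oracle <- function(span) {
  diffs <- span$diffs
  if (length(diffs) > 0L) {
    diffs <- diffs[order(vapply(diffs, function(d) d$lrg_start, integer(1)))]
  }
  dirn <- span$strand
  other_cursor <- if (dirn > 0L) span$other_start else span$other_end
  lrg <- integer(); other <- integer()
  l <- span$lrg_start
  di <- 1L
  while (l <= span$lrg_end) {
    d <- if (di <= length(diffs)) diffs[[di]] else NULL
    if (!is.null(d) && d$kind == "other_insertion" && d$lrg_start == l &&
        d$lrg_end < d$lrg_start) {
      other_cursor <- other_cursor + dirn * (d$other_end - d$other_start + 1L)
      di <- di + 1L
      next
    }
    if (!is.null(d) && d$kind == "lrg_insertion" &&
        l >= d$lrg_start && l <= d$lrg_end) {
      l <- l + 1L
      if (l > d$lrg_end) di <- di + 1L
      next
    }
    if (!is.null(d) && d$kind == "mismatch" && l > d$lrg_end) di <- di + 1L
    lrg <- c(lrg, l); other <- c(other, other_cursor)
    other_cursor <- other_cursor + dirn
    l <- l + 1L
  }
  data.frame(lrg = lrg, other = other)
}

# -- protein-consequence oracle --------------------------------------------

# whole-CDS re-translation with an independent codon table (Biostrings'
# GENETIC_CODE when available, else a hand-entered copy of the standard
# code restricted to what the fixtures use)
oracle_translate <- function(cds) {
  tab <- if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::GENETIC_CODE
  } else {
    standard_codon_table() # fallback; acceptance runs with Biostrings present
  }
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  paste(unname(tab[codons]), collapse = "")
}

# expected p.-level outcome of substituting `alt` at CDS position `cpos`:
# re-translate the entire mutated CDS and diff the protein strings
protein_consequence_oracle <- function(cds_seq, cpos, alt) {
  mutated <- cds_seq
  substr(mutated, cpos, cpos) <- alt
  p0 <- oracle_translate(cds_seq)
  p1 <- oracle_translate(mutated)
  stopifnot(substr(p0, nchar(p0), nchar(p0)) == "*")
  if (identical(p0, p1)) return(list(kind = "synonymous"))
  if (substr(p1, nchar(p1), nchar(p1)) != "*") return(list(kind = "stop_loss"))
  diffs <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  stopifnot(length(diffs) == 1L)
  list(kind = "missense",
       residue = diffs,
       ref = substr(p0, diffs, diffs),
       alt = substr(p1, diffs, diffs))
}

# -- record corruption helpers (mutation coverage of the validator) --------

corruptions <- function(record) {
  seq <- record$fixed$sequence
  list(
    bad_id = function(r) { r$lrg_id <- "LRG_0"; r },
    foreign_base = function(r) {
      substr(r$fixed$sequence, 5, 5) <- "X"; r
    },
    cdna_edit = function(r) {
      t <- r$fixed$transcripts[[1]]
      pos <- nchar(t$cdna_sequence) %/% 2L
      base <- substr(t$cdna_sequence, pos, pos)
      substr(r$fixed$transcripts[[1]]$cdna_sequence, pos, pos) <-
        setdiff(c("A", "C", "G", "T"), base)[1]
      r
    },
    protein_truncated = function(r) {
      p <- r$fixed$transcripts[[1]]$protein$sequence
      r$fixed$transcripts[[1]]$protein$sequence <- substr(p, 1, nchar(p) - 1L)
      r
    },
    exon_overlap = function(r) {
      r$fixed$transcripts[[1]]$exons[[2]]$lrg_start <-
        r$fixed$transcripts[[1]]$exons[[1]]$lrg_end
      r
    },
    exon_out_of_bounds = function(r) {
      n <- length(r$fixed$transcripts[[1]]$exons)
      r$fixed$transcripts[[1]]$exons[[n]]$lrg_end <- nchar(seq) + 10L
      r
    },
    cdna_gap = function(r) {
      r$fixed$transcripts[[1]]$exons[[2]]$cdna_start <-
        r$fixed$transcripts[[1]]$exons[[2]]$cdna_start + 1L
      r
    },
    cds_off_exon = function(r) {
      cr <- r$fixed$transcripts[[1]]$coding_region
      intronic <- r$fixed$transcripts[[1]]$exons[[1]]$lrg_end + 1L
      r$fixed$transcripts[[1]]$coding_region$cds_start <- intronic
      r
    },
    frameshifted_cds = function(r) {
      r$fixed$transcripts[[1]]$coding_region$cds_start <-
        r$fixed$transcripts[[1]]$coding_region$cds_start + 1L
      r
    },
    transcript_renamed = function(r) {
      r$fixed$transcripts[[1]]$name <- "t9"; r
    },
    bad_date = function(r) {
      if (length(r$updatable$annotation_sets) == 0L) {
        r$updatable$annotation_sets <- list(
          new_annotation_set("x", "2020-01-01"))
      }
      r$updatable$annotation_sets[[1]]$modification_date <- "yesterday"
      r
    },
    xref_identical_unversioned = function(r) {
      bad <- new_xref("db", "ACC", identical_to_lrg = FALSE)
      bad$identical_to_lrg <- TRUE     # bypass constructor-side use
      r$updatable$annotation_sets <- list(
        new_annotation_set("x", "2020-01-01", xrefs = list(bad)))
      r
    },
    legacy_overlapping_ranges = function(r) {
      lm <- new_legacy_map("s", residue_shifts = data.frame(
        start = c(1L, 5L), end = c(10L, 12L), shift = c(0L, 1L)))
      r$updatable$annotation_sets <- list(
        new_annotation_set("x", "2020-01-01", legacy_maps = list(lm)))
      r
    },
    span_length_mismatch = function(r) {
      bad <- new_mapping_span(1L, 100L, 1L, 150L, strand = 1L)
      r$updatable$annotation_sets <- list(
        new_annotation_set("x", "2020-01-01", mappings = list(
          new_assembly_mapping("A", "ACC.1", list(bad)))))
      r
    }
  )
}

# -- random updatable-layer edits (digest invariance) ----------------------

random_updatable_edit <- function(record, i) {
  choice <- i %% 4L
  s <- new_annotation_set(sprintf("src%d", i),
                          sprintf("20%02d-01-%02d", i %% 30L, i %% 27L + 1L))
  if (choice == 0L) {
    s$notes <- sprintf("note %d", i)
  } else if (choice == 1L) {
    s$xrefs <- list(new_xref("db", sprintf("ACC%d", i), i,
                             identical_to_lrg = TRUE))
  } else if (choice == 2L) {
    n <- nchar(record$fixed$sequence)
    s$mappings <- list(new_assembly_mapping(
      sprintf("ASM%d", i), sprintf("CTG%d.1", i),
      list(new_mapping_span(1L, n, 1000L + i, 999L + i + n,
                            strand = if (i %% 2L == 0L) 1L else -1L))))
  } else {
    s$overlaps <- list(new_overlap(sprintf("LRG_%d", 100L + i),
                                   strand = if (i %% 2L == 0L) 1L else -1L))
  }
  record$updatable$annotation_sets <-
    c(record$updatable$annotation_sets, list(s))
  record
}
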
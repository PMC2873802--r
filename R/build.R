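# Record construction from parts, and the synthetic gene generators used
# throughout the test suite.  Every generated record is synthetic: the
# engineered collagen-like fixture reproduces published numeric relations
# (codon math, intron-offset anchoring, reverse-complement contig
# placement) without reproducing any real locus sequence.

# run code under a temporary RNG state without disturbing the caller's
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop-free codons used for deterministic CDS text
SAFE_CODONS <- c("GCT", "GAA", "TTC", "GGC", "CAT", "ATC", "AAG", "CTG",
                 "ATG", "AAC", "CCA", "CAG", "CGT", "TCT", "ACC", "GTG")

#' Build a complete record from genomic sequence and gene-model parts
#'
#' Derives everything the fixed layer stores from the supplied exon
#' intervals and CDS bounds: cDNA coordinates of each exon, the spliced
#' cDNA sequence, peptide coordinates of coding exons, and the translated
#' protein.  The resulting record passes [validate_record()] with zero
#' errors, or construction fails.
#'
#' @param lrg_id Record identifier, `"LRG_<n>"`.
#' @param genomic_seq Genomic DNA string.
#' @param transcripts_spec List with one entry per transcript:
#'   `list(exons = list(c(start, end), ...), cds = c(start, end))` in LRG
#'   coordinates; `cds = NULL` gives a non-coding transcript.
#' @param organism,taxon_id Organism fields of the fixed layer.
#' @param updatable Optional [new_updatable_annotation()].
#' @return A validated [lrg_record()].
#' @export
#' @examples
#' r <- build_record("LRG_900", "AAATGGGCTGATTT",
#'                   list(list(exons = list(c(2, 14)), cds = c(3, 11))))
#' r$fixed$transcripts[[1]]$protein$sequence  # "MG"
build_record <- function(lrg_id, genomic_seq, transcripts_spec,
                         organism = "Homo sapiens", taxon_id = 9606L,
                         updatable = new_updatable_annotation()) {
  assert_dna(genomic_seq, allow_n = TRUE, what = "genomic sequence")
  transcripts <- vector("list", length(transcripts_spec))
  for (k in seq_along(transcripts_spec)) {
    spec <- transcripts_spec[[k]]
    transcripts[[k]] <- build_transcript(paste0("t", k), genomic_seq,
                                         spec$exons, spec$cds)
  }
  rec <- lrg_record(lrg_id,
                    new_fixed_annotation(genomic_seq, transcripts,
                                         organism = organism,
                                         taxon_id = taxon_id),
                    updatable)
  f <- validate_record(rec)
  errs <- f[f$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    stop(sprintf("built record fails validation: %s at %s (%s)", # nocov
                 errs$code[1], errs$location[1], errs$message[1]), # nocov
         call. = FALSE) # nocov
  }
  rec
}

build_transcript <- function(name, genomic_seq, exon_intervals, cds) {
  ivs <- lapply(exon_intervals, function(x) as.integer(x))
  starts <- vapply(ivs, `[`, integer(1), 1L)
  ends <- vapply(ivs, `[`, integer(1), 2L)
  if (any(ends < starts)) stop("exon end before start", call. = FALSE)
  if (is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1] <= ends[-length(ends)])) {
    stop("exons must be strictly increasing and non-overlapping", call. = FALSE)
  }
  lens <- ends - starts + 1L
  cdna_ends <- cumsum(lens)
  cdna_starts <- cdna_ends - lens + 1L
  exons <- vector("list", length(ivs))
  bare <- lapply(seq_along(ivs), function(i) {
    new_exon(starts[i], ends[i], cdna_starts[i], cdna_ends[i])
  })
  cdna <- splice_exons(genomic_seq, bare)
  coding_region <- NULL
  protein <- NULL
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    cds_c1 <- lrg_to_cdna_pos(bare, cds[1])
    cds_c2 <- lrg_to_cdna_pos(bare, cds[2])
    cds_seq <- substr(cdna, cds_c1, cds_c2)
    prot_seq <- translate_cds(cds_seq)  # checks frame, stops, alphabet
    coding_region <- new_coding_region(cds[1], cds[2])
    protein <- new_protein(sub("^t", "p", name), prot_seq)
    for (i in seq_along(bare)) {
      lo <- max(cdna_starts[i], cds_c1)
      hi <- min(cdna_ends[i], cds_c2)
      if (lo <= hi) {
        bare[[i]]$peptide_start <- (lo - cds_c1) %/% 3L + 1L
        bare[[i]]$peptide_end <- (hi - cds_c1) %/% 3L + 1L
      }
    }
  }
  new_transcript(name, bare, coding_region = coding_region,
                 cdna_sequence = cdna, protein = protein)
}

#' Gene-model specification for the synthetic generator
#'
#' Defaults describe a small but structurally complete multi-exon gene: 8
#' exons of 30-200 nt, introns of 50-400 nt, modest UTRs and genomic
#' flanks, placed on a synthetic contig at a configurable offset and
#' strand.
#'
#' @param seed Integer seed; the generator is bit-reproducible per seed.
#' @param n_exons Number of exons.
#' @param exon_length_range,intron_length_range Inclusive length ranges.
#' @param utr5_len,utr3_len Untranslated lengths inside the transcript
#'   (the CDS end is nudged 5' by up to 2 nt to keep the frame).
#' @param flank5,flank3 Genomic flanks outside the transcript.
#' @param strand Strand of the synthetic assembly placement (`+1`/`-1`).
#' @param assembly_offset 0-based offset of the LRG on the synthetic
#'   contig.
#' @param n_transcripts `1` or `2`; with 2, `sharing` picks the pattern.
#' @param sharing `"alt_first"`, `"alt_last"` or `"skip_internal"` —
#'   distinct transcription start, alternative terminal exon, or a skipped
#'   internal exon.
#' @return A list of class `lrg_gene_model_spec`.
#' @export
gene_model_spec <- function(seed = 1L, n_exons = 8L,
                            exon_length_range = c(30L, 200L),
                            intron_length_range = c(50L, 400L),
                            utr5_len = 60L, utr3_len = 90L,
                            flank5 = 200L, flank3 = 200L,
                            strand = 1L, assembly_offset = 100000L,
                            n_transcripts = 1L, sharing = "skip_internal") {
  sharing <- match.arg(sharing, c("alt_first", "alt_last", "skip_internal"))
  spec <- list(seed = as.integer(seed), n_exons = as.integer(n_exons),
               exon_length_range = as.integer(exon_length_range),
               intron_length_range = as.integer(intron_length_range),
               utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
               flank5 = as.integer(flank5), flank3 = as.integer(flank3),
               strand = as.integer(strand),
               assembly_offset = as.integer(assembly_offset),
               n_transcripts = as.integer(n_transcripts), sharing = sharing)
  stopifnot(spec$n_exons >= 2L, all(spec$exon_length_range > 0L),
            all(spec$intron_length_range > 0L),
            spec$strand %in% c(1L, -1L), spec$n_transcripts %in% c(1L, 2L))
  structure(spec, class = "lrg_gene_model_spec")
}

# overwrite CDS bases in a genomic char vector so the frame is clean:
# no internal stop, terminal TAA, initial ATG
scrub_cds <- function(chars, cds_positions) {
  stopifnot(length(cds_positions) %% 3L == 0L)
  n_codons <- length(cds_positions) %/% 3L
  for (ci in seq_len(n_codons - 1L)) {
    idx <- cds_positions[(3L * ci - 2L):(3L * ci)]
    codon <- paste(chars[idx], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) chars[idx[3]] <- "C"
  }
  chars[cds_positions[1:3]] <- c("A", "T", "G")
  chars[cds_positions[(length(cds_positions) - 2L):length(cds_positions)]] <-
    c("T", "A", "A")
  chars
}

#' Generate a synthetic gene record with exhaustive truth tables
#'
#' Produces a random but valid record from a [gene_model_spec()], together
#' with truth tables computed by independent naive per-base walks (not by
#' the coordinate algebra): the per-base g. to c. labelling of every base
#' in each transcript span, the per-base LRG/contig correspondence of the
#' synthetic assembly placement, and the per-base codon/residue map of
#' each CDS.  The tables are the brute-force oracle the conversion
#' functions are tested against.
#'
#' @param spec A [gene_model_spec()].
#' @return A list with `record` (an [lrg_record()]) and `tables`:
#'   `g2c` (named per transcript; columns `g_pos`, `region`, `anchor`,
#'   `offset`), `assembly` (columns `lrg`, `other`, `strand`) and `codon`
#'   (named per transcript; columns `cds_pos`, `residue`).
#' @export
make_synthetic_gene <- function(spec = gene_model_spec()) {
  stopifnot(inherits(spec, "lrg_gene_model_spec"))
  with_seed(spec$seed, {
    n_ex <- spec$n_exons
    ex_len <- sample(spec$exon_length_range[1]:spec$exon_length_range[2],
                     n_ex, replace = TRUE)
    in_len <- sample(spec$intron_length_range[1]:spec$intron_length_range[2],
                     n_ex - 1L, replace = TRUE)

    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- spec$flank5 + 1L
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + ex_len[i] - 1L
      pos <- ends[i] + 1L + if (i < n_ex) in_len[i] else 0L
    }
    total_len <- ends[n_ex] + spec$flank3
    exonic_total <- sum(ex_len)

    cds_c1 <- spec$utr5_len + 1L
    cds_c2 <- exonic_total - spec$utr3_len
    cds_c2 <- cds_c2 - (cds_c2 - cds_c1 + 1L) %% 3L
    if (cds_c2 - cds_c1 + 1L < 6L) {
      stop("spec unsatisfiable: implied CDS is shorter than two codons",
           call. = FALSE)
    }

    chars <- strsplit(random_dna(total_len), "")[[1]]
    exonic_pos <- unlist(lapply(seq_len(n_ex), function(i) starts[i]:ends[i]))
    cds_positions <- exonic_pos[cds_c1:cds_c2]
    chars <- scrub_cds(chars, cds_positions)
    genomic <- paste(chars, collapse = "")

    all_exons <- lapply(seq_len(n_ex), function(i) c(starts[i], ends[i]))
    cds_bounds <- c(cds_positions[1], cds_positions[length(cds_positions)])

    tspec <- list(list(exons = all_exons, cds = cds_bounds))
    if (spec$n_transcripts == 2L) {
      alt <- switch(spec$sharing,
        alt_first = all_exons[-1L],
        alt_last = all_exons[-n_ex],
        skip_internal = all_exons[-max(2L, n_ex %/% 2L)])
      # keep the shared CDS inside the alternative transcript
      alt_pos <- unlist(lapply(alt, function(iv) iv[1]:iv[2]))
      if (!all(cds_positions %in% alt_pos)) {
        stop("spec unsatisfiable: sharing pattern removes part of the CDS",
             call. = FALSE)
      }
      tspec <- c(tspec, list(list(exons = alt, cds = cds_bounds)))
    }

    mapping <- synthetic_placement(total_len, spec$strand,
                                   spec$assembly_offset)
    up <- new_updatable_annotation(list(
      new_annotation_set("lrgkit-synthetic", "2010-03-01",
                         mappings = list(mapping))))
    record <- build_record(sprintf("LRG_%d", 9000L + (spec$seed %% 999L)),
                           genomic, tspec, updatable = up)
    tables <- list(
      g2c = lapply(record$fixed$transcripts, function(t)
        g2c_truth_table(t)),
      assembly = assembly_truth_table(total_len, spec$strand,
                                      spec$assembly_offset),
      codon = lapply(record$fixed$transcripts, function(t)
        codon_truth_table(t)))
    names(tables$g2c) <- vapply(record$fixed$transcripts, `[[`, "", "name")
    names(tables$codon) <- names(tables$g2c)
    list(record = record, tables = tables)
  })
}

synthetic_placement <- function(total_len, strand, offset) {
  span <- new_mapping_span(1L, total_len,
                           offset + 1L, offset + total_len,
                           strand = strand)
  new_assembly_mapping("SYN1", "SYNCTG_1.1", list(span))
}

# Naive per-base g->c labelling: walk every base of the transcript span
# and classify it by direct counting.  Shares no code with g_to_c().
g2c_truth_table <- function(transcript) {
  exs <- transcript$exons
  span <- transcript_span(transcript)
  cr <- transcript$coding_region
  exonic <- unlist(lapply(exs, function(e) e$lrg_start:e$lrg_end))
  cdna_index <- stats::setNames(seq_along(exonic), exonic)
  cds_c1 <- unname(cdna_index[as.character(cr$cds_start)])
  cds_c2 <- unname(cdna_index[as.character(cr$cds_end)])

  g_pos <- span[1]:span[2]
  region <- character(length(g_pos))
  anchor <- integer(length(g_pos))
  offset <- integer(length(g_pos))
  label_exonic <- function(j) {
    if (j < cds_c1) c("UTR5", j - cds_c1)
    else if (j <= cds_c2) c("CDS", j - cds_c1 + 1L)
    else c("UTR3", j - cds_c2)
  }
  for (i in seq_along(g_pos)) {
    p <- g_pos[i]
    key <- as.character(p)
    if (!is.na(cdna_index[key])) {
      lab <- label_exonic(unname(cdna_index[key]))
      region[i] <- lab[1]; anchor[i] <- as.integer(lab[2]); offset[i] <- 0L
    } else {
      # intronic: distances to both boundaries decide the side
      prev_end <- max(exonic[exonic < p])
      next_start <- min(exonic[exonic > p])
      d_up <- p - prev_end
      d_down <- next_start - p
      if (d_up <= d_down) {
        lab <- label_exonic(unname(cdna_index[as.character(prev_end)]))
        region[i] <- lab[1]; anchor[i] <- as.integer(lab[2]); offset[i] <- d_up
      } else {
        lab <- label_exonic(unname(cdna_index[as.character(next_start)]))
        region[i] <- lab[1]; anchor[i] <- as.integer(lab[2]); offset[i] <- -d_down
      }
    }
  }
  data.frame(g_pos = g_pos, region = region, anchor = anchor,
             offset = offset, stringsAsFactors = FALSE)
}

assembly_truth_table <- function(total_len, strand, offset) {
  other <- if (strand > 0L) offset + seq_len(total_len)
           else offset + rev(seq_len(total_len))
  data.frame(lrg = seq_len(total_len), other = other, strand = strand)
}

codon_truth_table <- function(transcript) {
  bounds <- cds_cdna_bounds(transcript)
  cds_len <- bounds[2] - bounds[1] + 1L
  data.frame(cds_pos = seq_len(cds_len),
             residue = rep(seq_len(cds_len %/% 3L), each = 3L))
}

#' Engineered collagen-like demonstration record (synthetic)
#'
#' A single-transcript record built so that the classic collagen worked
#' examples hold simultaneously on one synthetic locus:
#' \itemize{
#'   \item the genomic length equals the contig span 13535609..13553152
#'     (17544 nt) and the updatable layer places the record as the reverse
#'     complement of that interval on a pseudo-contig (`NT_010783.15`), so
#'     LRG position 1 maps to contig position 13553152 on the minus strand;
#'   \item the transcript has 50 exons; the 5' UTR (100 nt) plus 35 coding
#'     exons of 69 nt and a 36th of 36 nt put the donor site of exon 36 at
#'     c.2451, so the base 77 nt into intron 36 is c.2451+77 (IVS36+77);
#'   \item codon 191 is GGC (Gly), so the substitution c.572G>C (middle
#'     base of the codon) yields p.Gly191Ala;
#'   \item pseudo-accessions `NG_007400.1`, `NM_000088.3` and
#'     `NP_000079.2` are flagged as sequence-identical reference frames,
#'     so descriptions carry over unchanged (e.g. g.8463).
#' }
#' The sequence itself is a deterministic synthetic filler — no real locus
#' sequence is reproduced; only the published coordinate relations are.
#'
#' @return An [lrg_record()] with id `"LRG_1"`.
#' @export
make_col1a1_like <- function() {
  flank5 <- 1000L
  utr5 <- 100L
  utr3 <- 200L
  intron <- 260L
  ex_cds <- c(69L, rep(69L, 34L), 36L, rep(69L, 13L), 36L)  # 50 coding chunks
  ex_len <- ex_cds
  ex_len[1] <- ex_len[1] + utr5
  ex_len[50] <- ex_len[50] + utr3

  starts <- integer(50L); ends <- integer(50L)
  pos <- flank5 + 1L
  for (i in 1:50) {
    starts[i] <- pos
    ends[i] <- pos + ex_len[i] - 1L
    pos <- ends[i] + 1L + intron
  }
  total_len <- 13553152L - 13535609L + 1L  # 17544
  stopifnot(ends[50] <= total_len)

  # deterministic background, then an explicit stop-free CDS
  chars <- strsplit(paste(rep("ACGT", ceiling(total_len / 4)), collapse = ""),
                    "")[[1]][seq_len(total_len)]
  chars[1] <- "G"
  cds_len <- sum(ex_cds)                   # 3384 nt = 1128 codons
  n_codons <- cds_len %/% 3L
  codons <- SAFE_CODONS[(seq_len(n_codons) - 1L) %% length(SAFE_CODONS) + 1L]
  codons[1] <- "ATG"
  codons[191] <- "GGC"
  codons[n_codons] <- "TAA"
  cds_chars <- strsplit(paste(codons, collapse = ""), "")[[1]]

  exonic_pos <- unlist(lapply(1:50, function(i) starts[i]:ends[i]))
  cds_positions <- exonic_pos[(utr5 + 1L):(utr5 + cds_len)]
  chars[cds_positions] <- cds_chars
  genomic <- paste(chars, collapse = "")

  mapping <- new_assembly_mapping(
    "NCBI36", "NT_010783.15",
    list(new_mapping_span(1L, total_len, 13535609L, 13553152L,
                          strand = -1L)))
  legacy <- new_legacy_map(
    "mature_protein",
    exon_labels = list("1" = "1", "2" = "2A", "3" = "2B"),
    residue_shifts = data.frame(start = 24L, end = n_codons - 1L,
                                shift = 23L))
  up <- new_updatable_annotation(list(new_annotation_set(
    "lrgkit-synthetic", "2010-03-01",
    mappings = list(mapping),
    xrefs = list(
      new_xref("RefSeqGene", "NG_007400", 1L, identical_to_lrg = TRUE),
      new_xref("RefSeq", "NM_000088", 3L, identical_to_lrg = TRUE),
      new_xref("RefSeq", "NP_000079", 2L, identical_to_lrg = TRUE)),
    legacy_maps = list(legacy),
    overlaps = list(new_overlap("LRG_SYN_OVL_1", strand = -1L)),
    notes = "synthetic demonstration record; coordinate relations engineered, sequence is filler")))

  build_record("LRG_1", genomic,
               list(list(exons = lapply(1:50, function(i) c(starts[i], ends[i])),
                         cds = c(cds_positions[1],
                                 cds_positions[length(cds_positions)]))),
               updatable = up)
}

#' Two-transcript synthetic fixture
#'
#' A record with transcripts `t1` and `t2` that share their internal exons
#' and coding region but differ in transcription start and polyadenylation
#' exon, emulating genes whose single reference transcript cannot describe
#' every variant.  Both transcripts translate cleanly and the record
#' validates with zero findings.
#'
#' @param seed Integer seed.
#' @return An [lrg_record()] with two transcripts.
#' @export
make_multi_transcript_fixture <- function(seed = 42L) {
  with_seed(seed, {
    ex_len <- sample(60:150, 6L, replace = TRUE)
    in_len <- sample(80:300, 6L, replace = TRUE)
    # layout: [A1] i [B1] i [S2] i [S3] i [S4] i [LA] i [LB]
    lens <- c(ex_len[1], in_len[1], ex_len[2], in_len[2], ex_len[3], in_len[3],
              ex_len[4], in_len[4], ex_len[5], in_len[5], 90L, in_len[6], 110L)
    bounds <- cumsum(c(200L, lens))
    iv <- function(k) c(bounds[k] + 1L, bounds[k + 1L])
    a1 <- iv(1); b1 <- iv(3); s2 <- iv(5); s3 <- iv(7); s4 <- iv(9)
    la <- iv(11); lb <- iv(13)
    total_len <- bounds[14] + 200L

    chars <- strsplit(random_dna(total_len), "")[[1]]
    # shared CDS: starts 10 nt into S2, ends 30 nt before the end of S4
    shared_pos <- c(s2[1]:s2[2], s3[1]:s3[2], s4[1]:s4[2])
    cds_pos <- shared_pos[10:(length(shared_pos) - 30L)]
    cds_pos <- cds_pos[seq_len(length(cds_pos) - length(cds_pos) %% 3L)]
    chars <- scrub_cds(chars, cds_pos)
    genomic <- paste(chars, collapse = "")
    cds <- c(cds_pos[1], cds_pos[length(cds_pos)])

    build_record("LRG_77", genomic, list(
      list(exons = list(a1, s2, s3, s4, la), cds = cds),
      list(exons = list(b1, s2, s3, s4, lb), cds = cds)))
  })
}
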
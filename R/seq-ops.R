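# Elementary sequence computations shared by the whole package.  All
# coordinates in lrgkit are 1-based and fully inclusive unless a function
# says otherwise (only the BED exporter converts at its boundary).

#' The standard genetic code
#'
#' A named character vector mapping the 64 DNA codons to one-letter amino
#' acid codes, with `"*"` marking the three stop codons.  This is the table
#' used by default throughout the package; [translate_cds()] accepts any
#' complete 64-entry replacement, since records are not restricted to human
#' loci.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' standard_codon_table()[["ATG"]]  # "M"
standard_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  # classic TCAG ordering: first base slowest, third base fastest
  codons <- paste0(rep(bases, each = 16L),
                   rep(bases, each = 4L, times = 4L),
                   rep(bases, times = 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

check_codon_table <- function(table) {
  if (length(table) != 64L || is.null(names(table)) ||
      anyDuplicated(names(table)) || !all(nchar(names(table)) == 3L)) {
    stop("codon table must map exactly the 64 DNA triplets", call. = FALSE)
  }
  invisible(table)
}

assert_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- regexpr(sprintf("[^%s]", alphabet), seq)
  if (bad > 0L) {
    stop(sprintf("%s contains invalid character '%s' at position %d",
                 what, substr(seq, bad, bad), bad), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq Single string over the alphabet `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement, same length.  The operation is an
#'   involution: `reverse_complement(reverse_complement(x)) == x`.
#' @export
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
reverse_complement <- function(seq) {
  assert_dna(seq, allow_n = TRUE)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Splice exon intervals out of a genomic sequence
#'
#' Concatenates the genomic slices `[lrg_start..lrg_end]` of each exon, in
#' exon order, producing the cDNA.
#'
#' @param genomic Genomic DNA string.
#' @param exons List of exons (see [new_exon()]) or any list whose elements
#'   carry `lrg_start` and `lrg_end`.
#' @return The spliced cDNA string; its length is the sum of exon lengths.
#' @export
#' @examples
#' e <- list(list(lrg_start = 1, lrg_end = 3), list(lrg_start = 7, lrg_end = 9))
#' splice_exons("AAACCCGGGTTT", e)  # "AAAGGG"
splice_exons <- function(genomic, exons) {
  assert_dna(genomic, allow_n = TRUE, what = "genomic sequence")
  n <- nchar(genomic)
  parts <- vapply(seq_along(exons), function(i) {
    ex <- exons[[i]]
    s <- as.integer(ex$lrg_start); e <- as.integer(ex$lrg_end)
    if (s < 1L || e > n || e < s) {
      stop(sprintf("exon %d interval [%d,%d] outside sequence of length %d",
                   i, s, e, n), call. = FALSE)
    }
    substr(genomic, s, e)
  }, character(1))
  paste(parts, collapse = "")
}

#' Translate a coding sequence
#'
#' Translates a CDS (start-codon first base through stop-codon last base)
#' with the standard genetic code, dropping the terminal stop.  The CDS is
#' taken as declared data: it need not begin with ATG, but it must be a
#' clean open reading frame.
#'
#' @param cds DNA string; length a multiple of 3 and at least 6, no `N`,
#'   exactly one stop codon and it must be the final codon.
#' @param table Codon table; defaults to [standard_codon_table()].
#' @return Amino-acid string of length `nchar(cds)/3 - 1`.
#' @export
#' @examples
#' translate_cds("ATGGGCTGA")  # "MG"
translate_cds <- function(cds, table = standard_codon_table()) {
  check_codon_table(table)
  assert_dna(cds, allow_n = TRUE, what = "CDS")
  len <- nchar(cds)
  if (len %% 3L != 0L) {
    stop(sprintf("CDS length %d is not a multiple of 3", len), call. = FALSE)
  }
  if (len < 6L) stop("CDS must contain at least two codons", call. = FALSE)
  if (grepl("N", cds, fixed = TRUE)) {
    stop("CDS contains N; translation would be ambiguous", call. = FALSE)
  }
  codons <- substring(cds, seq(1L, len - 2L, by = 3L), seq(3L, len, by = 3L))
  aa <- unname(table[codons])
  n_codons <- length(aa)
  internal_stops <- which(aa[-n_codons] == "*")
  if (length(internal_stops) > 0L) {
    stop(sprintf("internal stop codon at codon %d (CDS position %d)",
                 internal_stops[1], 3L * internal_stops[1] - 2L),
         call. = FALSE)
  }
  if (aa[n_codons] != "*") {
    stop("CDS does not end in a stop codon", call. = FALSE)
  }
  paste(aa[-n_codons], collapse = "")
}

#' Coding positions of a codon
#'
#' Returns the three c. anchors `(3n-2, 3n-1, 3n)` of residue `n`.
#'
#' @param residue_index Positive residue index.
#' @return Integer vector of length 3.
#' @export
#' @examples
#' codon_span(191)  # 571 572 573
codon_span <- function(residue_index) {
  n <- as.integer(residue_index)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("residue index must be a positive integer", call. = FALSE)
  }
  c(3L * n - 2L, 3L * n - 1L, 3L * n)
}

# amino-acid code conversions used by the HGVS layer
AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              "*" = "Ter")

aa_one_to_three <- function(one) {
  out <- AA_THREE[one]
  if (anyNA(out)) {
    stop("unknown amino-acid code: ", paste(one[is.na(out)], collapse = ","),
         call. = FALSE)
  }
  unname(out)
}

aa_three_to_one <- function(three) {
  lut <- stats::setNames(names(AA_THREE), AA_THREE)
  out <- lut[three]
  if (anyNA(out)) {
    stop("unknown 3-letter amino-acid code: ",
         paste(three[is.na(out)], collapse = ","), call. = FALSE)
  }
  unname(out)
}

complement_base <- function(base) {
  chartr("ACGTN", "TGCAN", base)
}
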
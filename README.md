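# lrgkit

Stable locus reference records for reporting sequence variants.

Clinical variant reporting needs a reference DNA sequence that never
changes: versioned genomic records silently alter the meaning of a
description like `g.8463G>C` when the sequence behind the accession moves.
The Locus Reference Genomic (LRG) approach fixes this with a two-layer
record per locus — an **immutable fixed layer** (the genomic sequence, the
transcripts, their exon markup, CDS bounds, cDNA and protein sequences)
under a permanent, never-versioned identifier, and a **date-stamped
updatable layer** (assembly mappings, cross-references, legacy numbering,
overlapping-gene reports) that may evolve freely. If the core content ever
needs an essential change — say a newly discovered upstream exon — a *new*
record with a *new* id is issued instead.

`lrgkit` implements that record model as a tested R library plus CLI, for
curators of locus-specific databases, diagnostic-lab bioinformaticians and
tool developers:

* record construction, validation (machine-readable findings, never
  exceptions) and a fixed-layer digest enforcing the new-id policy;
* the full HGVS coordinate algebra: genomic `g.`, coding-DNA `c.` (UTR
  numbering `c.-n` / `c.*n`, intron offsets `c.2451+77`), protein `p.`
  residues via codon arithmetic `residue = floor((pos-1)/3) + 1`;
* strand-aware mapping between the LRG and assembly/contig frames,
  including composite-sequence diffs, e.g. a gene stored as the reverse
  complement of contig bases 13535609..13553152;
* parsing/formatting of substitution descriptions
  (`LRG_1t1:c.572G>C`), conversion between systems and reference frames,
  and rescue of the deprecated `IVS36+77C>T` intron notation;
* XML serialization with a shipped, versioned schema dialect (strict fixed
  section, forward-compatible updatable section), plus FASTA, BED12, GFF3
  and plain-text rendering;
* deterministic synthetic-record generators with exhaustive per-base truth
  tables, used as brute-force oracles by the test suite.

All coordinates are 1-based and fully inclusive everywhere; only the BED
exporter converts to 0-based half-open, at that boundary alone.

## Worked example

The package ships an engineered, clearly synthetic collagen-like record
(`make_col1a1_like()`) on which the classic worked-example relations hold
simultaneously — a 50-exon transcript whose exon-36 donor sits at c.2451,
a GGC glycine codon at residue 191, and a minus-strand placement against a
pseudo-contig:

```r
library(lrgkit)
r <- make_col1a1_like()
r
#> <lrg_record LRG_1>
#>   fixed layer: 17544 nt genomic sequence, 1 transcript(s)
#>     t1: 50 exon(s), CDS 1101..17224
#>   updatable layer: 1 annotation set(s)

# protein consequence of a coding substitution (codon 191 GGC -> GCC)
format_hgvs(c_variant_to_p(r, "t1", parse_hgvs("LRG_1t1:c.572G>C")))
#> [1] "LRG_1p1:p.Gly191Ala"

# intronic position 77 nt past the exon-36 donor site
t1 <- r$fixed$transcripts[[1]]
format_coding_position(g_to_c(t1, t1$exons[[36]]$lrg_end + 77L))
#> [1] "2451+77"

# first LRG base on the reverse-complement contig placement
m <- r$updatable$annotation_sets[[1]]$mappings[[1]]
map_lrg_to_other(m, 1L)
#> <NT_010783.15:13553152 (-)>

# the fixed layer is immutable; updatable edits never move this value
fixed_layer_digest(r)
#> [1] "md5:7a26628ccccad7f413d6cf2ade168bec"
```

`LRG_1p1:p.Gly191Ala` says: in protein `p1` of record `LRG_1`, residue 191
changes from glycine to alanine — the protein-level consequence of the
coding-DNA substitution `c.572G>C`. Because pseudo-accessions are declared
sequence-identical in the updatable layer, the same description carries
over unchanged, e.g.
`translate_reference_frame(r, v, "NG_007400.1")` for a genomic variant `v`.

## Command line

```sh
exec/lrgkit fixture --name col1a1-like --out LRG_1.xml
exec/lrgkit validate --record LRG_1.xml          # findings TSV, exit code
exec/lrgkit map --record LRG_1.xml --from lrg --to assembly --pos 1
exec/lrgkit convert --record LRG_1.xml --to gff3
echo "LRG_1t1:c.572G>C" | exec/lrgkit hgvs convert --record LRG_1.xml --to p
```

## Documentation

The methods vignette (`vignettes/lrg-records.Rmd`) describes the record
model and its assumptions, every numbering convention and tie-break, what
the synthetic generators do and do not emulate, and known limitations.
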
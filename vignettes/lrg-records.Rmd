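---
title: "Locus reference records: model, coordinate algebra and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus reference records: model, coordinate algebra and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrgkit)
```

## The problem and the model

A variant description is only as stable as the reference sequence it is
written against. Versioned reference records change content under a fixed
accession; legacy gene sequences have unreliable intronic stretches; and
genes on the reverse strand of a genomic contig force error-prone
arithmetic on anyone reporting in contig coordinates. The locus reference
record model answers this with one record per locus and a strict
separation of concerns:

* **Fixed-annotation layer** — the genomic sequence, the transcripts
  (`t1`, `t2`, ...), their exon markup in three coordinate systems
  (LRG/genomic, cDNA, peptide), CDS bounds, cDNA sequences and translated
  proteins (`p1`, ...). This layer never changes under a given id. The
  record id (`LRG_<n>`) carries **no version**; an essential change to
  core content requires a new record with a new id.
* **Updatable-annotation layer** — date-stamped annotation sets holding
  assembly/contig mappings, cross-references (including the assertion
  that one specific version of an external record is sequence-identical),
  legacy numbering maps, overlapping-locus reports and free-text notes.

`validate_record()` makes the immutability guarantee checkable: the stored
cDNA must equal the splice of the exon intervals, the stored protein must
equal the translation of the declared CDS, exon markup must be internally
consistent, and every annotation set must carry an ISO 8601 date. All
problems are *findings* (severity, machine-readable code, location),
never exceptions, so broken records can be loaded and reported on. The
CLI's `--strict` flag turns warnings into a nonzero exit; the library
itself never throws during validation.

`fixed_layer_digest()` hashes a canonical, whitespace-free, key-ordered
serialization of fixed-layer fields only (`md5:` prefix makes the
algorithm self-describing; see *Design choices*). `check_new_id_policy()`
compares digests: updatable-layer edits are `allowed`, any fixed-layer
drift `requires_new_id`, with the first moved field named.

## Coordinate conventions

Everything in the package is **1-based and fully inclusive**. The single
exception is the BED12 exporter, which converts to BED's 0-based
half-open intervals at the output boundary only.

Coding-DNA (`c.`) positions follow HGVS usage:

* CDS bases are `1..cds_len`, counting the start-codon A of ATG as `c.1`
  and including the stop codon; CDS bounds are data declared by the
  record, so translation does not require the CDS to begin with ATG.
* the base immediately 5' of `c.1` is `c.-1` — there is no position 0;
* the base immediately 3' of the stop codon is `c.*1`;
* intronic bases anchor to the nearest exon boundary: `+k` after a donor,
  `-k` before an acceptor.

**Midpoint tie-break.** The published examples show only `+` offsets, so
the split of an intron between its two anchors was a genuinely open
choice. `lrgkit` assigns a base at distance `d` from the donor (intron
length `L`) to the `+` side iff `d <= ceiling(L/2)`: the proximal half
anchors upstream, the distal half downstream, and the equidistant middle
base of an odd-length intron belongs to the `+` side. This matches
standard HGVS practice, is deterministic, and makes the counts of `+` and
`-` labels in any intron differ by at most one (a tested property). The
naive per-base oracle in the synthetic generator states the same rule
independently as "closer-or-equal to the donor".

Consequences of the convention, chosen deliberately:

* `c_to_g()` refuses an offset that walks past the midpoint into
  territory labelled from the other boundary (e.g. `+131` in a 260-nt
  intron). Accepting it would give two names to one base; refusing keeps
  description → position single-valued.
* positions 5' of the first exon or 3' of the last exon are errors, not
  extended UTR labels — with no published example to anchor such labels,
  refusing is safer than guessing.
* protein residues come from pure codon arithmetic,
  `floor((anchor-1)/3) + 1`; positions in the stop codon map to one past
  the last stored residue (the stop is stored in the CDS but excluded
  from the protein string, conventional CDS semantics).

## Mapping between reference frames

A mapping span relates an LRG interval to an interval on an assembly or
contig, with strand ±1 and an optional list of sequence diffs
(`mismatch`, `lrg_insertion`, `other_insertion`) so a composite reference
can disagree with the assembly it maps to. Span geometry must close
exactly after accounting for diffs — this is validated, not assumed.
Mismatches are collinear in coordinates; insertions shift them; positions
inside either-side insertions are unmappable *by design* and the error
names the nearest mapped flanks, mirroring liftover semantics. Reverse
spans count downward from `other_end`, so the first LRG base of a gene
stored as the reverse complement of contig bases 13535609..13553152 maps
to 13553152 on the minus strand.

Variant descriptions cross frames two ways. Through a cross-reference
flagged *identical* (a specific external version asserted
sequence-identical), coordinates and edit carry over verbatim — only the
reference id changes. Through an assembly mapping, the position is
projected and, on a minus-strand span, the edit bases are complemented
(`g.1G>C` becomes `...:g.13553152C>G`). A stated reference base that
contradicts the record is a `REF_MISMATCH` error and is never
auto-corrected: the checkable reference base is precisely what protects
against silently mismatched reference versions.

## HGVS subset and the IVS rescue

Single-nucleotide substitutions (and their protein consequences) are the
supported core — every published worked example for this record format is
a substitution. del/dup/ins descriptions parse into a structured
"unsupported" edit that formats back losslessly but cannot be converted
between frames. Out of scope: inversions, repeats, uncertain positions,
and variant normalization (3'-shifting). Synonymous consequences render
as `p.(=)` (a documented dialect choice); missense uses 3-letter codes
(`p.Gly191Ala`); stop gains use `Ter`; substitutions destroying the stop
codon are refused (protein extension is out of scope). The deprecated
intron notation `IVS36+77C>T` is rejected by the parser with a dedicated
error and converted explicitly by `ivs_to_c()`, which anchors `IVS<k>+n`
to exon *k*'s last base and `IVS<k>-n` to exon *k+1*'s first base — the
conversion needs the transcript's exon structure, which is why it is a
separate, transcript-aware operation.

Reference suffixes imply the coordinate system (`t` → `c.`, `p` → `p.`,
bare id or genomic accession → `g.`) and the parser enforces the
consistency. Transcript numbers use longest-match digit runs, so `t12`
cannot be misread as `t1` + `2`.

## XML dialect and schema

The original schema of the hosted record format is not reproduced here;
`lrgkit` defines a documented dialect (`lrgkit-1.0`, shipped in
`inst/schema/lrg-dialect-1.0.xsd`) with the same two-section layout.
Strictness is asymmetric by design:

* **fixed section** — a closed contract: unknown elements are errors on
  read and schema violations; cDNA and protein sequences are stored
  explicitly *and* cross-checked by `validate_record()` (storing them
  makes files self-contained; the cross-check keeps them honest);
* **updatable section** — forward-compatible: after the mandatory
  `source` and `modification_date`, unknown elements are accepted,
  preserved verbatim as opaque fragments, and re-emitted byte-identically
  on the next write.

Constraints XSD cannot express (interval orientation, agreement of the
three exon coordinate systems, strand values) form a semantic stage of
`validate_xml()`, reported in the same `(path, message)` shape. The
writer is deterministic (stable element and attribute order, UTF-8, ISO
8601 dates) and refuses invalid records, so writer output always
validates — a tested coherence property.

## Synthetic data: what it emulates, what it does not

No real locus sequence ships with the package; every record is generated.

`make_synthetic_gene()` draws a gene model from `gene_model_spec()`:
defaults are a compact but structurally complete vertebrate-style gene —
8 exons of 30–200 nt, introns of 50–400 nt, 60/90 nt UTRs, 200 nt genomic
flanks, placed on a synthetic contig at a configurable strand and offset.
These sizes are chosen for exhaustive per-base testing (a few thousand
bases per fixture) while preserving every structural feature the
coordinate algebra must handle: multi-exon splicing, UTRs spanning exon
boundaries, intron anchoring on both sides, both mapping strands.
Sequences are uniform random bases with stop codons scrubbed from the CDS
frame (determinism and validity over realism). The generator also emits
**truth tables** computed by independent naive walks — per-base g.↔c.
labels, per-base assembly correspondence, per-residue codon map — which
are the brute-force oracles the conversions are tested against.

`make_col1a1_like()` is an engineered demonstration record: the published
numeric relations (donor of exon 36 at c.2451, GGC codon at residue 191,
reverse-complement placement over a 17544-nt contig interval, identical
pseudo-accession frames) hold on one synthetic locus, but the sequence is
deterministic filler, UTR lengths (100/200 nt) and uniform 260-nt introns
are unconstrained choices, and the exon count beyond the engineered
region is arbitrary. A green test on these fixtures establishes that the
*algebra* is correct, not that any real record is reproduced: splice-site
motifs, GC structure, repeat content and real exon-size distributions are
deliberately absent.

## Numerical and degenerate-input choices

* `N` is allowed in genomic sequence (warning) but is an error inside any
  CDS — translation must be deterministic. Other IUPAC degenerate codes
  are rejected outright.
* A fixed layer with zero transcripts (pure regulatory region) is
  permitted with a warning; non-coding transcripts are valid records, but
  `c.` coordinates on them are refused (`n.` numbering is reserved, not
  implemented).
* Transcripts are expressed on the forward strand of the LRG sequence;
  antisense overlapping genes are updatable-layer overlap reports, each
  deserving its own record, not extra fixed-layer transcripts.
* Mapping spans may not overlap in LRG coordinates, and target-side
  overlap (segmental duplication) is likewise disallowed pending a use
  case.
* Every updatable-layer substructure is optional; only the date stamp is
  mandatory per annotation set.
* The digest uses MD5 via base R (`tools::md5sum`) over the canonical
  fixed-layer text. The role of the hash is change *detection* for the
  new-id policy, not adversarial collision resistance; the `md5:` prefix
  keeps the record self-describing so the algorithm can be upgraded
  without ambiguity.
* Legacy residue renumbering is `legacy = systematic - shift` over
  declared, non-overlapping ranges (e.g. mature-protein numbering
  discounting a cleaved propeptide); a residue outside every range is an
  error listing the ranges, and an exon ordinal missing from a legacy
  scheme falls back to the systematic number with an explicit
  `systematic` provenance flag.

## Known limitations

* Substitutions only for cross-system conversion; no normalization.
* No projection through multi-record chains (LRG → assembly → second
  LRG); mappings are consumed as data, never computed by alignment.
* Only the standard genetic code ships (the table is pluggable, since
  records are not restricted to human loci); no alternative initiation,
  selenocysteine or frameshifting.
* No byte-compatibility with externally hosted record files, no record
  fetching, no HTML rendering, and no aggregation of known variants into
  the record — the record is the reference, not the database.
* Mitochondrial loci are out of scope.
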
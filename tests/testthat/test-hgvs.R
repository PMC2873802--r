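test_that("parse handles the printed description forms", {
  v <- parse_hgvs("LRG_13:g.8290C>A")
  expect_identical(v$reference, "LRG_13")
  expect_identical(v$system, "g")
  expect_identical(v$location, 8290L)
  expect_identical(v$edit, list(type = "sub", ref = "C", alt = "A"))

  v2 <- parse_hgvs("c.2451+77C>T")
  expect_null(v2$reference)
  expect_identical(v2$location$anchor, 2451L)
  expect_identical(v2$location$intron_offset, 77L)
  expect_identical(v2$edit$ref, "C")

  err <- tryCatch(parse_hgvs("IVS36+77C>T"), error = function(e) e)
  expect_s3_class(err, "lrg_hgvs_deprecated_ivs")
  expect_match(conditionMessage(err), "deprecated")

  expect_identical(parse_hgvs("c.-12G>A")$location$region, "UTR5")
  expect_identical(parse_hgvs("c.*46T>C")$location$anchor, 46L)
  expect_identical(parse_hgvs("c.*46+3T>C")$location$intron_offset, 3L)
  expect_identical(parse_hgvs("c.101-1G>A")$location$intron_offset, -1L)
})

test_that("parse reports character offsets and inconsistencies", {
  err <- tryCatch(parse_hgvs("g.12Q>A"), error = function(e) e)
  expect_s3_class(err, "lrg_hgvs_error")
  expect_match(conditionMessage(err), "character")
  expect_error(parse_hgvs("x.100A>T"), "coordinate system")
  expect_error(parse_hgvs("LRG_1t1:g.100A>T"), "implies the 'c\\.'")
  expect_error(parse_hgvs("LRG_1p1:c.100A>T"), "implies the 'p\\.'")
  expect_error(parse_hgvs("bad id:c.100A>T"), "reference identifier")
  expect_error(parse_hgvs("c.0A>T"), "c\\.0")
  expect_error(parse_hgvs("p.Gl191Ala"), "protein substitution")
})

test_that("parse/format are mutual inverses on a generated corpus", {
  refs <- list(NULL, "LRG_1", "LRG_12t3", "LRG_4p2", "NM_000088.3",
               "NG_007400.1", "NP_000079.2")
  with_seed_local(21, {
    for (i in 1:300) {
      ref <- refs[[sample.int(length(refs), 1)]]
      system <- if (is.null(ref)) sample(c("g", "c", "p"), 1) else
        switch(lrgkit:::implied_system(ref), g = "g", c = "c", p = "p")
      v <- if (system == "g") {
        new_variant("g", sample.int(99999L, 1),
                    list(type = "sub", ref = sample(c("A", "C", "G", "T"), 1),
                         alt = sample(c("A", "C", "G", "T"), 1)),
                    reference = ref)
      } else if (system == "c") {
        region <- sample(c("CDS", "UTR5", "UTR3"), 1)
        anchor <- if (region == "UTR5") -sample.int(300L, 1) else
          sample.int(3000L, 1)
        off <- sample(c(0L, sample(c(-60:-1, 1:60), 1)), 1)
        new_variant("c", new_coding_position(region, anchor, off),
                    list(type = "sub", ref = sample(c("A", "C", "G", "T"), 1),
                         alt = sample(c("A", "C", "G", "T"), 1)),
                    reference = ref)
      } else {
        aas <- setdiff(unname(lrgkit:::AA_THREE), "Ter")
        new_variant("p", sample.int(2000L, 1),
                    list(type = "sub", ref = sample(aas, 1),
                         alt = sample(c(sample(aas, 1), "Ter"), 1)),
                    reference = ref)
      }
      txt <- format_hgvs(v)
      expect_identical(parse_hgvs(txt), v, label = txt)
      expect_identical(format_hgvs(parse_hgvs(txt)), txt)
    }
  })
})

test_that("UTR3 rendering and unsupported edits round trip losslessly", {
  v <- new_variant("c", new_coding_position("UTR3", 46),
                   list(type = "sub", ref = "T", alt = "C"))
  expect_identical(format_hgvs(v), "c.*46T>C")
  expect_identical(
    format_hgvs(new_variant("p", 191, list(type = "sub", ref = "Gly",
                                           alt = "Ala"))),
    "p.Gly191Ala")

  for (txt in c("c.76del", "g.123dup", "c.76_78delACT", "g.100_101insA")) {
    v <- parse_hgvs(txt)
    expect_identical(v$edit$type, "unsupported")
    expect_identical(format_hgvs(v), txt)
    expect_error(
      g_variant_to_c(make_col1a1_like(), "t1",
                     new_variant("g", 100L, v$edit)),
      "substitution")
  }
})

test_that("IVS conversion anchors to the correct exon boundaries", {
  r <- make_col1a1_like()
  t1 <- r$fixed$transcripts[[1]]
  v <- ivs_to_c(t1, "IVS36+77C>T")
  expect_identical(format_hgvs(v), "c.2451+77C>T")

  # 2-exon toy: exon 1 carries c.1..100, exon 2 starts at c.101
  toy <- toy_two_exon()
  tt <- toy$fixed$transcripts[[1]]
  expect_identical(format_hgvs(ivs_to_c(tt, "IVS1-1G>A")), "c.101-1G>A")
  expect_identical(ivs_to_c(tt, "IVS1+2A>T")$location$anchor, 100L)
  expect_error(ivs_to_c(tt, "IVS99+1A>T"), "99")
  expect_error(ivs_to_c(tt, "IVS2+1A>T"), "1 introns")
})

test_that("g -> c variant conversion checks the stated reference base", {
  r <- make_col1a1_like()
  t1 <- r$fixed$transcripts[[1]]
  x <- c_to_g(t1, new_coding_position("CDS", 572))
  expect_identical(substr(r$fixed$sequence, x, x), "G")
  v <- g_variant_to_c(r, "t1",
                      new_variant("g", x, list(type = "sub", ref = "G",
                                               alt = "C"),
                                  reference = "LRG_1"))
  expect_identical(format_hgvs(v), "LRG_1t1:c.572G>C")

  # intronic position converts to anchor+offset form
  gi <- t1$exons[[36]]$lrg_end + 77L
  base <- substr(r$fixed$sequence, gi, gi)
  vi <- g_variant_to_c(r, "t1", new_variant("g", gi,
                                            list(type = "sub", ref = base,
                                                 alt = setdiff(c("A", "C", "G", "T"), base)[1])))
  expect_identical(vi$location$anchor, 2451L)
  expect_identical(vi$location$intron_offset, 77L)

  wrong <- setdiff(c("A", "C", "G", "T"), substr(r$fixed$sequence, x, x))[1]
  err <- tryCatch(
    g_variant_to_c(r, "t1", new_variant("g", x, list(type = "sub",
                                                     ref = wrong, alt = "C"))),
    error = function(e) e)
  expect_s3_class(err, "lrg_ref_mismatch")
  expect_match(conditionMessage(err), "REF_MISMATCH")

  # g -> c -> g round trip preserves position and edit across the span
  with_seed_local(31, {
    fx <- make_synthetic_gene(gene_model_spec(seed = 17))
    rec <- fx$record
    tr <- rec$fixed$transcripts[[1]]
    span <- c(tr$exons[[1]]$lrg_start,
              tr$exons[[length(tr$exons)]]$lrg_end)
    for (p in sample(span[1]:span[2], 120L)) {
      base <- substr(rec$fixed$sequence, p, p)
      alt <- setdiff(c("A", "C", "G", "T"), base)[1]
      vc <- g_variant_to_c(rec, "t1",
                           new_variant("g", p, list(type = "sub", ref = base,
                                                    alt = alt)))
      expect_identical(c_to_g(tr, vc$location), p)
      expect_identical(vc$edit, list(type = "sub", ref = base, alt = alt))
    }
  })
})

test_that("c -> p reproduces the printed codon example and refusals", {
  r <- make_col1a1_like()
  pv <- c_variant_to_p(r, "t1", parse_hgvs("LRG_1t1:c.572G>C"))
  expect_identical(format_hgvs(pv), "LRG_1p1:p.Gly191Ala")

  # synonymous: identical base, and a third-position wobble change
  expect_identical(
    format_hgvs(c_variant_to_p(r, "t1",
      new_variant("c", new_coding_position("CDS", 3),
                  list(type = "sub", ref = "G", alt = "G")))),
    "LRG_1p1:p.(=)")
  expect_identical(
    format_hgvs(c_variant_to_p(r, "t1",
      new_variant("c", new_coding_position("CDS", 573),
                  list(type = "sub", ref = "C", alt = "A")))),
    "LRG_1p1:p.(=)")   # GGC -> GGA, both glycine

  expect_error(
    c_variant_to_p(r, "t1", parse_hgvs("c.2451+77C>T")), "outside the CDS")
  expect_error(
    c_variant_to_p(r, "t1", parse_hgvs("c.-5G>A")), "outside the CDS")
  err <- tryCatch(
    c_variant_to_p(r, "t1",
                   new_variant("c", new_coding_position("CDS", 572),
                               list(type = "sub", ref = "T", alt = "C"))),
    error = function(e) e)
  expect_s3_class(err, "lrg_ref_mismatch")
})

test_that("c -> p agrees with whole-CDS re-translation for every substitution", {
  fx <- small_cds_fixture()
  rec <- fx$record
  t1 <- rec$fixed$transcripts[[1]]
  cds_c1 <- lrgkit:::lrg_to_cdna_pos(t1$exons, t1$coding_region$cds_start)
  cds_c2 <- lrgkit:::lrg_to_cdna_pos(t1$exons, t1$coding_region$cds_end)
  cds_seq <- substr(t1$cdna_sequence, cds_c1, cds_c2)
  n_prot <- nchar(t1$protein$sequence)

  for (cpos in seq_len(nchar(cds_seq))) {
    ref <- substr(cds_seq, cpos, cpos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- new_variant("c", new_coding_position("CDS", cpos),
                       list(type = "sub", ref = ref, alt = alt))
      want <- protein_consequence_oracle(cds_seq, cpos, alt)
      got <- tryCatch(c_variant_to_p(rec, "t1", v), error = function(e) e)
      lab <- sprintf("c.%d%s>%s", cpos, ref, alt)
      if (want$kind == "synonymous") {
        expect_identical(got$edit$type, "synonymous", label = lab)
      } else if (want$kind == "stop_loss") {
        expect_s3_class(got, "error")
        expect_match(conditionMessage(got), "stop codon", label = lab)
      } else {
        expect_false(inherits(got, "error"), label = lab)
        expect_identical(got$location, want$residue, label = lab)
        expect_identical(got$edit$ref,
                         unname(lrgkit:::AA_THREE[want$ref]), label = lab)
        expect_identical(got$edit$alt,
                         unname(lrgkit:::AA_THREE[want$alt]), label = lab)
      }
    }
  }
})

test_that("reference-frame translation: identity crossrefs and reverse mapping", {
  r <- make_col1a1_like()

  base <- substr(r$fixed$sequence, 8463, 8463)
  v <- new_variant("g", 8463L, list(type = "sub", ref = base, alt = "C"),
                   reference = "LRG_1")
  out <- translate_reference_frame(r, v, "NG_007400.1")
  expect_identical(out$location, v$location)
  expect_identical(out$edit, v$edit)
  expect_identical(out$reference, "NG_007400.1")

  vc <- parse_hgvs("LRG_1t1:c.572G>C")
  expect_identical(format_hgvs(translate_reference_frame(r, vc, "NM_000088.3")),
                   "NM_000088.3:c.572G>C")

  # reverse-strand contig frame: edit bases complemented
  gv <- new_variant("g", 1L, list(type = "sub", ref = "G", alt = "C"),
                    reference = "LRG_1")
  out2 <- translate_reference_frame(r, gv, "NT_010783.15")
  expect_identical(out2$location, 13553152L)
  expect_identical(out2$edit, list(type = "sub", ref = "C", alt = "G"))

  err <- tryCatch(translate_reference_frame(r, v, "XX_1.1"),
                  error = function(e) e)
  expect_match(conditionMessage(err), "NG_007400.1")
  expect_match(conditionMessage(err), "NT_010783.15")
})
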
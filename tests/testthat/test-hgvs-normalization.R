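test_that("protein substitutions normalize to one-letter form with * stops", {
  expect_equal(normalize_protein_sub("Ala", 140, "Thr")$hgvs, "A140T")
  expect_equal(normalize_protein_sub("Gly", 12, "Gly")$hgvs, "G12G")
  expect_equal(normalize_protein_sub("Arg", 226, "Stop")$hgvs, "R226*")
  expect_equal(normalize_protein_sub("G", 12, "D")$hgvs, "G12D")
  expect_equal(normalize_protein_sub("Glutamate", 6, "Valine")$hgvs,
               "E6V")
  expect_error(normalize_protein_sub("Xyz", 5, "Thr"), "unknown")
})

test_that("cDNA substitutions normalize with the c. prefix", {
  expect_equal(normalize_dna_sub(676, "C", "T")$hgvs, "c.676C>T")
  expect_equal(normalize_dna_sub(1, "A", "G")$hgvs, "c.1A>G")
  expect_error(normalize_dna_sub(5, "A", "A"), "degenerate")
  expect_error(normalize_dna_sub(5, "A", "U"), "nucleotides")
  # intronic offsets are carried verbatim as opaque position tokens
  expect_equal(normalize_dna_sub("1410-54", "C", "T")$hgvs,
               "c.1410-54C>T")
})

test_that("indels get underscore ranges and a restored c. prefix", {
  expect_equal(normalize_indel("c.597-598delGA")$hgvs, "c.597_598delGA")
  expect_equal(normalize_indel("c.501delG")$hgvs, "c.501delG")
  expect_equal(normalize_indel("840insT")$hgvs, "c.840insT")
  expect_equal(normalize_indel("1704_1705delAG")$hgvs,
               "c.1704_1705delAG")
  expect_error(normalize_indel("nonsense"), "unparseable")
  expect_error(normalize_indel("840insT", tolerant_prefix = FALSE),
               "prefix")
})

test_that("codon positions expand to three consecutive candidates", {
  expect_equal(expand_codon(1), c(1L, 2L, 3L))
  expect_equal(expand_codon(140), c(418L, 419L, 420L))
  expect_error(expand_codon(0))
  for (c_i in c(2L, 17L, 1000L)) {
    p <- expand_codon(c_i)
    expect_length(p, 3L)
    expect_equal(diff(p), c(1L, 1L))
    expect_equal(p[3], 3L * c_i)
  }
})

test_that("rs-number expansion passes through the local lookup", {
  lk <- load_rsid_lookup(system.file("extdata", "rsid_lookup.tsv",
                                     package = "varminer"))
  cands <- expand_rsid("rs1000", lk)
  expect_setequal(vapply(cands, `[[`, "", "hgvs"), c("c.35G>A", "G12D"))
  expect_length(suppressMessages(expand_rsid("rs9999999", lk)), 0L)
  expect_error(expand_rsid("rsX", lk), "malformed")
})

test_that("imprecise mentions are dropped before normalization", {
  sec <- document_section("body",
                          "Del exon 3 and entire gene deletion and c.676C>T")
  m <- scan_mentions(sec)
  dropped <- m[m$exon_intron, ]
  kept <- m[!m$exon_intron, ]
  expect_equal(nrow(dropped), 2L)
  for (i in seq_len(nrow(dropped))) {
    expect_null(drop_imprecise(dropped[i, ]))
    expect_length(normalize_mention(dropped[i, ]), 0L)
  }
  v <- normalize_mention(kept[1, ])
  expect_equal(v[[1]]$hgvs, "c.676C>T")
})

test_that("deletion length equivalence behaves as configured", {
  on <- match_config(del_length_equivalence = TRUE)
  off <- match_config()
  a <- normalized_variant("dna", "c.482_483delGA")
  b <- normalized_variant("dna", "c.482_483del2")
  expect_true(variant_equivalent(a, b, on))
  expect_false(variant_equivalent(a, b, off))
  expect_true(variant_equivalent(normalized_variant("dna", "c.501delG"),
                                 normalized_variant("dna", "c.501del1"),
                                 on))
  expect_false(variant_equivalent(a,
                                  normalized_variant("dna",
                                                     "c.482_483del3"),
                                  on))
})

test_that("equivalence is level-gated, reflexive, symmetric and reduces to equality", {
  d <- normalized_variant("dna", "c.35G>A")
  p <- normalized_variant("protein", "G12D")
  expect_false(variant_equivalent(d, p))
  strict <- match_config(del_length_equivalence = FALSE,
                         codon_expansion = FALSE, rsid_expansion = FALSE)
  vars <- list(d, p, normalized_variant("dna", "c.501delG"),
               normalized_variant("dna", "c.35G>A", alternates = "c.36G>A",
                                  provenance = "codon"))
  for (a in vars) for (b in vars) {
    expect_equal(variant_equivalent(a, b, strict),
                 a$level == b$level && a$hgvs == b$hgvs)
    expect_equal(variant_equivalent(a, b), variant_equivalent(b, a))
  }
})

test_that("relaxations are monotone: no flag turns a true equivalence false", {
  pairs <- list(
    list(normalized_variant("dna", "c.482_483delGA"),
         normalized_variant("dna", "c.482_483del2")),
    list(normalized_variant("dna", "c.35G>A"),
         normalized_variant("dna", "c.34G>A",
                            alternates = c("c.34G>A", "c.35G>A", "c.36G>A"),
                            provenance = "codon")),
    list(normalized_variant("dna", "c.676C>T"),
         normalized_variant("dna", "c.676C>T")))
  base <- match_config()
  flags <- c("ignore_gene", "del_length_equivalence", "tolerant_prefix",
             "codon_expansion", "rsid_expansion")
  for (pr in pairs) {
    was <- variant_equivalent(pr[[1]], pr[[2]], base)
    for (f in flags) {
      cfg <- base
      cfg[[f]] <- TRUE
      if (was) expect_true(variant_equivalent(pr[[1]], pr[[2]], cfg),
                           info = f)
    }
  }
})

test_that("normalizing already-canonical mentions is the identity", {
  canon <- c("c.676C>T", "c.1A>G", "c.597_598delGA", "c.501delG",
             "c.840insT", "c.100_105dup")
  sec <- document_section("body", paste(canon, collapse = " and "))
  m <- scan_mentions(sec)
  out <- vapply(seq_len(nrow(m)), function(i) {
    normalize_mention(m[i, ])[[1]]$hgvs
  }, "")
  expect_setequal(out, canon)
})
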
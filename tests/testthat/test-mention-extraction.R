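sec_of <- function(text) document_section("body", text)

test_that("the scanner recognizes the catalogued surface forms", {
  m <- scan_mentions(sec_of("we saw c580G > T there"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$mention_class, "dna_sub")
  expect_equal(m$pos, "580")
  expect_equal(m$wt, "G")
  expect_equal(m$mut, "T")

  m <- scan_mentions(sec_of("a C > T mutation at nucleotide 2131 was"))
  expect_equal(m$mention_class, "nl_sub")
  expect_equal(m$pos, "2131")
  expect_false(m$codon)

  m <- scan_mentions(sec_of("carrying p.Glu554_Val559del allele"))
  expect_equal(m$mention_class, "protein_indel")

  expect_equal(nrow(scan_mentions(sec_of("the cat sat"))), 0L)

  # further forms: canonical, legacy, rsid, indel, codon-positioned
  forms <- c("c.676C>T" = "dna_sub", "676C>T" = "dna_sub",
             "C676T" = "dna_sub", "Ala140Thr" = "protein_sub",
             "p.G12D" = "protein_sub", "rs121913529" = "rsid",
             "c.597_598delGA" = "dna_indel", "840insT" = "dna_indel",
             "c.501del1" = "dna_indel")
  for (i in seq_along(forms)) {
    m <- scan_mentions(sec_of(paste("x", names(forms)[i], "y")))
    expect_equal(nrow(m), 1L, info = names(forms)[i])
    expect_equal(m$mention_class, unname(forms[i]), info = names(forms)[i])
  }
  m <- scan_mentions(sec_of("G > A mutation at codon 12"))
  expect_true(m$codon)
})

test_that("imprecise exon/intron mentions are flagged", {
  for (txt in c("Del exon 3", "deletion of exon 5", "intron 2 deletion",
                "entire gene deletion")) {
    m <- scan_mentions(sec_of(txt))
    expect_equal(nrow(m), 1L, info = txt)
    expect_true(m$exon_intron, info = txt)
  }
})

test_that("spans are disjoint, match the text, and ties go leftmost-longest", {
  txt <- "noted c.676C>T and 840insT plus c.597-598delGA in text"
  m <- scan_mentions(sec_of(txt))
  # raw equals the section substring at the span (0-based half-open)
  for (i in seq_len(nrow(m))) {
    expect_equal(substr(txt, m$start[i] + 1L, m$end[i]), m$raw[i])
  }
  m <- m[order(m$start), ]
  expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  # the prefix-free sub pattern must not fire inside the canonical one
  expect_equal(m$raw[1], "c.676C>T")
})

test_that("enabling extra pattern classes never removes mentions", {
  txt <- paste("c.676C>T and C > T mutation at nucleotide 21 and",
               "p.Glu554_Val559del and rs100 and Ala140Thr and Del exon 3")
  base <- pattern_config(protein_sub = FALSE, protein_indel = FALSE,
                         rsid = FALSE, nl_sub = FALSE,
                         exon_intron = FALSE)
  m0 <- scan_mentions(sec_of(txt), base)
  flags <- c("protein_sub", "protein_indel", "rsid", "nl_sub",
             "exon_intron")
  cfgs <- base
  for (f in flags) {
    cfgs[[f]] <- TRUE
    m1 <- scan_mentions(sec_of(txt), cfgs)
    expect_true(all(m0$raw %in% m1$raw), info = f)
    m0 <- m1
  }
})

test_that("gene scanning is dictionary-driven with alias and stop-list rules", {
  dict <- default_gene_dictionary()
  g <- scan_genes(sec_of("hMLH1 variants observed"), dict)
  expect_equal(nrow(g), 0L) # h-prefix off by default
  g <- scan_genes(sec_of("hMLH1 variants observed"), dict,
                  strip_h_prefix = TRUE)
  expect_equal(g$symbol, "MLH1")

  g <- scan_genes(sec_of("a P53 mutation"), dict)
  expect_equal(g$symbol, "TP53")

  # stop-listed surface forms never match
  expect_true("ARG" %in% dict$stop_list)
  expect_false("ARG" %in% dict$entries$surface)
  g <- scan_genes(sec_of("the ARG residue"), dict)
  expect_equal(nrow(g), 0L)

  # matching is case-insensitive over word boundaries
  g <- scan_genes(sec_of("kras and KRASX"), dict)
  expect_equal(g$symbol, "KRAS")
  expect_equal(nrow(g), 1L)
})

test_that("association pairs mentions with co-occurring genes per scope", {
  txt <- "KRAS and TP53 studied. We saw c.35G>A here."
  mentions <- scan_mentions(sec_of(txt))
  genes <- scan_genes(sec_of(txt), default_gene_dictionary())
  out <- associate(mentions, genes, "document")
  expect_equal(nrow(out), 2L) # one mention x two genes
  expect_setequal(out$gene_symbol, c("KRAS", "TP53"))

  out0 <- associate(mentions, genes[0, ], "document")
  expect_equal(nrow(out0), 1L)
  expect_true(is.na(out0$gene_symbol))

  # sentence scope: gene and mention in different sentences -> absent
  outs <- associate(mentions, genes, "sentence", text = txt)
  expect_equal(nrow(outs), 1L)
  expect_true(is.na(outs$gene_symbol))
})

test_that("document-scope association count follows the counting identity", {
  txt <- paste("KRAS TP53 seen. c.35G>A and c.36G>A and 840insT.")
  mentions <- scan_mentions(sec_of(txt))
  genes <- scan_genes(sec_of(txt), default_gene_dictionary())
  out <- associate(mentions, genes, "document")
  n_genes <- length(unique(genes$symbol))
  expect_equal(nrow(out), nrow(mentions) * n_genes)
})
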
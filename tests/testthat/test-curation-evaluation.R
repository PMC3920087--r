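triple <- function(doc, gene, hgvs, level = NULL, source = "body",
                   hgnc = NA_character_, alternates = character(),
                   provenance = NA_character_) {
  if (is.null(level)) {
    level <- if (startsWith(hgvs, "c.")) "dna" else "protein"
  }
  tibble::tibble(doc_id = doc, source_kind = source, gene_symbol = gene,
                 gene_hgnc_id = hgnc, level = level, hgvs = hgvs,
                 alternates = list(alternates), provenance = provenance)
}

record <- function(doc, gene, dna = NA, prot = NA, hgnc = NA) {
  tibble::tibble(doc_id = doc, gene_symbol = gene,
                 hgnc_id = as.character(hgnc),
                 dna_hgvs = as.character(dna),
                 protein_hgvs = as.character(prot))
}

test_that("a record matches through either variant, gated by the gene test", {
  rec <- record("d1", "KRAS", dna = "c.35G>A", prot = "G12D")
  expect_true(record_matches(rec, triple("d1", "KRAS", "G12D")))
  expect_true(record_matches(rec, triple("d1", "KRAS", "c.35G>A")))

  wrong_gene <- triple("d1", "TP53", "G12D")
  expect_false(record_matches(rec, wrong_gene))
  expect_true(record_matches(rec, wrong_gene,
                             match_config(ignore_gene = TRUE)))

  expect_false(record_matches(rec, triple("d2", "KRAS", "c.35G>A")))

  # HGNC identity is preferred when both sides carry one
  rec2 <- record("d1", "KRAS", dna = "c.35G>A", hgnc = "HGNC:6407")
  expect_true(record_matches(rec2, triple("d1", "kras", "c.35G>A",
                                          hgnc = "HGNC:6407")))
  expect_false(record_matches(rec2, triple("d1", "KRAS", "c.35G>A",
                                           hgnc = "HGNC:9999")))
  # absent gene on the triple never satisfies the strict gene test
  expect_false(record_matches(rec, triple("d1", NA_character_, "G12D")))
})

test_that("compute_recall divides matched records by the right denominators", {
  curated <- dplyr::bind_rows(
    record("d1", "KRAS", dna = "c.35G>A"),
    record("d1", "KRAS", dna = "c.36G>A"),
    record("d2", "TP53", prot = "R175H"),
    record("d2", "TP53", prot = "R273C"))
  tri <- dplyr::bind_rows(triple("d1", "KRAS", "c.35G>A"),
                          triple("d2", "TP53", "R175H"))
  rep <- compute_recall(curated, tri, c("d1", "d2"))
  expect_equal(rep$recall, 0.5)
  expect_equal(rep$recall_common, 0.5)
  expect_equal(rep$n_common_art, 2L)

  # denominator restriction: only d1 yields extractions
  curated10 <- dplyr::bind_rows(
    record("d1", "KRAS", dna = "c.35G>A"),
    record("d1", "KRAS", dna = "c.40A>T"),
    lapply(paste0("x", 1:8),
           function(d) record(d, "TP53", prot = "R175H")))
  tri10 <- dplyr::bind_rows(triple("d1", "KRAS", "c.35G>A"),
                            triple("d1", "KRAS", "c.40A>T"))
  rep <- compute_recall(curated10, tri10, unique(curated10$doc_id))
  expect_equal(rep$recall, 0.2)
  expect_equal(rep$recall_common, 1.0)

  expect_error(compute_recall(record("d", "G")[0, ], tri, "d"),
               "undefined")
})

test_that("duplicate curated rows count once", {
  curated <- dplyr::bind_rows(record("d1", "KRAS", dna = "c.35G>A"),
                              record("d1", "KRAS", dna = "c.35G>A"),
                              record("d1", "KRAS", dna = "c.36G>A"))
  rep <- compute_recall(curated, triple("d1", "KRAS", "c.35G>A"), "d1")
  expect_equal(rep$n_curated, 2L)
  expect_equal(rep$recall, 0.5)
})

test_that("per-source rows behave as unions of their member sources", {
  curated <- dplyr::bind_rows(record("d1", "KRAS", dna = "c.35G>A"),
                              record("d1", "KRAS", dna = "c.36G>A"))
  tri <- dplyr::bind_rows(
    triple("d1", "KRAS", "c.35G>A", source = "supplement"),
    triple("d1", "KRAS", "c.36G>A", source = "supplement"))
  tab <- per_source_evaluation(tri, curated, "d1")
  get <- function(s) tab$recall[tab$source_set == s]
  expect_equal(get("supplement"), get("all"))
  expect_equal(get("abstract"), 0)
  expect_equal(get("body"), 0)

  # disjoint matches from body and table add up in the combined row
  tri2 <- dplyr::bind_rows(triple("d1", "KRAS", "c.35G>A", source = "body"),
                           triple("d1", "KRAS", "c.36G>A",
                                  source = "table"))
  tab2 <- per_source_evaluation(tri2, curated, "d1")
  expect_equal(tab2$matched[tab2$source_set == "body+table"],
               tab2$matched[tab2$source_set == "body"] +
                 tab2$matched[tab2$source_set == "table"])
})

test_that("abstract precision against full text is a restricted intersection", {
  t1 <- triple("d1", "KRAS", "c.35G>A")
  t2 <- triple("d1", "KRAS", "c.36G>A")
  t3 <- triple("d1", "TP53", "R175H")
  expect_equal(abstract_vs_fulltext_precision(
    dplyr::bind_rows(t1, t2), dplyr::bind_rows(t1, t2, t3)), 1.0)
  expect_equal(abstract_vs_fulltext_precision(
    dplyr::bind_rows(t1, t2), t1), 0.5)
  # triples in articles absent from the full-text set are excluded
  t_other <- triple("d9", "KRAS", "c.35G>A")
  expect_equal(abstract_vs_fulltext_precision(
    dplyr::bind_rows(t1, t_other), t1), 1.0)
  expect_error(abstract_vs_fulltext_precision(t1[0, ], t1), "undefined")
})

test_that("threshold grouping sizes, shares and ordering are correct", {
  counts <- c(d1 = 3, d2 = 12, d3 = 25, d4 = 40)
  curated <- dplyr::bind_rows(lapply(names(counts), function(d) {
    dplyr::bind_rows(lapply(seq_len(counts[[d]]), function(i) {
      record(d, "KRAS", dna = paste0("c.", i, "A>G"))
    }))
  }))
  tri <- triple("d1", "KRAS", "c.1A>G")
  tg <- threshold_grouping(curated, c(10, 20, 30), tri,
                           unique(curated$doc_id))
  expect_equal(tg$group, c("<=10", "<=20", "<=30", ">30"))
  expect_equal(tg$n_docs_with_mut, c(1L, 2L, 3L, 1L))
  expect_equal(tg$mutation_share[tg$group == ">30"], 40 / 80)
  expect_error(threshold_grouping(curated, c(30, 10), tri,
                                  unique(curated$doc_id)), "ascending")
})

test_that("corpus statistics summarize per-article mutation counts", {
  curated <- dplyr::bind_rows(
    lapply(1:10, function(i) record("d1", "KRAS",
                                    dna = paste0("c.", i, "A>G"))),
    record("d2", "TP53", prot = "R175H"))
  st <- corpus_stats(curated, corpus_docs = c("d1", "d2", "d3"))
  expect_equal(st$n_docs, 3L)
  expect_equal(st$n_docs_with_mut, 2L)
  expect_equal(st$n_mutations, 11L)
  expect_equal(st$mean_mut_per_doc, 5.5)
  expect_equal(st$sd_mut_per_doc, stats::sd(c(10, 1)))
})
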
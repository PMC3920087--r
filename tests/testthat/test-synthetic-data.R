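test_that("generator configurations are validated", {
  expect_error(generator_config(placement = c(abstract = 0.5)),
               "summing to 1")
  expect_error(generator_config(format_mix = c(bogus = 1)), "named")
  expect_error(generator_config(distractor_rate = -1))
  expect_s3_class(generator_config(), "generator_config")
})

test_that("generation is a pure function of the configuration", {
  cfg <- generator_config(n_articles = 8, seed = 5)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$curated, b$curated)
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$bundles, `[[`, "sections"),
                   lapply(b$bundles, `[[`, "sections"))
})

test_that("an empty corpus is representable", {
  corpus <- generate_corpus(generator_config(n_articles = 0, seed = 1))
  expect_equal(nrow(corpus$curated), 0L)
  expect_length(corpus$bundles, 0L)
})

test_that("conventional-article counts follow the configured Poisson law", {
  cfg <- generator_config(n_articles = 500, ht_fraction = 0,
                          lambda_nht = 5, distractor_rate = 0,
                          seed = 99)
  corpus <- generate_corpus(cfg)
  counts <- table(factor(corpus$curated$doc_id,
                         levels = names(corpus$bundles)))
  m <- mean(counts)
  se <- sqrt(5 / 500)
  expect_lt(abs(m - 5), 3 * se)
})

test_that("rendering honours the placement and format contracts", {
  cfg <- generator_config(n_articles = 6, lambda_nht = 4,
                          ht_fraction = 0, distractor_rate = 0,
                          footnote_rate = 0,
                          placement = c(table = 1),
                          format_mix = c(canonical_hgvs = 1), seed = 3)
  corpus <- generate_corpus(cfg)
  man <- corpus$manifest
  for (i in seq_len(nrow(man))) {
    b <- corpus$bundles[[man$doc_id[i]]]
    tab <- b$sections$text[b$sections$source_kind == "table"]
    hits <- gregexpr(man$dna_hgvs[i], tab, fixed = TRUE)[[1]]
    planted_here <- sum(man$dna_hgvs == man$dna_hgvs[i] &
                          man$doc_id == man$doc_id[i])
    expect_equal(sum(hits > 0), planted_here, info = man$dna_hgvs[i])
    expect_false(any(grepl(man$dna_hgvs[i],
                           b$sections$text[b$sections$source_kind !=
                                             "table"], fixed = TRUE)))
  }
})

test_that("field-split supplements contain no scannable mention", {
  cfg <- generator_config(n_articles = 6, lambda_nht = 4,
                          ht_fraction = 0, distractor_rate = 0,
                          format_mix = c(split_fields = 1), seed = 4)
  corpus <- generate_corpus(cfg)
  for (b in corpus$bundles) {
    for (i in seq_len(nrow(b$sections))) {
      m <- scan_mentions(b$sections[i, ])
      vars <- normalize_mentions_bulk(m)
      expect_equal(nrow(vars), 0L)
    }
  }
})

test_that("footnote noise decorates table cells with declared marks", {
  cfg <- generator_config(n_articles = 10, lambda_nht = 5,
                          ht_fraction = 0, distractor_rate = 0,
                          footnote_rate = 1,
                          placement = c(table = 1),
                          format_mix = c(canonical_hgvs = 1), seed = 6)
  corpus <- generate_corpus(cfg)
  grids <- Filter(Negate(is.null), corpus$grids)
  expect_gt(length(grids), 0L)
  decorated <- FALSE
  for (g in grids) {
    if (length(g$footnote_marks)) {
      decorated <- TRUE
      cls <- paste0("[", paste(g$footnote_marks, collapse = ""), "]")
      expect_true(any(grepl(cls, g$cells)))
      # linearization strips them
      expect_false(grepl(cls, linearize_table(g)$text))
    }
  }
  expect_true(decorated)
  # the decorated mentions are still recovered by the pipeline
  res <- evaluate_corpus(corpus$bundles, corpus$curated)
  exp <- expected_recall(corpus$manifest)
  expect_equal(as.data.frame(res$per_source),
               as.data.frame(exp)[, names(res$per_source)])
})

test_that("the manifest conserves curated and planted counts", {
  cfg <- generator_config(n_articles = 20, lambda_nht = 5,
                          ht_fraction = 0, unplanted_fraction = 0.3,
                          distractor_rate = 0.5, seed = 8)
  corpus <- generate_corpus(cfg)
  man <- corpus$manifest
  expect_equal(sum(man$curated), nrow(corpus$curated))
  expect_equal(sum(man$curated & man$planted),
               nrow(corpus$curated) - sum(man$curated & !man$planted))
  # distractors are flagged uncurated and never collide with records
  expect_false(any(man$dna_hgvs[!man$curated] %in%
                     man$dna_hgvs[man$curated]))
})

test_that("expected_recall matches hand-computable cases", {
  man <- tibble::tibble(
    doc_id = rep("d1", 5),
    gene = "KRAS", hgnc_id = "HGNC:6407",
    dna_hgvs = paste0("c.", 1:5, "A>G"),
    protein_hgvs = NA_character_, pos = 1:5, wt = "A", mut = "G",
    source_kind = "supplement", format = "canonical_hgvs",
    curated = TRUE, planted = TRUE, h_prefixed = FALSE)
  e <- expected_recall(man)
  expect_equal(e$recall[e$source_set == "supplement"], 1.0)
  expect_equal(e$recall[e$source_set == "abstract"], 0.0)
  expect_equal(e$recall[e$source_set == "all"], 1.0)

  man2 <- man
  man2$format[1] <- "exon_intron"
  e2 <- expected_recall(man2)
  expect_equal(e2$recall[e2$source_set == "all"], 0.8)
})

test_that("distractors lower diagnostic precision but never recall", {
  noisy <- generator_config(n_articles = 25, lambda_nht = 4,
                            ht_fraction = 0, distractor_rate = 2,
                            format_mix = c(canonical_hgvs = 1),
                            seed = 12)
  corpus <- generate_corpus(noisy)
  expect_gt(sum(!corpus$manifest$curated), 0L)
  r1 <- evaluate_corpus(corpus$bundles, corpus$curated)
  # measured recall still equals the analytic expectation exactly, so
  # the planted distractors contributed nothing to the numerator
  exp <- expected_recall(corpus$manifest)
  expect_equal(as.data.frame(r1$per_source),
               as.data.frame(exp)[, names(r1$per_source)])
  # but they do appear among the extracted triples (precision < 1)
  all_row <- r1$per_source[r1$per_source$source_set == "all", ]
  expect_gt(nrow(r1$triples), all_row$matched)
})
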
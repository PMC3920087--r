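# Synthetic corpus and curated-database generator.
#
# The generator emulates the conditions under which curated-variant
# recovery is studied: per-article mutation counts follow a two-group
# mixture (conventional articles with a small Poisson count;
# high-throughput articles with a heavy-tailed log-normal count, so a
# small fraction of articles carries most mutations), each mutation is
# placed in one article source (abstract, body, table, supplementary
# file, PDF text) with supplementary material dominating, and mentions
# are rendered in a mix of canonical HGVS, legacy, natural-language,
# codon-positioned, exon-level and field-split formats. A ground-truth
# manifest records every planted mention, making every downstream
# metric analytically checkable via expected_recall().

NUCS <- c("A", "C", "G", "T")
FOOTNOTE_MARKS <- c("ᵃ", "ᵇ", "ᶜ", "ᵈ", "ᵉ")
FORMATS <- c("canonical_hgvs", "legacy_nodot", "natural_language",
             "codon_position", "exon_intron", "split_fields", "del_count")

#' Configure the synthetic corpus generator
#'
#' @param n_articles Number of articles.
#' @param n_genes Size of the gene pool drawn from the dictionary.
#' @param ht_fraction Fraction of articles that are high-throughput
#'   studies.
#' @param lambda_nht Poisson mean of curated mutations per conventional
#'   article.
#' @param ht_meanlog,ht_sdlog Log-normal parameters of the heavy-tailed
#'   per-article count for high-throughput articles.
#' @param placement Named probabilities over
#'   `abstract`/`body`/`table`/`supplement`/`pdf_text` for the source in
#'   which each mutation is rendered; must sum to 1.
#' @param format_mix Named probabilities over the rendering formats
#'   (`canonical_hgvs`, `legacy_nodot`, `natural_language`,
#'   `codon_position`, `exon_intron`, `split_fields`, `del_count`);
#'   must sum to 1.
#' @param ht_placement,ht_format_mix Optional overrides applied to
#'   high-throughput articles only.
#' @param footnote_rate Probability that a table cell is decorated with
#'   declared footnote marks.
#' @param h_prefix_rate Probability that a gene is rendered with a
#'   legacy `h` prefix (`hMLH1`).
#' @param distractor_rate Mean number of true-but-uncurated mentions
#'   planted per article.
#' @param unplanted_fraction Fraction of curated records never rendered
#'   anywhere (curation from sources the miner cannot see).
#' @param cds_codons Length of the synthetic coding sequence per gene,
#'   in codons.
#' @param seed Integer seed; all outputs are pure functions of the
#'   configuration including this seed.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_articles = 500, n_genes = 25,
                             ht_fraction = 0.2, lambda_nht = 7,
                             ht_meanlog = 4.6, ht_sdlog = 1.1,
                             placement = c(abstract = 0.15, body = 0.25,
                                           table = 0.10, supplement = 0.50,
                                           pdf_text = 0),
                             format_mix = c(canonical_hgvs = 0.55,
                                            legacy_nodot = 0.10,
                                            natural_language = 0.05,
                                            codon_position = 0.05,
                                            exon_intron = 0.05,
                                            split_fields = 0.15,
                                            del_count = 0.05),
                             ht_placement = NULL, ht_format_mix = NULL,
                             footnote_rate = 0.2, h_prefix_rate = 0,
                             distractor_rate = 0.3,
                             unplanted_fraction = 0, cds_codons = 2000,
                             seed = 17) {
  check_dist <- function(x, allowed, what) {
    if (is.null(x)) return(NULL)
    if (!all(names(x) %in% allowed) || is.null(names(x))) {
      stop(what, " must be named with: ", paste(allowed, collapse = ", "),
           call. = FALSE)
    }
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      stop(what, " must be a non-negative distribution summing to 1",
           call. = FALSE)
    }
    full <- stats::setNames(rep(0, length(allowed)), allowed)
    full[names(x)] <- x
    full
  }
  placement <- check_dist(placement, SOURCE_KINDS, "placement")
  format_mix <- check_dist(format_mix, FORMATS, "format_mix")
  ht_placement <- check_dist(ht_placement, SOURCE_KINDS, "ht_placement")
  ht_format_mix <- check_dist(ht_format_mix, FORMATS, "ht_format_mix")
  stopifnot(n_articles >= 0, n_genes >= 1, ht_fraction >= 0,
            ht_fraction <= 1, lambda_nht >= 0, footnote_rate >= 0,
            footnote_rate <= 1, h_prefix_rate >= 0, h_prefix_rate <= 1,
            distractor_rate >= 0, unplanted_fraction >= 0,
            unplanted_fraction <= 1, cds_codons >= 10)
  structure(list(n_articles = as.integer(n_articles),
                 n_genes = as.integer(n_genes), ht_fraction = ht_fraction,
                 lambda_nht = lambda_nht, ht_meanlog = ht_meanlog,
                 ht_sdlog = ht_sdlog, placement = placement,
                 format_mix = format_mix, ht_placement = ht_placement,
                 ht_format_mix = ht_format_mix,
                 footnote_rate = footnote_rate,
                 h_prefix_rate = h_prefix_rate,
                 distractor_rate = distractor_rate,
                 unplanted_fraction = unplanted_fraction,
                 cds_codons = as.integer(cds_codons),
                 seed = as.integer(seed)),
            class = "generator_config")
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

empty_manifest <- function() {
  tibble::tibble(doc_id = character(), gene = character(),
                 hgnc_id = character(), dna_hgvs = character(),
                 protein_hgvs = character(), pos = integer(),
                 wt = character(), mut = character(),
                 source_kind = character(), format = character(),
                 curated = logical(), planted = logical(),
                 h_prefixed = logical())
}

# Draw the manifest rows for one article.
article_rows <- function(doc_id, m, ht, genes, cds, cfg) {
  n_pos <- 3L * cfg$cds_codons
  fm <- if (ht && !is.null(cfg$ht_format_mix)) cfg$ht_format_mix else
    cfg$format_mix
  pm <- if (ht && !is.null(cfg$ht_placement)) cfg$ht_placement else
    cfg$placement
  m <- min(m, n_pos)
  rows <- NULL
  if (m > 0L) {
    # positions are drawn without replacement within an article, so
    # curated variant strings never collide across records of one
    # article and per-record recovery is analytically exact
    pos <- sample.int(n_pos, m)
    g <- sample.int(cfg$n_genes, m, replace = TRUE)
    format <- sample(names(fm), m, replace = TRUE, prob = fm)
    source <- sample(names(pm), m, replace = TRUE, prob = pm)
    source[format == "split_fields"] <- "supplement"
    wt <- substr(cds[g], pos, pos)
    is_del <- format == "del_count"
    mut <- rep(NA_character_, m)
    dna <- character(m)
    prot <- rep(NA_character_, m)
    for (j in seq_len(m)) {
      if (is_del[j]) {
        len <- if (pos[j] < n_pos) sample(1:2, 1L) else 1L
        bases <- substr(cds[g[j]], pos[j], pos[j] + len - 1L)
        range <- if (len == 1L) pos[j] else
          paste0(pos[j], "_", pos[j] + 1L)
        dna[j] <- paste0("c.", range, "del", bases)
      } else {
        mut[j] <- sample(setdiff(NUCS, wt[j]), 1L)
        dna[j] <- paste0("c.", pos[j], wt[j], ">", mut[j])
        ci <- (pos[j] - 1L) %/% 3L + 1L
        cstart <- 3L * (ci - 1L) + 1L
        codon_wt <- substr(cds[g[j]], cstart, cstart + 2L)
        off <- pos[j] - cstart + 1L
        codon_mut <- codon_wt
        substr(codon_mut, off, off) <- mut[j]
        prot[j] <- paste0(translate_codon(codon_wt), ci,
                          translate_codon(codon_mut))
      }
    }
    rows <- tibble::tibble(
      doc_id = doc_id, gene = genes$symbol[g], hgnc_id = genes$hgnc_id[g],
      dna_hgvs = dna, protein_hgvs = prot, pos = pos, wt = wt, mut = mut,
      source_kind = source, format = format, curated = TRUE,
      planted = stats::runif(m) >= cfg$unplanted_fraction,
      h_prefixed = stats::runif(m) < cfg$h_prefix_rate)
  }
  k <- stats::rpois(1L, cfg$distractor_rate)
  if (k > 0L) {
    g <- sample.int(cfg$n_genes, k, replace = TRUE)
    # beyond the curated position space: distractors never collide
    # with curated variants
    pos <- sample.int(n_pos, k, replace = TRUE) + n_pos
    wt <- sample(NUCS, k, replace = TRUE)
    mut <- vapply(wt, function(w) sample(setdiff(NUCS, w), 1L), "")
    dis <- tibble::tibble(
      doc_id = doc_id, gene = genes$symbol[g], hgnc_id = genes$hgnc_id[g],
      dna_hgvs = paste0("c.", pos, wt, ">", mut),
      protein_hgvs = NA_character_, pos = pos, wt = wt, mut = unname(mut),
      source_kind = sample(names(pm), k, replace = TRUE, prob = pm),
      format = "canonical_hgvs", curated = FALSE, planted = TRUE,
      h_prefixed = stats::runif(k) < cfg$h_prefix_rate)
    rows <- dplyr::bind_rows(rows, dis)
  }
  rows
}

# The surface string a manifest row is rendered as (NA for field-split
# rows, which have no single mention string).
mention_surface <- function(row) {
  pos <- row$pos
  switch(row$format,
         canonical_hgvs = row$dna_hgvs,
         legacy_nodot = paste0("c", pos, row$wt, " > ", row$mut),
         natural_language = paste0(row$wt, " > ", row$mut,
                                   " mutation at nucleotide ", pos),
         codon_position = paste0(row$wt, " > ", row$mut,
                                 " mutation at codon ",
                                 (pos - 1L) %/% 3L + 1L),
         exon_intron = paste0("Del exon ", (pos %% 9L) + 1L),
         del_count = {
           d <- parse_del(row$dna_hgvs)
           paste0("c.", d$range, "del", d$len)
         },
         split_fields = NA_character_)
}

# Render the in-memory bundle for one article from its planted rows.
render_bundle <- function(doc_id, rows, cfg) {
  secs <- list()
  rows <- rows[rows$planted, , drop = FALSE]
  gene_surface <- function(r) ifelse(r$h_prefixed, paste0("h", r$gene),
                                     r$gene)
  surfaces <- if (nrow(rows)) {
    vapply(seq_len(nrow(rows)),
           function(i) mention_surface(rows[i, , drop = FALSE]), "")
  } else character()

  ab <- which(rows$source_kind == "abstract")
  ab_text <- if (length(ab)) {
    paste0("The ", gene_surface(rows[ab, ]), " variant ", surfaces[ab],
           " was detected in tumour samples.", collapse = " ")
  } else {
    "No specific variants were reported in this study."
  }
  secs[[length(secs) + 1L]] <- document_section("abstract", ab_text)

  bd <- which(rows$source_kind == "body")
  if (length(bd)) {
    body_text <- paste0("We observed ", surfaces[bd], " in ",
                        gene_surface(rows[bd, ]), ".", collapse = " ")
    secs[[length(secs) + 1L]] <- document_section("body", body_text)
  }

  tb <- which(rows$source_kind == "table")
  grid <- NULL
  if (length(tb)) {
    cells <- character(2L * length(tb))
    marks_used <- character()
    for (i in seq_along(tb)) {
      mcell <- surfaces[tb[i]]
      if (stats::runif(1) < cfg$footnote_rate && nchar(mcell) >= 3L) {
        mk <- sample(FOOTNOTE_MARKS, 2L)
        cut <- nchar(mcell) - 2L
        mcell <- paste0(substr(mcell, 1L, cut), mk[1],
                        substring(mcell, cut + 1L), mk[2])
        marks_used <- union(marks_used, mk)
      }
      cells[2L * i - 1L] <- gene_surface(rows[tb[i], ])
      cells[2L * i] <- mcell
    }
    grid <- table_grid("Table 1. Identified variants.",
                       matrix(cells, ncol = 2L, byrow = TRUE),
                       footnote_marks = marks_used, origin = "T1")
    secs[[length(secs) + 1L]] <- linearize_table(grid)
  }

  pf <- which(rows$source_kind == "pdf_text")
  if (length(pf)) {
    secs[[length(secs) + 1L]] <-
      pdf_text_section(paste0(gene_surface(rows[pf, ]), " ", surfaces[pf],
                              collapse = "\n"))
  }

  sp <- which(rows$source_kind == "supplement")
  if (length(sp)) {
    lines <- vapply(sp, function(i) {
      r <- rows[i, , drop = FALSE]
      if (r$format == "split_fields") {
        paste(gene_surface(r), "", r$pos, r$wt, r$mut, sep = "\t")
      } else {
        paste(gene_surface(r), surfaces[i], "", "", "", sep = "\t")
      }
    }, "")
    txt <- paste(c("gene\tvariant\tposition\twt\tmut", lines),
                 collapse = "\n")
    secs[[length(secs) + 1L]] <- document_section("supplement", txt,
                                                  origin = "S1")
  }
  list(bundle = document_bundle(doc_id, dplyr::bind_rows(secs)),
       grid = grid)
}

#' Generate a synthetic corpus with its curated database
#'
#' Deterministic given the configuration (including its seed): draws the
#' gene pool and a synthetic coding sequence per gene, the per-article
#' mutation counts from the HT/NHT mixture, per-mutation placement and
#' rendering format, then renders every article bundle and assigns each
#' article a MeSH heading consistent with its HT status.
#'
#' @param cfg A [generator_config()].
#' @param dict A [gene_dictionary()] supplying the gene pool.
#' @param mesh A descriptor tibble (see [default_mesh_descriptors()]).
#' @return A `variant_corpus` list: `cfg`, `genes` (with coding
#'   sequences), `curated` records, the truth `manifest`, rendered
#'   `bundles`, per-article `mesh` headings and ground-truth `labels`.
#' @export
generate_corpus <- function(cfg = generator_config(),
                            dict = default_gene_dictionary(),
                            mesh = default_mesh_descriptors()) {
  withr::with_seed(cfg$seed, {
    pool <- dict$entries[dict$entries$surface == dict$entries$symbol, ,
                         drop = FALSE]
    if (cfg$n_genes > nrow(pool)) {
      stop("gene pool larger than the dictionary provides", call. = FALSE)
    }
    genes <- pool[sample.int(nrow(pool), cfg$n_genes), , drop = FALSE]
    cds <- vapply(seq_len(cfg$n_genes), function(i) {
      paste(sample(NUCS, 3L * cfg$cds_codons, replace = TRUE),
            collapse = "")
    }, "")
    genes <- tibble::tibble(symbol = genes$symbol,
                            hgnc_id = genes$hgnc_id, cds = cds)

    n <- cfg$n_articles
    docs <- sprintf("D%04d", seq_len(n))
    ht <- stats::runif(n) < cfg$ht_fraction
    counts <- integer(n)
    if (any(!ht)) counts[!ht] <- stats::rpois(sum(!ht), cfg$lambda_nht)
    if (any(ht)) {
      counts[ht] <- pmax(1L, pmin(5000L, round(
        stats::rlnorm(sum(ht), cfg$ht_meanlog, cfg$ht_sdlog))))
    }

    manifest <- list()
    bundles <- vector("list", n)
    grids <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- article_rows(docs[i], counts[i], ht[i], genes, genes$cds,
                           cfg)
      rendered <- render_bundle(docs[i],
                                if (is.null(rows)) empty_manifest() else
                                  rows, cfg)
      bundles[[i]] <- rendered$bundle
      grids[i] <- list(rendered$grid)
      if (!is.null(rows)) manifest[[length(manifest) + 1L]] <- rows
    }
    names(bundles) <- docs
    names(grids) <- docs
    manifest <- if (length(manifest)) dplyr::bind_rows(manifest) else
      empty_manifest()

    seeds <- ht_seed_set()
    in_closure <- vapply(seq_len(nrow(mesh)), function(i) {
      any(vapply(seeds$descriptors$tree_code,
                 function(s) is_descendant(mesh$tree_code[i], s),
                 logical(1)))
    }, logical(1))
    ht_headings <- unique(mesh$heading[in_closure])
    nht_headings <- setdiff(unique(mesh$heading), ht_headings)
    heading <- ifelse(ht,
                      sample(ht_headings, n, replace = TRUE),
                      sample(nht_headings, n, replace = TRUE))

    curated <- manifest[manifest$curated, , drop = FALSE]
    curated <- tibble::tibble(doc_id = curated$doc_id,
                              gene_symbol = curated$gene,
                              hgnc_id = curated$hgnc_id,
                              dna_hgvs = curated$dna_hgvs,
                              protein_hgvs = curated$protein_hgvs)
    structure(list(cfg = cfg, genes = genes, curated = curated,
                   manifest = manifest, bundles = bundles, grids = grids,
                   mesh = tibble::tibble(doc_id = docs, heading = heading),
                   labels = tibble::tibble(doc_id = docs,
                                           label = ifelse(ht, "HT", "NHT"))),
              class = "variant_corpus")
  })
}

#' @export
print.variant_corpus <- function(x, ...) {
  cat("<variant_corpus> ", length(x$bundles), " articles, ",
      nrow(x$curated), " curated records, ",
      sum(x$labels$label == "HT"), " HT articles\n", sep = "")
  invisible(x)
}

# Does a planted row's rendering yield an extracted triple at all under
# the enabled pattern classes? (Whether that triple then *matches* the
# record additionally depends on the match_config relaxations, which
# enter through the key generation below.)
recognizable_format <- function(format, dna_hgvs,
                                patterns = pattern_config()) {
  is_del <- grepl("del", dna_hgvs, fixed = TRUE)
  switch(format,
         canonical_hgvs = if (is_del) patterns$dna_indel else
           patterns$dna_sub,
         legacy_nodot = patterns$dna_sub && patterns$tolerant_dna,
         natural_language = patterns$nl_sub,
         codon_position = patterns$nl_sub,
         del_count = patterns$dna_indel,
         FALSE)
}

# Matching keys generated by a recognizable planted row, mirroring what
# the extractor's normalization would produce.
row_match_keys <- function(row, cfg) {
  if (row$format == "codon_position") {
    ci <- (row$pos - 1L) %/% 3L + 1L
    cands <- paste0("c.", expand_codon(ci), row$wt, ">", row$mut)
    variant_keys("dna", cands[1], alternates = cands,
                 provenance = "codon", cfg = cfg)
  } else if (row$format == "del_count") {
    d <- parse_del(row$dna_hgvs)
    variant_keys("dna", paste0("c.", d$range, "del", d$len), cfg = cfg)
  } else {
    variant_keys("dna", row$dna_hgvs, cfg = cfg)
  }
}

#' Analytic per-source recall expected from a truth manifest
#'
#' Computes, without any rendering, scanning or simulation, the recall
#' report the extraction pipeline must produce on the corpus described
#' by a truth manifest: a curated record is recovered from a source set
#' when some planted mention of an equivalent variant, in a format
#' recognizable under the given configurations, occurs there in the
#' same article, and (unless the gene is ignored) the record's gene is
#' mentioned in that source set of the article.
#'
#' @param manifest A truth manifest (from [generate_corpus()]).
#' @param patterns A [pattern_config()].
#' @param cfg A [match_config()].
#' @param strip_h_prefix Whether the extractor resolves `h`-prefixed
#'   gene renderings.
#' @return A tibble shaped like [per_source_evaluation()] output.
#' @export
expected_recall <- function(manifest, patterns = pattern_config(),
                            cfg = match_config(), strip_h_prefix = FALSE) {
  rec <- manifest[manifest$curated, , drop = FALSE]
  key <- paste(rec$doc_id, toupper(rec$gene), rec$dna_hgvs,
               rec$protein_hgvs, sep = "\r")
  rec <- rec[!duplicated(key), , drop = FALSE]
  if (!nrow(rec)) {
    stop("manifest holds no curated records", call. = FALSE)
  }
  planted <- manifest[manifest$planted, , drop = FALSE]
  recog <- vapply(seq_len(nrow(planted)), function(i) {
    recognizable_format(planted$format[i], planted$dna_hgvs[i], patterns)
  }, logical(1))

  rec_keys <- lapply(seq_len(nrow(rec)), function(i) {
    k <- variant_keys("dna", rec$dna_hgvs[i], cfg = cfg)
    if (!is.na(rec$protein_hgvs[i])) {
      k <- c(k, variant_keys("protein", rec$protein_hgvs[i], cfg = cfg))
    }
    k
  })

  # per single source: does each record's variant occur (recognizably)
  # and is its gene mentioned? triples never associate across sources,
  # so a source *set* matches when some member source does.
  n <- nrow(rec)
  var_hit <- matrix(FALSE, n, length(SOURCE_KINDS),
                    dimnames = list(NULL, SOURCE_KINDS))
  gene_hit <- var_hit
  triple_docs <- stats::setNames(vector("list", length(SOURCE_KINDS)),
                                 SOURCE_KINDS)
  for (kind in SOURCE_KINDS) {
    in_s <- planted$source_kind == kind
    sub <- planted[in_s & recog, , drop = FALSE]
    keyset <- if (nrow(sub)) {
      ks <- lapply(seq_len(nrow(sub)), function(i) {
        row_match_keys(sub[i, , drop = FALSE], cfg)
      })
      split(unlist(ks), rep(sub$doc_id, lengths(ks)))
    } else list()
    gene_rows <- planted[in_s & (!planted$h_prefixed | strip_h_prefix), ,
                         drop = FALSE]
    gene_set <- split(toupper(gene_rows$gene), gene_rows$doc_id)
    var_hit[, kind] <- vapply(seq_len(n), function(i) {
      any(rec_keys[[i]] %in% keyset[[rec$doc_id[i]]])
    }, logical(1))
    gene_hit[, kind] <- vapply(seq_len(n), function(i) {
      toupper(rec$gene[i]) %in% gene_set[[rec$doc_id[i]]]
    }, logical(1))
    triple_docs[[kind]] <- unique(sub$doc_id)
  }
  matched_one <- var_hit & (cfg$ignore_gene | gene_hit)

  rows <- lapply(names(SOURCE_SETS), function(nm) {
    kinds <- SOURCE_SETS[[nm]]
    m <- apply(matched_one[, kinds, drop = FALSE], 1L, any)
    m_ng <- apply(var_hit[, kinds, drop = FALSE], 1L, any)
    docs_with_triple <- unique(unlist(triple_docs[kinds]))
    common <- intersect(unique(rec$doc_id), docs_with_triple)
    in_common <- rec$doc_id %in% common
    n_common <- sum(in_common)
    tibble::tibble(
      source_set = nm, n_curated = n, n_common_art = length(common),
      n_common_curated = n_common, matched = sum(m),
      matched_ng = sum(m_ng), matched_common = sum(m & in_common),
      matched_common_ng = sum(m_ng & in_common),
      recall = sum(m) / n, recall_ng = sum(m_ng) / n,
      recall_common = if (n_common) sum(m & in_common) / n_common else
        NA_real_,
      recall_common_ng = if (n_common) sum(m_ng & in_common) / n_common
        else NA_real_)
  })
  dplyr::bind_rows(rows)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a synthetic corpus to disk
#'
#' Serializes every bundle into the formats the ingest module consumes —
#' abstract XML, simplified JATS-style full-text XML with embedded
#' tables, TSV supplements, plain-text PDF extractions — plus the JSON
#' bundle manifest, the curated database TSV, the truth-manifest TSV and
#' the per-article MeSH heading TSV. Output is byte-identical for a
#' fixed configuration.
#'
#' @param corpus A `variant_corpus` from [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "variant_corpus"))
  for (sub in c("", "abstracts", "fulltext", "supplements", "pdf")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)
  }
  entries <- list()
  for (doc in names(corpus$bundles)) {
    b <- corpus$bundles[[doc]]
    secs <- b$sections
    sources <- list()
    ab <- secs$text[secs$source_kind == "abstract"]
    if (length(ab)) {
      path <- file.path("abstracts", paste0(doc, ".xml"))
      writeLines(paste0("<PubmedArticle><PMID>", doc, "</PMID><Abstract>",
                        xml_escape(ab[[1]]), "</Abstract></PubmedArticle>"),
                 file.path(dir, path), useBytes = TRUE)
      sources[[length(sources) + 1L]] <-
        list(source_kind = "abstract", path = path)
    }
    body <- secs$text[secs$source_kind == "body"]
    tab_rows <- which(secs$source_kind == "table")
    if (length(body) || length(tab_rows)) {
      body_xml <- if (length(body)) {
        sentences <- strsplit(body[[1]], "(?<=\\.) ", perl = TRUE)[[1]]
        paste0("<body>",
               paste0("<p>", xml_escape(sentences), "</p>",
                      collapse = ""),
               "</body>")
      } else "<body></body>"
      # the original mark-decorated grid is serialized so that ingest
      # performs the footnote stripping on re-read
      tab_xml <- ""
      grid <- corpus$grids[[doc]]
      if (!is.null(grid)) {
        tds <- vapply(seq_len(nrow(grid$cells)), function(i) {
          paste0("<tr>",
                 paste0("<td>", xml_escape(grid$cells[i, ]), "</td>",
                        collapse = ""),
                 "</tr>")
        }, "")
        mark_attr <- paste(grid$footnote_marks, collapse = "")
        tab_xml <- paste0("<table-wrap id=\"T1\"",
                          if (nzchar(mark_attr)) {
                            paste0(" footnote-marks=\"", mark_attr, "\"")
                          } else "",
                          "><caption>", xml_escape(grid$caption),
                          "</caption><table>",
                          paste(tds, collapse = ""),
                          "</table></table-wrap>")
      }
      path <- file.path("fulltext", paste0(doc, ".xml"))
      writeLines(paste0("<article>", body_xml, tab_xml, "</article>"),
                 file.path(dir, path), useBytes = TRUE)
      sources[[length(sources) + 1L]] <-
        list(source_kind = "body", path = path)
    }
    pdf <- secs$text[secs$source_kind == "pdf_text"]
    if (length(pdf)) {
      path <- file.path("pdf", paste0(doc, ".txt"))
      writeLines(pdf[[1]], file.path(dir, path), useBytes = TRUE)
      sources[[length(sources) + 1L]] <-
        list(source_kind = "pdf_text", path = path)
    }
    supp <- secs$text[secs$source_kind == "supplement"]
    if (length(supp)) {
      path <- file.path("supplements", paste0(doc, "_S1.tsv"))
      writeLines(supp[[1]], file.path(dir, path), useBytes = TRUE)
      sources[[length(sources) + 1L]] <-
        list(source_kind = "supplement", path = path)
    }
    entries[[length(entries) + 1L]] <- list(doc_id = doc,
                                            sources = sources)
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  utils::write.table(corpus$curated, file.path(dir, "curated_db.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  utils::write.table(corpus$manifest, file.path(dir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  utils::write.table(corpus$mesh, file.path(dir, "mesh_headings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(manifest_path)
}
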
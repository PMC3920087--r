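# End-to-end orchestration: scan bundles for mentions and genes,
# normalize mentions, associate them by document-scope co-occurrence,
# and evaluate the resulting triples against a curated database.

empty_triples <- function() {
  tibble::tibble(doc_id = character(), source_kind = character(),
                 gene_symbol = character(), gene_hgnc_id = character(),
                 level = character(), hgvs = character(),
                 alternates = list(), provenance = character())
}

#' Extract normalized triples from one article bundle
#'
#' Each source kind of the bundle is processed independently: mentions
#' and genes are scanned in every section of that kind, mentions are
#' normalized (imprecise ones dropped, rs-numbers expanded through the
#' lookup), and every surviving variant is paired with every distinct
#' gene symbol found in the same source (document-scope association);
#' variants with no co-occurring gene keep an absent (`NA`) gene.
#'
#' @param bundle A [document_bundle()].
#' @param patterns A [pattern_config()].
#' @param dict A [gene_dictionary()].
#' @param lookup Optional [rsid_lookup()].
#' @param strip_h_prefix Passed to [scan_genes()].
#' @return A tibble of triples: `doc_id`, `source_kind`, `gene_symbol`,
#'   `gene_hgnc_id`, `level`, `hgvs`, `alternates` (list column),
#'   `provenance`.
#' @export
extract_triples <- function(bundle, patterns = pattern_config(),
                            dict = default_gene_dictionary(),
                            lookup = NULL, strip_h_prefix = FALSE) {
  stopifnot(inherits(bundle, "document_bundle"))
  secs <- bundle$sections
  out <- list()
  for (kind in unique(secs$source_kind)) {
    rows <- which(secs$source_kind == kind)
    mention_list <- list()
    gene_list <- list()
    for (i in rows) {
      sec <- secs[i, , drop = FALSE]
      mention_list[[length(mention_list) + 1L]] <-
        scan_mentions(sec, patterns)
      gene_list[[length(gene_list) + 1L]] <-
        scan_genes(sec, dict, strip_h_prefix = strip_h_prefix)
    }
    mentions <- dplyr::bind_rows(mention_list)
    genes <- dplyr::bind_rows(gene_list)
    if (!nrow(mentions)) next
    syms <- unique(genes$symbol)
    hgnc <- genes$hgnc_id[match(syms, genes$symbol)]
    var_tbl <- normalize_mentions_bulk(mentions, lookup)
    if (!nrow(var_tbl)) next
    gene_tbl <- if (length(syms)) {
      tibble::tibble(gene_symbol = syms, gene_hgnc_id = hgnc)
    } else {
      tibble::tibble(gene_symbol = NA_character_,
                     gene_hgnc_id = NA_character_)
    }
    grid <- var_tbl[rep(seq_len(nrow(var_tbl)), each = nrow(gene_tbl)), ,
                    drop = FALSE]
    grid$gene_symbol <- rep(gene_tbl$gene_symbol, times = nrow(var_tbl))
    grid$gene_hgnc_id <- rep(gene_tbl$gene_hgnc_id, times = nrow(var_tbl))
    grid$doc_id <- bundle$doc_id
    grid$source_kind <- kind
    # triples differing only in their alternate sets are kept apart, so
    # a codon-derived triple never loses its candidates to a plain
    # duplicate of its canonical string
    alt_key <- vapply(grid$alternates,
                      function(a) paste(sort(a), collapse = ","), "")
    key <- paste(grid$gene_symbol, grid$level, grid$hgvs, alt_key,
                 sep = "\r")
    grid <- grid[!duplicated(key), , drop = FALSE]
    out[[length(out) + 1L]] <- grid[, names(empty_triples())]
  }
  if (!length(out)) return(empty_triples())
  dplyr::bind_rows(out)
}

#' Extract triples from every bundle of a corpus
#'
#' @param bundles List of [document_bundle()] objects.
#' @inheritParams extract_triples
#' @return One triples tibble (see [extract_triples()]).
#' @export
extract_corpus_triples <- function(bundles, patterns = pattern_config(),
                                   dict = default_gene_dictionary(),
                                   lookup = NULL, strip_h_prefix = FALSE) {
  out <- lapply(bundles, extract_triples, patterns = patterns, dict = dict,
                lookup = lookup, strip_h_prefix = strip_h_prefix)
  if (!length(out)) return(empty_triples())
  dplyr::bind_rows(out)
}

#' Evaluate a corpus against a curated database
#'
#' Runs extraction over all bundles and produces the per-source recall
#' table, overall recall, the abstract-versus-full-text precision
#' (when both sources yielded triples), and, when `thresholds` is
#' given, recall grouped by per-article curated-mutation count.
#'
#' @param bundles List of [document_bundle()] objects.
#' @param curated Curated records tibble.
#' @param patterns A [pattern_config()].
#' @param dict A [gene_dictionary()].
#' @param cfg A [match_config()].
#' @param lookup Optional [rsid_lookup()].
#' @param thresholds Optional ascending integer thresholds.
#' @param strip_h_prefix Passed to [scan_genes()].
#' @return A list with `triples`, `per_source`, `overall`,
#'   `abs_vs_ft_precision` and (optionally) `thresholds`.
#' @export
evaluate_corpus <- function(bundles, curated, patterns = pattern_config(),
                            dict = default_gene_dictionary(),
                            cfg = match_config(), lookup = NULL,
                            thresholds = NULL, strip_h_prefix = FALSE) {
  corpus_docs <- vapply(bundles, function(b) b$doc_id, character(1))
  triples <- extract_corpus_triples(bundles, patterns, dict, lookup,
                                    strip_h_prefix)
  per_source <- per_source_evaluation(triples, curated, corpus_docs, cfg)
  overall <- compute_recall(curated, triples, corpus_docs, cfg)
  abs_tri <- triples[triples$source_kind == "abstract", , drop = FALSE]
  ft_tri <- triples[triples$source_kind %in% c("body", "table"), ,
                    drop = FALSE]
  prec <- if (nrow(abs_tri) && nrow(ft_tri)) {
    tryCatch(abstract_vs_fulltext_precision(abs_tri, ft_tri),
             error = function(e) NA_real_)
  } else NA_real_
  res <- list(triples = triples, per_source = per_source,
              overall = overall, abs_vs_ft_precision = prec)
  if (!is.null(thresholds)) {
    res$thresholds <- threshold_grouping(curated, thresholds, triples,
                                         corpus_docs, cfg)
  }
  res
}

#' Write evaluation reports to disk
#'
#' Emits tab-separated (UTF-8, header row) and JSON renderings of the
#' per-source table, and of the threshold table when present.
#'
#' @param results The list returned by [evaluate_corpus()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(tbl, stem) {
    tsv <- file.path(dir, paste0(stem, ".tsv"))
    utils::write.table(tbl, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    js <- file.path(dir, paste0(stem, ".json"))
    jsonlite::write_json(tbl, js, dataframe = "rows", na = "null",
                         digits = NA, pretty = TRUE)
    paths <<- c(paths, tsv, js)
  }
  emit(results$per_source, "per_source_recall")
  emit(results$overall, "overall_recall")
  if (!is.null(results$thresholds)) {
    drop <- names(results$thresholds) == "alternates"
    emit(results$thresholds[, !drop, drop = FALSE], "threshold_recall")
  }
  if (!is.null(results$ht_split)) emit(results$ht_split, "ht_split")
  invisible(paths)
}
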
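# Matching extracted (article, gene, variant) triples against a curated
# variant database, and the recall metrics reported per source, per
# article subset, and per mutation-frequency threshold.

#' Load a curated variant database from TSV
#'
#' Expected columns: `doc_id`, `gene_symbol`, `hgnc_id`, `dna_hgvs`,
#' `protein_hgvs`. Empty strings become `NA`; every row must carry at
#' least one of the two variant columns.
#'
#' @param path Path to the TSV file.
#' @return A tibble of curated records.
#' @export
load_curated_db <- function(path) {
  tbl <- tibble::as_tibble(utils::read.delim(path, colClasses = "character",
                                             na.strings = c("", "NA")))
  validate_curated(tbl)
}

validate_curated <- function(tbl) {
  need <- c("doc_id", "gene_symbol", "dna_hgvs", "protein_hgvs")
  stopifnot(all(need %in% names(tbl)))
  if (!"hgnc_id" %in% names(tbl)) tbl$hgnc_id <- NA_character_
  if (any(is.na(tbl$doc_id) | !nzchar(tbl$doc_id))) {
    stop("curated records must carry a non-empty doc_id", call. = FALSE)
  }
  if (any(is.na(tbl$dna_hgvs) & is.na(tbl$protein_hgvs))) {
    stop("curated records must carry a DNA or a protein variant",
         call. = FALSE)
  }
  tbl
}

# Distinct curated facts: repeated rows of the same (article, gene,
# variants) count once in all denominators.
dedupe_curated <- function(curated) {
  curated <- validate_curated(tibble::as_tibble(curated))
  curated$gene_symbol <- toupper(curated$gene_symbol)
  key <- paste(curated$doc_id, curated$gene_symbol, curated$dna_hgvs,
               curated$protein_hgvs, sep = "\r")
  curated[!duplicated(key), , drop = FALSE]
}

# Matching keys for one variant string under the active relaxations.
# Codon- and rs-derived alternates contribute keys only when their flag
# is on; deletions additionally key on position+length when the
# del-length relaxation is on.
variant_keys <- function(level, hgvs, alternates = character(),
                         provenance = NA_character_,
                         cfg = match_config()) {
  keys <- paste0(level, ":", hgvs)
  use_alt <- switch(ifelse(is.na(provenance), "other", provenance),
                    codon = cfg$codon_expansion,
                    rsid = cfg$rsid_expansion,
                    TRUE)
  if (use_alt && length(alternates)) {
    keys <- c(keys, paste0(level, ":", alternates))
  }
  if (cfg$del_length_equivalence && level == "dna") {
    for (h in c(hgvs, if (use_alt) alternates)) {
      d <- parse_del(h)
      if (!is.null(d) && !is.na(d$len)) {
        keys <- c(keys, paste0(level, ":c.", d$range, "del#", d$len))
      }
    }
  }
  unique(keys)
}

gene_ok <- function(rec_sym, rec_hgnc, tri_sym, tri_hgnc, ignore_gene) {
  if (ignore_gene) return(rep(TRUE, length(tri_sym)))
  has_hgnc <- !is.na(rec_hgnc) & nzchar(rec_hgnc) &
    !is.na(tri_hgnc) & nzchar(tri_hgnc)
  ifelse(has_hgnc, rec_hgnc == tri_hgnc,
         !is.na(tri_sym) & toupper(tri_sym) == toupper(rec_sym))
}

#' Does a curated record have a matching extracted triple?
#'
#' A record matches when some triple shares its article, passes the gene
#' test (HGNC-id equality when both sides carry one, otherwise
#' case-folded symbol equality; skipped under `ignore_gene`), and is
#' [variant_equivalent()] to the record's DNA variant or to its protein
#' variant.
#'
#' @param record A one-row curated record.
#' @param extracted A triples tibble (see [extract_triples()]).
#' @param cfg A [match_config()].
#' @return Logical.
#' @export
record_matches <- function(record, extracted, cfg = match_config()) {
  tri <- extracted[extracted$doc_id == record$doc_id[[1]], , drop = FALSE]
  if (!nrow(tri)) return(FALSE)
  ok <- gene_ok(record$gene_symbol[[1]], record$hgnc_id[[1]],
                tri$gene_symbol, tri$gene_hgnc_id, cfg$ignore_gene)
  tri <- tri[ok, , drop = FALSE]
  if (!nrow(tri)) return(FALSE)
  targets <- list()
  if (!is.na(record$dna_hgvs[[1]])) {
    targets <- c(targets, list(normalized_variant("dna",
                                                  record$dna_hgvs[[1]])))
  }
  if (!is.na(record$protein_hgvs[[1]])) {
    targets <- c(targets, list(normalized_variant("protein",
                                                  record$protein_hgvs[[1]])))
  }
  for (i in seq_len(nrow(tri))) {
    v <- normalized_variant(tri$level[[i]], tri$hgvs[[i]],
                            alternates = tri$alternates[[i]],
                            provenance = tri$provenance[[i]])
    for (t in targets) {
      if (variant_equivalent(v, t, cfg)) return(TRUE)
    }
  }
  FALSE
}

# Vectorized key generation for many variants at once: the common case
# (no alternates, no deletion re-keying) is a single paste; only
# alternate-carrying or deletion variants take the per-item path.
build_keys <- function(level, hgvs, alternates, provenance, cfg) {
  n <- length(hgvs)
  if (!n) return(list())
  level <- rep_len(level, n)
  provenance <- rep_len(provenance, n)
  keys <- as.list(paste0(level, ":", hgvs))
  has_alt <- lengths(alternates) > 0L
  if (any(has_alt)) {
    use <- ifelse(is.na(provenance), TRUE,
                  ifelse(provenance == "codon", cfg$codon_expansion,
                         ifelse(provenance == "rsid", cfg$rsid_expansion,
                                TRUE)))
    has_alt <- has_alt & use
  }
  needs <- has_alt |
    (cfg$del_length_equivalence & level == "dna" &
       grepl("del", hgvs, fixed = TRUE))
  for (i in which(needs)) {
    keys[[i]] <- variant_keys(level[i], hgvs[i], alternates[[i]],
                              provenance[i], cfg)
  }
  keys
}

# Which deduplicated curated records have a matching triple? One join
# on (doc, variant key) serves both the gene-strict and the
# gene-relaxed ("NG") computation.
matched_both <- function(curated, extracted, cfg) {
  n <- nrow(curated)
  none <- list(m = logical(n), m_ng = logical(n))
  if (!n || !nrow(extracted)) return(none)
  tri_keys <- build_keys(extracted$level, extracted$hgvs,
                         extracted$alternates, extracted$provenance, cfg)
  tri <- tibble::tibble(
    doc_id = rep(extracted$doc_id, lengths(tri_keys)),
    gene_symbol = rep(extracted$gene_symbol, lengths(tri_keys)),
    gene_hgnc_id = rep(extracted$gene_hgnc_id, lengths(tri_keys)),
    key = unlist(tri_keys))
  has_dna <- !is.na(curated$dna_hgvs)
  has_prot <- !is.na(curated$protein_hgvs)
  empty_alts <- rep(list(character()), sum(has_dna))
  dna_keys <- build_keys("dna", curated$dna_hgvs[has_dna], empty_alts,
                         NA_character_, cfg)
  prot_keys <- if (any(has_prot)) {
    as.list(paste0("protein:", curated$protein_hgvs[has_prot]))
  } else list()
  rec_id <- c(rep(which(has_dna), lengths(dna_keys)), which(has_prot))
  rec <- tibble::tibble(
    rec_id = rec_id,
    doc_id = curated$doc_id[rec_id],
    gene_symbol = curated$gene_symbol[rec_id],
    hgnc_id = curated$hgnc_id[rec_id],
    key = c(unlist(dna_keys), unlist(prot_keys)))
  hits <- dplyr::inner_join(rec, tri, by = c("doc_id", "key"),
                            relationship = "many-to-many")
  if (!nrow(hits)) return(none)
  ok <- gene_ok(hits$gene_symbol.x, hits$hgnc_id, hits$gene_symbol.y,
                hits$gene_hgnc_id, cfg$ignore_gene)
  m <- logical(n)
  m[unique(hits$rec_id[ok])] <- TRUE
  m_ng <- logical(n)
  m_ng[unique(hits$rec_id)] <- TRUE
  list(m = m, m_ng = m_ng)
}

#' Compute the four recall metrics
#'
#' `recall` is the fraction of (deduplicated) curated records with a
#' matching extracted triple; `recall_ng` drops the gene requirement;
#' `recall_common` restricts the denominator to records from the common
#' articles — articles the extractor processed that have at least one
#' curated record and at least one extracted triple; `recall_common_ng`
#' applies both.
#'
#' @param curated Curated records tibble.
#' @param extracted Extracted triples tibble.
#' @param corpus_docs Character vector of article ids the extractor
#'   actually processed.
#' @param cfg A [match_config()].
#' @return A one-row tibble with matched counts, denominators and the
#'   four recall proportions.
#' @export
compute_recall <- function(curated, extracted, corpus_docs,
                           cfg = match_config()) {
  curated <- dedupe_curated(curated)
  if (!nrow(curated)) {
    stop("recall is undefined for an empty curated set", call. = FALSE)
  }
  mm <- matched_both(curated, extracted, cfg)
  m <- mm$m
  m_ng <- mm$m_ng
  common <- intersect(intersect(unique(curated$doc_id), corpus_docs),
                      unique(extracted$doc_id))
  in_common <- curated$doc_id %in% common
  n <- nrow(curated)
  n_common <- sum(in_common)
  tibble::tibble(
    n_curated = n,
    n_common_art = length(common),
    n_common_curated = n_common,
    matched = sum(m),
    matched_ng = sum(m_ng),
    matched_common = sum(m & in_common),
    matched_common_ng = sum(m_ng & in_common),
    recall = sum(m) / n,
    recall_ng = sum(m_ng) / n,
    recall_common = if (n_common) sum(m & in_common) / n_common else NA_real_,
    recall_common_ng = if (n_common) sum(m_ng & in_common) / n_common
                       else NA_real_)
}

#' Descriptive statistics of a curated corpus
#'
#' @param curated Curated records tibble.
#' @param corpus_docs All article ids of the corpus (defaults to the
#'   articles appearing in `curated`).
#' @return A one-row tibble: `n_docs`, `n_docs_with_mut`, `n_mutations`,
#'   `mean_mut_per_doc`, `sd_mut_per_doc` (moments over the articles
#'   that have at least one mutation).
#' @export
corpus_stats <- function(curated, corpus_docs = NULL) {
  curated <- dedupe_curated(curated)
  counts <- table(curated$doc_id)
  docs <- if (is.null(corpus_docs)) names(counts) else
    union(corpus_docs, names(counts))
  tibble::tibble(
    n_docs = length(docs),
    n_docs_with_mut = length(counts),
    n_mutations = nrow(curated),
    mean_mut_per_doc = if (length(counts)) mean(counts) else 0,
    sd_mut_per_doc = if (length(counts) > 1L) stats::sd(counts) else 0)
}

SOURCE_SETS <- list(
  abstract = "abstract",
  body = "body",
  pdf_text = "pdf_text",
  table = "table",
  `body+table` = c("body", "table"),
  supplement = "supplement",
  all = c("abstract", "body", "pdf_text", "table", "supplement"))

#' Recall per mutation source and for their union
#'
#' Evaluates recall separately over the triples extracted from each
#' source of the articles — abstract, narrative body, pre-extracted PDF
#' text, tables, supplementary files — plus the body+table combination
#' and the union of all sources.
#'
#' @param triples Extracted triples carrying a `source_kind` column
#'   (from [extract_corpus_triples()]).
#' @param curated Curated records tibble.
#' @param corpus_docs Article ids the extractor processed.
#' @param cfg A [match_config()].
#' @return A tibble with one row per source set (`source_set` column)
#'   and the [compute_recall()] columns.
#' @export
per_source_evaluation <- function(triples, curated, corpus_docs,
                                  cfg = match_config()) {
  rows <- lapply(names(SOURCE_SETS), function(nm) {
    sub <- triples[triples$source_kind %in% SOURCE_SETS[[nm]], ,
                   drop = FALSE]
    rep <- compute_recall(curated, sub, corpus_docs, cfg)
    dplyr::bind_cols(tibble::tibble(source_set = nm), rep)
  })
  dplyr::bind_rows(rows)
}

triple_key <- function(triples) {
  paste(triples$doc_id,
        ifelse(is.na(triples$gene_symbol), "-",
               toupper(triples$gene_symbol)),
        triples$level, triples$hgvs, sep = "\r")
}

#' Precision of abstract-derived triples against full-text triples
#'
#' Over the articles present in both sets, the fraction of distinct
#' abstract triples also extracted from the full text. Used to ask
#' whether the abstract carries information the full text does not.
#'
#' @param abs_triples Triples extracted from abstracts.
#' @param ft_triples Triples extracted from full text.
#' @return A proportion in `[0, 1]`.
#' @export
abstract_vs_fulltext_precision <- function(abs_triples, ft_triples) {
  common <- intersect(unique(abs_triples$doc_id),
                      unique(ft_triples$doc_id))
  a <- unique(triple_key(abs_triples[abs_triples$doc_id %in% common, ,
                                     drop = FALSE]))
  f <- unique(triple_key(ft_triples[ft_triples$doc_id %in% common, ,
                                    drop = FALSE]))
  if (!length(a)) {
    stop("precision is undefined for an empty abstract triple set",
         call. = FALSE)
  }
  length(intersect(a, f)) / length(a)
}

#' Recall grouped by per-article curated-mutation count
#'
#' Articles are grouped by how many curated mutations they carry: one
#' group per threshold `t` (articles with count <= t) plus a final
#' group of articles above the largest threshold. Each group gets
#' descriptive statistics (including its share of all curated
#' mutations) and a recall report.
#'
#' @param curated Curated records tibble.
#' @param thresholds Strictly ascending positive integers.
#' @param extracted Extracted triples tibble.
#' @param corpus_docs Article ids the extractor processed.
#' @param cfg A [match_config()].
#' @return A tibble with one row per group: `group`, the [corpus_stats()]
#'   columns, `mutation_share`, and the [compute_recall()] columns.
#' @export
threshold_grouping <- function(curated, thresholds, extracted, corpus_docs,
                               cfg = match_config()) {
  thresholds <- as.integer(thresholds)
  if (length(thresholds) == 0L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending", call. = FALSE)
  }
  curated <- dedupe_curated(curated)
  counts <- table(curated$doc_id)
  total_mut <- nrow(curated)
  groups <- c(stats::setNames(
    lapply(thresholds, function(t) names(counts)[counts <= t]),
    paste0("<=", thresholds)),
    stats::setNames(list(names(counts)[counts > max(thresholds)]),
                    paste0(">", max(thresholds))))
  rows <- lapply(names(groups), function(nm) {
    docs <- groups[[nm]]
    sub <- curated[curated$doc_id %in% docs, , drop = FALSE]
    stats_row <- if (nrow(sub)) corpus_stats(sub, docs) else
      tibble::tibble(n_docs = length(docs), n_docs_with_mut = 0L,
                     n_mutations = 0L, mean_mut_per_doc = 0,
                     sd_mut_per_doc = 0)
    rec <- if (nrow(sub)) {
      compute_recall(sub, extracted, intersect(corpus_docs, docs), cfg)
    } else NULL
    out <- dplyr::bind_cols(
      tibble::tibble(group = nm), stats_row,
      tibble::tibble(mutation_share = stats_row$n_mutations / total_mut))
    if (!is.null(rec)) out <- dplyr::bind_cols(out, rec)
    out
  })
  dplyr::bind_rows(rows)
}
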
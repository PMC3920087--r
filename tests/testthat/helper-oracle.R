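# Independent oracles used by the acceptance and property tests. These
# deliberately avoid the package's join-based matcher and prefix-based
# classifier internals.

# Exhaustive double-loop recall: every (record, triple) pair is tested
# individually with variant_equivalent(); metrics assembled from first
# principles.
brute_force_recall <- function(curated, extracted, corpus_docs,
                               cfg = match_config()) {
  key <- paste(curated$doc_id, toupper(curated$gene_symbol),
               curated$dna_hgvs, curated$protein_hgvs)
  curated <- curated[!duplicated(key), , drop = FALSE]
  n <- nrow(curated)
  pair_gene_ok <- function(rs, rh, ts, th) {
    if (cfg$ignore_gene) return(TRUE)
    if (is.na(ts)) return(FALSE)
    if (!is.na(rh) && nzchar(rh) && !is.na(th) && nzchar(th)) {
      return(rh == th)
    }
    toupper(ts) == toupper(rs)
  }
  one <- function(i, need_gene) {
    tri <- extracted[extracted$doc_id == curated$doc_id[i], ,
                     drop = FALSE]
    if (!nrow(tri)) return(FALSE)
    targets <- list()
    if (!is.na(curated$dna_hgvs[i])) {
      targets <- c(targets,
                   list(normalized_variant("dna", curated$dna_hgvs[i])))
    }
    if (!is.na(curated$protein_hgvs[i])) {
      targets <- c(targets,
                   list(normalized_variant("protein",
                                           curated$protein_hgvs[i])))
    }
    for (j in seq_len(nrow(tri))) {
      if (need_gene &&
          !pair_gene_ok(curated$gene_symbol[i], curated$hgnc_id[i],
                        tri$gene_symbol[j], tri$gene_hgnc_id[j])) next
      v <- normalized_variant(tri$level[j], tri$hgvs[j],
                              alternates = tri$alternates[[j]],
                              provenance = tri$provenance[j])
      for (t in targets) {
        if (variant_equivalent(v, t, cfg)) return(TRUE)
      }
    }
    FALSE
  }
  m <- vapply(seq_len(n), one, logical(1), need_gene = TRUE)
  m_ng <- vapply(seq_len(n), one, logical(1), need_gene = FALSE)
  common <- intersect(intersect(unique(curated$doc_id), corpus_docs),
                      unique(extracted$doc_id))
  in_common <- curated$doc_id %in% common
  list(matched = sum(m), matched_ng = sum(m_ng),
       recall = sum(m) / n, recall_ng = sum(m_ng) / n,
       recall_common = if (sum(in_common)) {
         sum(m & in_common) / sum(in_common)
       } else NA_real_,
       recall_common_ng = if (sum(in_common)) {
         sum(m_ng & in_common) / sum(in_common)
       } else NA_real_)
}

# Materialized-closure MeSH oracle: instead of a prefix test, walk each
# code's parent chain (chopping one dotted component at a time) and
# check whether a seed is reached.
closure_label_oracle <- function(codes, seeds = ht_seed_set()) {
  if (!length(codes)) return("UNINDEXED")
  seed_codes <- seeds$descriptors$tree_code
  reaches_seed <- function(code) {
    while (TRUE) {
      if (code %in% seed_codes) return(TRUE)
      parent <- sub("\\.[0-9]+$", "", code)
      if (identical(parent, code)) return(FALSE)
      code <- parent
    }
  }
  if (any(vapply(codes, reaches_seed, logical(1)))) "HT" else "NHT"
}

# A small fully rendered corpus for fast tests.
small_corpus <- function(seed, n_articles = 12, ...) {
  generate_corpus(generator_config(n_articles = n_articles,
                                   ht_fraction = 0, lambda_nht = 5,
                                   seed = seed, ...))
}
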
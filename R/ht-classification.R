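# High-throughput (HT) study classification from MeSH headings.
# An article counts as HT when any of its MeSH descriptors lies at or
# below one of six seed positions in the MeSH tree; the descendant test
# is a dotted-prefix test on tree codes, which is equivalent to walking
# the materialized hierarchy by construction of MeSH tree numbers.

MESH_CODE_RE <- "^[A-Z][0-9]{2}(\\.[0-9]+)*$"

#' The default high-throughput seed descriptors
#'
#' Six MeSH headings whose subtrees mark high-throughput genetic
#' studies: Computational biology (H01.158.273.180), Genetic techniques
#' (E05.393), Genome (G05.360.340), Molecular sequence data
#' (L01.453.245.667), Proteome (D12.776.817) and Proteomics
#' (H01.181.122.738).
#'
#' @param descriptors Optional replacement tibble with columns `heading`
#'   and `tree_code` (one row per seed code).
#' @return An `ht_seed_set` object.
#' @export
ht_seed_set <- function(descriptors = NULL) {
  if (is.null(descriptors)) {
    descriptors <- tibble::tibble(
      heading = c("Computational biology", "Genetic techniques", "Genome",
                  "Molecular sequence data", "Proteome", "Proteomics"),
      tree_code = c("H01.158.273.180", "E05.393", "G05.360.340",
                    "L01.453.245.667", "D12.776.817", "H01.181.122.738"))
  }
  descriptors <- tibble::as_tibble(descriptors)
  stopifnot(all(c("heading", "tree_code") %in% names(descriptors)))
  if (!all(grepl(MESH_CODE_RE, descriptors$tree_code))) {
    stop("malformed MeSH tree code in seed set", call. = FALSE)
  }
  structure(list(descriptors = descriptors), class = "ht_seed_set")
}

#' Is one MeSH tree code a descendant of another?
#'
#' `code` descends from `seed` when the two are equal or `code` extends
#' `seed` past a dot boundary (`E05.393.760` descends from `E05.393`;
#' `E05.3931` does not).
#'
#' @param code,seed Dotted MeSH tree codes (vectorized over `code`).
#' @return Logical vector.
#' @export
is_descendant <- function(code, seed) {
  if (!all(grepl(MESH_CODE_RE, code)) || !all(grepl(MESH_CODE_RE, seed))) {
    stop("malformed MeSH tree code", call. = FALSE)
  }
  code == seed | startsWith(code, paste0(seed, "."))
}

#' Load a MeSH descriptor table from TSV
#'
#' Columns: `heading` and `tree_codes` (semicolon-joined codes).
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per (heading, tree_code) pair.
#' @export
load_mesh_descriptors <- function(path) {
  tbl <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("heading", "tree_codes") %in% names(tbl)))
  codes <- strsplit(tbl$tree_codes, ";", fixed = TRUE)
  tibble::tibble(heading = rep(tbl$heading, lengths(codes)),
                 tree_code = trimws(unlist(codes)))
}

#' The synthetic MeSH descriptor fixture shipped with the package
#'
#' A small tree of descriptors covering the seed headings, a few of
#' their descendants, and unrelated headings; used by the synthetic
#' corpus generator and the classifier tests. It is not a MeSH extract.
#'
#' @return A descriptor tibble (see [load_mesh_descriptors()]).
#' @export
default_mesh_descriptors <- function() {
  load_mesh_descriptors(system.file("extdata", "mesh_descriptors.tsv",
                                    package = "varminer", mustWork = TRUE))
}

#' Label one article as HT, NHT or UNINDEXED
#'
#' @param headings Tibble of the article's MeSH descriptors with a
#'   `tree_code` column (zero rows for an unindexed article).
#' @param seeds An [ht_seed_set()].
#' @return `"HT"`, `"NHT"`, or `"UNINDEXED"` when no headings are
#'   assigned.
#' @export
label_article <- function(headings, seeds = ht_seed_set()) {
  if (is.null(headings) || !nrow(headings)) return("UNINDEXED")
  codes <- headings$tree_code
  for (seed in seeds$descriptors$tree_code) {
    if (any(is_descendant(codes, seed))) return("HT")
  }
  "NHT"
}

#' Label every article of a corpus
#'
#' @param article_headings Tibble with columns `doc_id`, `heading` (one
#'   row per assigned heading).
#' @param descriptors Descriptor tibble mapping `heading` to
#'   `tree_code` (e.g. [default_mesh_descriptors()]).
#' @param seeds An [ht_seed_set()].
#' @param all_docs Optional article ids to label; ids without headings
#'   come out `UNINDEXED`.
#' @return A tibble with `doc_id` and `label`.
#' @export
label_corpus <- function(article_headings, descriptors,
                         seeds = ht_seed_set(), all_docs = NULL) {
  merged <- dplyr::inner_join(tibble::as_tibble(article_headings),
                              tibble::as_tibble(descriptors),
                              by = "heading",
                              relationship = "many-to-many")
  docs <- if (is.null(all_docs)) unique(article_headings$doc_id) else
    unique(c(all_docs, article_headings$doc_id))
  labels <- vapply(docs, function(d) {
    label_article(merged[merged$doc_id == d, , drop = FALSE], seeds)
  }, character(1))
  tibble::tibble(doc_id = docs, label = unname(labels))
}

#' Split corpus statistics by HT label
#'
#' @param curated Curated records tibble.
#' @param labels Tibble with `doc_id` and `label` covering every curated
#'   article (an uncovered article is an error).
#' @param exclude_unindexed Drop UNINDEXED articles from the shares and
#'   denominators instead of reporting them as their own row.
#' @return A tibble with one row per label: the [corpus_stats()] columns
#'   plus `mutation_share` of the total curated mutations.
#' @export
split_corpus <- function(curated, labels, exclude_unindexed = FALSE) {
  curated <- dedupe_curated(curated)
  idx <- match(curated$doc_id, labels$doc_id)
  if (anyNA(idx)) {
    stop("missing HT label for curated article(s): ",
         paste(utils::head(unique(curated$doc_id[is.na(idx)]), 3),
               collapse = ", "), call. = FALSE)
  }
  curated$label <- labels$label[idx]
  if (exclude_unindexed) {
    curated <- curated[curated$label != "UNINDEXED", , drop = FALSE]
  }
  total <- nrow(curated)
  rows <- lapply(unique(curated$label), function(lb) {
    sub <- curated[curated$label == lb, , drop = FALSE]
    st <- corpus_stats(sub)
    dplyr::bind_cols(tibble::tibble(label = lb), st,
                     tibble::tibble(mutation_share = st$n_mutations / total))
  })
  dplyr::bind_rows(rows)
}
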
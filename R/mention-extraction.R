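# Pattern-based recognition of variant mentions and gene mentions in
# section text, and their association by co-occurrence.
#
# The pattern set covers the surface forms that matter for curation
# recovery: canonical HGVS cDNA substitutions and indels, prefix- and
# dot-tolerant legacy forms (c580G > T, 676C>T, C676T), protein
# substitutions in one- and three-letter code, extended protein indels
# (p.Glu554_Val559del, delins), dbSNP rs-numbers, natural-language
# substitutions ("C > T mutation at nucleotide 2131"), and imprecise
# exon/intron-level deletions which are flagged for later dropping.

AA1 <- "ACDEFGHIKLMNPQRSTVWY"
AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
         Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
         Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
         Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
         Ter = "*", Stop = "*", Sec = "U")

#' Configure the mention pattern classes
#'
#' Each class can be toggled independently; enabling an additional class
#' never removes a mention another class already found (scanning is
#' monotone in the enabled set).
#'
#' @param protein_sub Protein substitutions (one-letter, three-letter,
#'   `p.`-prefixed).
#' @param dna_sub cDNA substitutions (`c.676C>T`).
#' @param dna_indel cDNA insertions/deletions/duplications.
#' @param protein_indel Extended protein indels (`p.Glu554_Val559del`,
#'   `delins`).
#' @param rsid dbSNP rs-number identifiers.
#' @param nl_sub Natural-language substitutions
#'   (`"C > T mutation at nucleotide 2131"`), including codon-position
#'   phrasings.
#' @param tolerant_dna Accept cDNA forms missing the dot or the whole
#'   `c.` prefix, spaces around `>`, and the legacy `C676T` form.
#' @param exon_intron Recognize imprecise exon/intron deletions and
#'   whole-gene deletions (flagged; dropped at normalization).
#' @return A `pattern_config` list of logical flags.
#' @export
pattern_config <- function(protein_sub = TRUE, dna_sub = TRUE,
                           dna_indel = TRUE, protein_indel = TRUE,
                           rsid = TRUE, nl_sub = TRUE,
                           tolerant_dna = TRUE, exon_intron = TRUE) {
  cfg <- list(protein_sub = protein_sub, dna_sub = dna_sub,
              dna_indel = dna_indel, protein_indel = protein_indel,
              rsid = rsid, nl_sub = nl_sub, tolerant_dna = tolerant_dna,
              exon_intron = exon_intron)
  stopifnot(all(vapply(cfg, is.logical, logical(1))))
  structure(cfg, class = "pattern_config")
}

# All matches of a perl regex with capture groups, as a data frame of
# start/end (0-based half-open) plus one column per group.
match_all <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  n_grp <- if (is.null(cs)) 0L else ncol(cs)
  grp <- if (n_grp) {
    sapply(seq_len(n_grp), function(j) {
      ifelse(cs[, j] > 0L,
             substring(text, cs[, j], cs[, j] + cl[, j] - 1L), NA_character_)
    })
  }
  if (!is.null(grp) && is.null(dim(grp))) grp <- matrix(grp, nrow = 1L)
  out <- data.frame(start = starts - 1L, end = starts - 1L + lens,
                    raw = substring(text, starts, starts + lens - 1L),
                    stringsAsFactors = FALSE)
  if (n_grp) for (j in seq_len(n_grp)) out[[paste0("g", j)]] <- grp[, j]
  out
}

empty_mentions <- function() {
  tibble::tibble(mention_class = character(), raw = character(),
                 start = integer(), end = integer(),
                 wt = character(), pos = character(), pos2 = character(),
                 mut = character(), op = character(), seq = character(),
                 codon = logical(), exon_intron = logical())
}

mention_row <- function(class, m, wt = NA, pos = NA, pos2 = NA, mut = NA,
                        op = NA, seq = NA, codon = FALSE,
                        exon_intron = FALSE) {
  tibble::tibble(mention_class = class, raw = m$raw, start = m$start,
                 end = m$end, wt = as.character(wt),
                 pos = as.character(pos), pos2 = as.character(pos2),
                 mut = as.character(mut), op = as.character(op),
                 seq = as.character(seq), codon = codon,
                 exon_intron = exon_intron)
}

LB <- "(?<![A-Za-z0-9_.])"     # token must not continue a word/number
RB <- "(?![A-Za-z0-9])"

#' Scan a section for variant mentions
#'
#' Returns all non-overlapping mentions; overlapping candidates are
#' resolved leftmost-start first, then longest. Spans are 0-based
#' half-open character offsets into the section text.
#'
#' @param section A [document_section()] row (or any one-row tibble with
#'   a `text` column).
#' @param patterns A [pattern_config()].
#' @return A tibble of mentions with parsed components: `mention_class`,
#'   `raw`, `start`, `end`, `wt`, `pos`, `pos2`, `mut`, `op`, `seq`,
#'   `codon`, `exon_intron`.
#' @export
scan_mentions <- function(section, patterns = pattern_config()) {
  text <- section$text[[1]]
  out <- list()
  add <- function(x) if (!is.null(x) && nrow(x)) out[[length(out) + 1L]] <<- x

  # natural-language substitutions, nucleotide- or codon-positioned
  if (patterns$nl_sub) {
    p <- paste0(LB, "([ACGT])\\s?>\\s?([ACGT])\\s+(?:mutation|substitution|",
                "change)\\s+at\\s+(nucleotide|position|codon)\\s+([0-9]+)", RB)
    m <- match_all(text, p)
    if (!is.null(m)) {
      add(mention_row("nl_sub", m, wt = m$g1, pos = m$g4, mut = m$g2,
                      codon = m$g3 == "codon"))
    }
  }

  # extended protein indels: p.Glu554_Val559del, p.Ser566_Glu571delinsArg
  if (patterns$protein_indel) {
    p <- paste0(LB, "p\\.([A-Z][a-z]{2})([0-9]+)",
                "(?:_([A-Z][a-z]{2})([0-9]+))?",
                "(delins|del|dup|ins)([A-Za-z]*)", RB)
    m <- match_all(text, p)
    if (!is.null(m)) {
      keep <- m$g1 %in% names(AA3) & (is.na(m$g3) | m$g3 %in% names(AA3))
      m <- m[keep, , drop = FALSE]
      if (nrow(m)) {
        add(mention_row("protein_indel", m, wt = m$g1, pos = m$g2,
                        pos2 = m$g4, mut = m$g3, op = m$g5, seq = m$g6))
      }
    }
  }

  # imprecise exon/intron deletions and whole-gene deletions
  if (patterns$exon_intron && patterns$dna_indel) {
    p <- paste0("(?i)", LB,
                "(?:del(?:etions?)?\\s+(?:of\\s+)?(?:exons?|introns?)\\s+",
                "[0-9]+(?:\\s?[-–]\\s?[0-9]+)?",
                "|(?:exons?|introns?)\\s+[0-9]+\\s+del(?:etions?)?",
                "|entire\\s+gene\\s+deletion)", RB)
    m <- match_all(text, p)
    if (!is.null(m)) {
      add(mention_row("dna_indel", m, op = "del", exon_intron = TRUE))
    }
  }

  # cDNA indels: c.597_598delGA, c.597-598delGA, 840insT, c.501del1
  if (patterns$dna_indel) {
    pre <- if (patterns$tolerant_dna) "(?:[cC]\\s?\\.?\\s?)?" else "[cC]\\."
    p <- paste0(LB, pre, "([0-9]+)(?:\\s?[-_]\\s?([0-9]+))?",
                "(delins|del|ins|dup)([ACGT]+|[0-9]+)?", RB)
    m <- match_all(text, p)
    if (!is.null(m)) {
      add(mention_row("dna_indel", m, pos = m$g1, pos2 = m$g2, op = m$g3,
                      seq = m$g4))
    }
  }

  # cDNA substitutions with prefix: c.676C>T, c676G > T, c580G > T
  if (patterns$dna_sub) {
    dot <- if (patterns$tolerant_dna) "\\s?\\.?\\s?" else "\\."
    p <- paste0(LB, "[cC]", dot, "([0-9]+(?:[-+][0-9]+)?)",
                "\\s?([ACGT])\\s?>\\s?([ACGT])", RB)
    m <- match_all(text, p)
    if (!is.null(m)) {
      add(mention_row("dna_sub", m, wt = m$g2, pos = m$g1, mut = m$g3))
    }
    if (patterns$tolerant_dna) {
      # prefix-free: 676C>T
      p <- paste0(LB, "([0-9]+(?:[-+][0-9]+)?)\\s?([ACGT])\\s?>\\s?([ACGT])",
                  RB)
      m <- match_all(text, p)
      if (!is.null(m)) {
        add(mention_row("dna_sub", m, wt = m$g2, pos = m$g1, mut = m$g3))
      }
    }
  }

  # protein substitutions, p.-prefixed or three-letter
  if (patterns$protein_sub) {
    p <- paste0(LB, "p\\.\\(?([A-Z])([0-9]+)([A-Z*])\\)?", RB)
    m <- match_all(text, p)
    if (!is.null(m)) {
      aa <- strsplit(AA1, "")[[1]]
      keep <- m$g1 %in% aa & (m$g3 %in% c(aa, "*", "X"))
      m <- m[keep, , drop = FALSE]
      if (nrow(m)) {
        add(mention_row("protein_sub", m, wt = m$g1, pos = m$g2, mut = m$g3))
      }
    }
    aa3_alt <- paste(names(AA3), collapse = "|")
    p <- paste0("(?i)", LB, "(?:p\\.)?(", aa3_alt, ")\\s?-?([0-9]+)\\s?-?(",
                aa3_alt, ")", RB)
    m <- match_all(text, p)
    if (!is.null(m)) {
      add(mention_row("protein_sub", m, wt = m$g1, pos = m$g2, mut = m$g3))
    }
  }

  # bare letter-digits-letter: C676T is a legacy cDNA form when both
  # letters are nucleotides and differ; otherwise a one-letter protein
  # substitution (uppercase only, for precision)
  if (patterns$protein_sub || (patterns$dna_sub && patterns$tolerant_dna)) {
    p <- paste0(LB, "([A-Z])([0-9]+)([A-Z*])", RB)
    m <- match_all(text, p)
    if (!is.null(m)) {
      nt <- c("A", "C", "G", "T")
      aa <- strsplit(AA1, "")[[1]]
      is_dna <- m$g1 %in% nt & m$g3 %in% nt & m$g1 != m$g3
      if (patterns$dna_sub && patterns$tolerant_dna) {
        d <- m[is_dna, , drop = FALSE]
        if (nrow(d)) {
          add(mention_row("dna_sub", d, wt = d$g1, pos = d$g2, mut = d$g3))
        }
      }
      if (patterns$protein_sub) {
        is_prot <- !is_dna & m$g1 %in% aa & m$g3 %in% c(aa, "*", "X")
        pr <- m[is_prot, , drop = FALSE]
        if (nrow(pr)) {
          add(mention_row("protein_sub", pr, wt = pr$g1, pos = pr$g2,
                          mut = pr$g3))
        }
      }
    }
  }

  # dbSNP identifiers
  if (patterns$rsid) {
    m <- match_all(text, paste0(LB, "rs([0-9]+)", RB))
    if (!is.null(m)) add(mention_row("rsid", m, seq = m$raw))
  }

  if (!length(out)) return(empty_mentions())
  all <- dplyr::bind_rows(out)
  resolve_overlaps(all)
}

# Leftmost start wins; at equal start the longer match wins; remaining
# overlaps are discarded greedily.
resolve_overlaps <- function(mentions) {
  ord <- order(mentions$start, -(mentions$end - mentions$start))
  mentions <- mentions[ord, , drop = FALSE]
  keep <- logical(nrow(mentions))
  last_end <- -1L
  for (i in seq_len(nrow(mentions))) {
    if (mentions$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- mentions$end[i]
    }
  }
  mentions[keep, , drop = FALSE]
}

#' Build a gene dictionary
#'
#' Surface forms map to a normalized symbol and (optionally) an HGNC
#' identifier. Forms on the stop list — gene names that collide with
#' codon names — are removed. The alias `P53` (for TP53) is guaranteed
#' present: it is added when missing, since it is absent from the usual
#' source dictionaries yet frequent in text.
#'
#' @param entries Tibble/data.frame with columns `surface`, `symbol`,
#'   `hgnc_id` (optional, `NA` allowed).
#' @param stop_list Character vector of surface forms to exclude.
#' @return A `gene_dictionary` object.
#' @export
gene_dictionary <- function(entries, stop_list = character()) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("surface", "symbol") %in% names(entries)))
  if (!"hgnc_id" %in% names(entries)) entries$hgnc_id <- NA_character_
  entries$surface <- toupper(entries$surface)
  stop_list <- toupper(stop_list)
  entries <- entries[!entries$surface %in% stop_list, , drop = FALSE]
  if (!"P53" %in% entries$surface) {
    tp53 <- entries$hgnc_id[entries$symbol == "TP53"][1]
    entries <- dplyr::bind_rows(
      entries,
      tibble::tibble(surface = "P53", symbol = "TP53",
                     hgnc_id = if (length(tp53)) tp53 else NA_character_))
  }
  entries <- entries[!duplicated(entries$surface), , drop = FALSE]
  structure(list(entries = entries, stop_list = stop_list),
            class = "gene_dictionary")
}

#' Load a gene dictionary from TSV
#'
#' Expected columns: `surface`, `symbol`, `hgnc_id`; an optional logical
#' `is_stop` column marks stop-listed forms.
#'
#' @param path Path to the TSV file.
#' @return A [gene_dictionary()].
#' @export
load_gene_dictionary <- function(path) {
  tbl <- utils::read.delim(path, colClasses = "character")
  stop_list <- character()
  if ("is_stop" %in% names(tbl)) {
    stop_list <- tbl$surface[tbl$is_stop %in% c("TRUE", "true", "1")]
    tbl <- tbl[!tbl$is_stop %in% c("TRUE", "true", "1"), , drop = FALSE]
    tbl$is_stop <- NULL
  }
  gene_dictionary(tbl, stop_list = stop_list)
}

#' The dictionary shipped with the package
#'
#' A compact dictionary of human cancer- and mismatch-repair-associated
#' gene symbols with HGNC identifiers, sufficient for the synthetic
#' corpora; real analyses would load a full HGNC/NCBI-derived table with
#' [load_gene_dictionary()].
#'
#' @return A [gene_dictionary()].
#' @export
default_gene_dictionary <- function() {
  load_gene_dictionary(system.file("extdata", "gene_dictionary.tsv",
                                   package = "varminer", mustWork = TRUE))
}

#' Scan a section for gene mentions
#'
#' Case-insensitive, longest-match dictionary lookup over word-boundary
#' tokens. With `strip_h_prefix = TRUE`, a token `hX` also matches when
#' `X` is a dictionary entry (so `hMLH1` resolves to MLH1); the flag is
#' off by default.
#'
#' @param section A [document_section()] row.
#' @param dict A [gene_dictionary()].
#' @param strip_h_prefix Also match tokens with a leading `h`.
#' @return A tibble with `raw`, `symbol`, `hgnc_id`, `start`, `end`.
#' @export
scan_genes <- function(section, dict, strip_h_prefix = FALSE) {
  stopifnot(inherits(dict, "gene_dictionary"))
  text <- section$text[[1]]
  entries <- dict$entries
  empty <- tibble::tibble(raw = character(), symbol = character(),
                          hgnc_id = character(), start = integer(),
                          end = integer())
  if (!nrow(entries)) return(empty)
  forms <- entries$surface[order(-nchar(entries$surface))]
  alt <- paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", forms),
               collapse = "|")
  pats <- paste0("(?i)", LB, "(", alt, ")", RB)
  if (strip_h_prefix) {
    pats <- c(pats, paste0("(?i)", LB, "h(", alt, ")", RB))
  }
  hits <- list()
  for (p in pats) {
    m <- match_all(text, p)
    if (!is.null(m)) hits[[length(hits) + 1L]] <- m
  }
  if (!length(hits)) return(empty)
  m <- dplyr::bind_rows(hits)
  key <- toupper(m$g1)
  idx <- match(key, entries$surface)
  res <- tibble::tibble(raw = m$raw, symbol = entries$symbol[idx],
                        hgnc_id = entries$hgnc_id[idx],
                        start = m$start, end = m$end)
  ord <- order(res$start, -(res$end - res$start))
  res <- res[ord, , drop = FALSE]
  keep <- logical(nrow(res))
  last_end <- -1L
  for (i in seq_len(nrow(res))) {
    if (res$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- res$end[i]
    }
  }
  res[keep, , drop = FALSE]
}

#' Associate variant mentions with gene mentions by co-occurrence
#'
#' With `scope = "document"` (the operating mode throughout this
#' package), every mention is paired with every distinct gene symbol
#' found in the same text unit, so one mutation may yield several
#' pairs; mentions with no co-occurring gene pair with the absent gene
#' (`NA`). With `scope = "sentence"`, pairing is restricted to genes in
#' the same sentence, where sentences are split naively on terminal
#' punctuation followed by whitespace.
#'
#' @param mentions Tibble from [scan_mentions()].
#' @param genes Tibble from [scan_genes()].
#' @param scope `"document"` or `"sentence"`.
#' @param text Section text; required for sentence scope.
#' @return The `mentions` tibble replicated per associated gene, with
#'   `gene_symbol` and `gene_hgnc_id` columns (`NA` when absent).
#' @export
associate <- function(mentions, genes, scope = c("document", "sentence"),
                      text = NULL) {
  scope <- match.arg(scope)
  if (!nrow(mentions)) {
    mentions$gene_symbol <- character()
    mentions$gene_hgnc_id <- character()
    return(mentions)
  }
  pair_with <- function(mrows, grows) {
    syms <- unique(grows$symbol)
    if (!length(syms)) {
      mrows$gene_symbol <- NA_character_
      mrows$gene_hgnc_id <- NA_character_
      return(mrows)
    }
    hg <- grows$hgnc_id[match(syms, grows$symbol)]
    out <- mrows[rep(seq_len(nrow(mrows)), each = length(syms)), ,
                 drop = FALSE]
    out$gene_symbol <- rep(syms, times = nrow(mrows))
    out$gene_hgnc_id <- rep(hg, times = nrow(mrows))
    out
  }
  if (scope == "document") {
    return(pair_with(mentions, genes))
  }
  if (is.null(text)) {
    stop("sentence scope requires the section text", call. = FALSE)
  }
  bounds <- gregexpr("[.!?][[:space:]]", text)[[1]]
  cuts <- if (bounds[1] == -1L) integer() else as.integer(bounds)
  sent_of <- function(start) sum(cuts <= start) # 0-based sentence index
  m_sent <- vapply(mentions$start, sent_of, integer(1))
  g_sent <- if (nrow(genes)) vapply(genes$start, sent_of, integer(1)) else
    integer()
  out <- lapply(unique(m_sent), function(s) {
    pair_with(mentions[m_sent == s, , drop = FALSE],
              genes[g_sent == s, , drop = FALSE])
  })
  dplyr::bind_rows(out)
}
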
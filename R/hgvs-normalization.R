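# Normalization of variant mentions to canonical HGVS strings, position
# expansion for codon-level and rs-number mentions, and the equivalence
# relation used when matching against curated records.

#' A normalized variant
#'
#' @param level `"dna"` or `"protein"`.
#' @param hgvs Canonical string: cDNA strings start with `"c."`; protein
#'   substitutions have the form `A140T` (stop codon rendered `*`).
#' @param alternates Equally valid canonical strings arising from codon
#'   or rs-number expansion (empty otherwise).
#' @param provenance Mention class of origin, or `NA`.
#' @return A `normalized_variant` object.
#' @export
normalized_variant <- function(level, hgvs, alternates = character(),
                               provenance = NA_character_) {
  level <- match.arg(level, c("dna", "protein"))
  stopifnot(is.character(hgvs), length(hgvs) == 1L, nzchar(hgvs))
  if (level == "dna" && !startsWith(hgvs, "c.")) {
    stop("canonical cDNA strings must start with 'c.': ", hgvs,
         call. = FALSE)
  }
  structure(list(level = level, hgvs = hgvs,
                 alternates = unique(setdiff(alternates, hgvs)),
                 provenance = provenance),
            class = "normalized_variant")
}

#' @export
print.normalized_variant <- function(x, ...) {
  cat("<", x$level, "> ", x$hgvs, sep = "")
  if (length(x$alternates)) {
    cat(" (alternates: ", paste(x$alternates, collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Configure matching relaxations
#'
#' @param ignore_gene Drop the gene-match requirement (the "NG"
#'   evaluation mode).
#' @param del_length_equivalence Treat a deletion written with its base
#'   string as equivalent to one written with the base count at the same
#'   position(s): `c.482_483delGA` matches `c.482_483del2`.
#' @param tolerant_prefix Add a missing `c.` prefix during indel
#'   normalization (`840insT` becomes `c.840insT`).
#' @param codon_expansion Use the three candidate nucleotide positions
#'   derived from codon-level mentions during matching.
#' @param rsid_expansion Use candidate variants from the rs-number
#'   lookup during matching.
#' @return A `match_config` list of logical flags.
#' @export
match_config <- function(ignore_gene = FALSE, del_length_equivalence = FALSE,
                         tolerant_prefix = TRUE, codon_expansion = TRUE,
                         rsid_expansion = TRUE) {
  cfg <- list(ignore_gene = ignore_gene,
              del_length_equivalence = del_length_equivalence,
              tolerant_prefix = tolerant_prefix,
              codon_expansion = codon_expansion,
              rsid_expansion = rsid_expansion)
  stopifnot(all(vapply(cfg, is.logical, logical(1))))
  structure(cfg, class = "match_config")
}

aa_to_one <- function(x) {
  if (is.na(x)) return(NA_character_)
  if (nchar(x) == 1L) {
    if (x %in% c("X", "*")) return("*")
    if (grepl(paste0("^[", AA1, "]$"), x)) return(x)
    stop("unknown amino-acid code: ", x, call. = FALSE)
  }
  key <- paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
  full <- c(Alanine = "A", Arginine = "R", Asparagine = "N",
            Aspartate = "D", Cysteine = "C", Glutamine = "Q",
            Glutamate = "E", Glycine = "G", Histidine = "H",
            Isoleucine = "I", Leucine = "L", Lysine = "K",
            Methionine = "M", Phenylalanine = "F", Proline = "P",
            Serine = "S", Threonine = "T", Tryptophan = "W",
            Tyrosine = "Y", Valine = "V")
  out <- AA3[key]
  if (is.na(out)) out <- full[key]
  if (is.na(out)) stop("unknown amino-acid token: ", x, call. = FALSE)
  unname(out)
}

#' Normalize a protein substitution
#'
#' Wild-type and mutant residues may be given in one-letter, three-letter
#' or full-name form; `Stop`, `Ter`, `X` and `*` all denote a stop
#' codon, rendered `*` in the canonical string.
#'
#' @param wt Wild-type residue token.
#' @param pos Position, a positive integer.
#' @param mut Mutant residue token.
#' @return A protein-level [normalized_variant()], e.g. `A140T`.
#' @export
normalize_protein_sub <- function(wt, pos, mut) {
  pos <- as.integer(pos)
  stopifnot(!is.na(pos), pos >= 1L)
  normalized_variant("protein",
                     paste0(aa_to_one(wt), pos, aa_to_one(mut)),
                     provenance = "protein_sub")
}

#' Normalize a cDNA substitution
#'
#' @param pos Position: a positive integer, or an opaque intronic-offset
#'   token such as `"1410-54"` which is carried verbatim.
#' @param wt Wild-type nucleotide (A/C/G/T).
#' @param mut Mutant nucleotide; must differ from `wt`.
#' @return A DNA-level [normalized_variant()], e.g. `c.676C>T`.
#' @export
normalize_dna_sub <- function(pos, wt, mut) {
  wt <- toupper(wt); mut <- toupper(mut)
  if (!wt %in% c("A", "C", "G", "T") || !mut %in% c("A", "C", "G", "T")) {
    stop("nucleotides must be one of A, C, G, T", call. = FALSE)
  }
  if (wt == mut) {
    stop("degenerate substitution: wild-type equals mutant (", wt, ")",
         call. = FALSE)
  }
  pos <- as.character(pos)
  if (!grepl("^[0-9]+([-+][0-9]+)?$", pos) ||
      (grepl("^[0-9]+$", pos) && as.numeric(pos) < 1)) {
    stop("invalid cDNA position: ", pos, call. = FALSE)
  }
  normalized_variant("dna", paste0("c.", pos, wt, ">", mut),
                     provenance = "dna_sub")
}

#' Normalize a cDNA insertion/deletion/duplication
#'
#' Hyphen range separators become underscores (`c.597-598delGA` to
#' `c.597_598delGA`); a missing `c.` prefix is added when
#' `tolerant_prefix` is on (`840insT` to `c.840insT`); base strings are
#' upper-cased. Already-canonical input is returned unchanged.
#'
#' @param raw The indel string.
#' @param tolerant_prefix Add a missing `c.` prefix.
#' @return A DNA-level [normalized_variant()].
#' @export
normalize_indel <- function(raw, tolerant_prefix = TRUE) {
  p <- paste0("^([cC]\\s?\\.?\\s?)?([0-9]+)(?:\\s?[-_]\\s?([0-9]+))?",
              "(delins|del|ins|dup)([ACGTacgt]+|[0-9]+)?$")
  m <- regmatches(raw, regexec(p, trimws(raw), perl = TRUE))[[1]]
  if (!length(m)) stop("unparseable indel: ", raw, call. = FALSE)
  if (m[2] == "" && !tolerant_prefix) {
    stop("missing c. prefix in indel: ", raw, call. = FALSE)
  }
  pos <- m[3]
  range <- if (nzchar(m[4])) paste0(pos, "_", m[4]) else pos
  seq <- m[6]
  if (nzchar(seq) && !grepl("^[0-9]+$", seq)) seq <- toupper(seq)
  normalized_variant("dna", paste0("c.", range, m[5], seq),
                     provenance = "dna_indel")
}

#' Expand a codon position to its three candidate nucleotide positions
#'
#' Codon `c` covers cDNA positions `3c - 2`, `3c - 1`, `3c`.
#'
#' @param codon Positive integer codon number.
#' @return Integer vector of the three positions.
#' @export
expand_codon <- function(codon) {
  codon <- as.integer(codon)
  if (is.na(codon) || codon < 1L) {
    stop("codon number must be a positive integer", call. = FALSE)
  }
  (3L * codon - 2L):(3L * codon)
}

#' Build an rs-number lookup table
#'
#' Replaces a live dbSNP query with a local table mapping each rs-number
#' to its candidate DNA and protein variants.
#'
#' @param tbl Tibble/data.frame with columns `rsid`, `level`, `hgvs`.
#' @return An `rsid_lookup` object.
#' @export
rsid_lookup <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("rsid", "level", "hgvs") %in% names(tbl)))
  if (!all(grepl("^rs[0-9]+$", tbl$rsid))) {
    stop("rs-number keys must match rs[0-9]+", call. = FALSE)
  }
  structure(list(table = tbl), class = "rsid_lookup")
}

#' Load an rs-number lookup from TSV
#'
#' @param path TSV with columns `rsid`, `level`, `hgvs`.
#' @return An [rsid_lookup()].
#' @export
load_rsid_lookup <- function(path) {
  rsid_lookup(utils::read.delim(path, colClasses = "character"))
}

#' Expand an rs-number to its candidate variants
#'
#' @param rsid An rs-number string (`rs[0-9]+`).
#' @param lookup An [rsid_lookup()].
#' @return A list of [normalized_variant()] candidates; empty when the
#'   id is absent from the table.
#' @export
expand_rsid <- function(rsid, lookup) {
  if (!grepl("^rs[0-9]+$", rsid)) {
    stop("malformed rs-number: ", rsid, call. = FALSE)
  }
  stopifnot(inherits(lookup, "rsid_lookup"))
  rows <- lookup$table[lookup$table$rsid == rsid, , drop = FALSE]
  if (!nrow(rows)) {
    message("rs-number not in lookup table: ", rsid)
    return(list())
  }
  lapply(seq_len(nrow(rows)), function(i) {
    normalized_variant(rows$level[i], rows$hgvs[i], provenance = "rsid")
  })
}

#' Drop mentions whose position cannot be made precise
#'
#' Mentions located only by exon/intron number, and natural-language
#' whole-gene deletions, carry no derivable cDNA position and are
#' dropped rather than normalized.
#'
#' @param mention One mention row from [scan_mentions()].
#' @return `NULL` (dropped) for imprecise mentions; otherwise the
#'   mention row, to proceed to normalization.
#' @export
drop_imprecise <- function(mention) {
  if (isTRUE(mention$exon_intron[[1]])) return(NULL)
  mention
}

#' Normalize one scanned mention
#'
#' Dispatches on the mention class; imprecise (exon/intron) mentions
#' return `NULL`, rs-numbers expand through the lookup, codon-position
#' mentions expand to three candidate substitutions (the alternates).
#'
#' @param mention One mention row from [scan_mentions()].
#' @param lookup Optional [rsid_lookup()] for rs-number expansion.
#' @return A list of [normalized_variant()] (possibly empty).
#' @export
normalize_mention <- function(mention, lookup = NULL) {
  if (is.null(drop_imprecise(mention))) return(list())
  cls <- mention$mention_class[[1]]
  res <- tryCatch(switch(
    cls,
    protein_sub = list(normalize_protein_sub(mention$wt[[1]],
                                             mention$pos[[1]],
                                             mention$mut[[1]])),
    dna_sub = list(normalize_dna_sub(mention$pos[[1]], mention$wt[[1]],
                                     mention$mut[[1]])),
    dna_indel = list(normalize_indel(mention$raw[[1]])),
    protein_indel = list(normalize_protein_indel(mention)),
    nl_sub = if (isTRUE(mention$codon[[1]])) {
      positions <- expand_codon(mention$pos[[1]])
      cands <- paste0("c.", positions, toupper(mention$wt[[1]]), ">",
                      toupper(mention$mut[[1]]))
      list(normalized_variant("dna", cands[1], alternates = cands,
                              provenance = "codon"))
    } else {
      list(normalize_dna_sub(mention$pos[[1]], mention$wt[[1]],
                             mention$mut[[1]]))
    },
    rsid = if (is.null(lookup)) list() else
      expand_rsid(mention$seq[[1]], lookup),
    list()),
    error = function(e) list())
  res
}

# Bulk normalization of a mention table (the pipeline's fast path):
# class-wise vectorized where possible, with unparseable or degenerate
# mentions silently dropped, mirroring normalize_mention() row by row.
normalize_mentions_bulk <- function(mentions, lookup = NULL) {
  empty <- tibble::tibble(level = character(), hgvs = character(),
                          alternates = list(), provenance = character())
  mentions <- mentions[!mentions$exon_intron, , drop = FALSE]
  if (!nrow(mentions)) return(empty)
  cls <- mentions$mention_class
  out <- list(empty)

  plain_sub <- cls == "dna_sub" |
    (cls == "nl_sub" & !mentions$codon)
  if (any(plain_sub)) {
    wt <- toupper(mentions$wt[plain_sub])
    mut <- toupper(mentions$mut[plain_sub])
    pos <- mentions$pos[plain_sub]
    keep <- wt != mut & wt %in% NUCS & mut %in% NUCS
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        level = "dna",
        hgvs = paste0("c.", pos[keep], wt[keep], ">", mut[keep]),
        alternates = rep(list(character()), sum(keep)),
        provenance = "dna_sub")
    }
  }

  codon_sub <- which(cls == "nl_sub" & mentions$codon)
  for (i in codon_sub) {
    ci <- suppressWarnings(as.integer(mentions$pos[i]))
    if (is.na(ci) || ci < 1L) next
    wt <- toupper(mentions$wt[i]); mut <- toupper(mentions$mut[i])
    if (wt == mut) next
    cands <- paste0("c.", expand_codon(ci), wt, ">", mut)
    out[[length(out) + 1L]] <- tibble::tibble(
      level = "dna", hgvs = cands[1], alternates = list(cands),
      provenance = "codon")
  }

  indel <- which(cls == "dna_indel")
  if (length(indel)) {
    canon <- vapply(mentions$raw[indel], function(r) {
      tryCatch(normalize_indel(r)$hgvs, error = function(e) NA_character_)
    }, "", USE.NAMES = FALSE)
    keep <- !is.na(canon)
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        level = "dna", hgvs = canon[keep],
        alternates = rep(list(character()), sum(keep)),
        provenance = "dna_indel")
    }
  }

  prot <- which(cls == "protein_sub")
  if (length(prot)) {
    one <- function(x) tryCatch(aa_to_one(x),
                                error = function(e) NA_character_)
    wt <- vapply(mentions$wt[prot], one, "", USE.NAMES = FALSE)
    mut <- vapply(mentions$mut[prot], one, "", USE.NAMES = FALSE)
    pos <- suppressWarnings(as.integer(mentions$pos[prot]))
    keep <- !is.na(wt) & !is.na(mut) & !is.na(pos) & pos >= 1L
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        level = "protein",
        hgvs = paste0(wt[keep], pos[keep], mut[keep]),
        alternates = rep(list(character()), sum(keep)),
        provenance = "protein_sub")
    }
  }

  pindel <- which(cls == "protein_indel")
  for (i in pindel) {
    v <- tryCatch(normalize_protein_indel(mentions[i, , drop = FALSE]),
                  error = function(e) NULL)
    if (!is.null(v)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        level = v$level, hgvs = v$hgvs, alternates = list(v$alternates),
        provenance = v$provenance)
    }
  }

  rs <- which(cls == "rsid")
  if (length(rs) && !is.null(lookup)) {
    for (i in rs) {
      for (v in expand_rsid(mentions$seq[i], lookup)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          level = v$level, hgvs = v$hgvs,
          alternates = list(v$alternates), provenance = v$provenance)
      }
    }
  }
  dplyr::bind_rows(out)
}

normalize_protein_indel <- function(mention) {
  wt1 <- aa_to_one(mention$wt[[1]])
  part1 <- paste0(wt1, mention$pos[[1]])
  part2 <- if (!is.na(mention$mut[[1]])) {
    paste0("_", aa_to_one(mention$mut[[1]]), mention$pos2[[1]])
  } else ""
  seq <- mention$seq[[1]]
  seq <- if (is.na(seq) || !nzchar(seq)) "" else seq
  normalized_variant("protein",
                     paste0(part1, part2, mention$op[[1]], seq),
                     provenance = "protein_indel")
}

# Parse a canonical-ish deletion string into position key and payload.
parse_del <- function(hgvs) {
  m <- regmatches(hgvs,
                  regexec("^c\\.([0-9]+(?:_[0-9]+)?)del([ACGT]+|[0-9]+)?$",
                          hgvs))[[1]]
  if (!length(m)) return(NULL)
  payload <- m[3]
  list(range = m[2],
       len = if (!nzchar(payload)) NA_integer_
             else if (grepl("^[0-9]+$", payload)) as.integer(payload)
             else nchar(payload))
}

#' Test whether two normalized variants are equivalent
#'
#' Variants at different levels are never equivalent. Otherwise,
#' equivalence holds when the canonical strings are equal; when
#' `del_length_equivalence` is on and both are deletions over the same
#' position(s) with equal deleted length (one written as a base string,
#' the other as a count); or when the expanded candidate sets intersect
#' (codon alternates under `codon_expansion`, rs-number candidates under
#' `rsid_expansion`). With all flags off, equivalence is string
#' equality.
#'
#' @param a,b [normalized_variant()] objects.
#' @param cfg A [match_config()].
#' @return Logical.
#' @export
variant_equivalent <- function(a, b, cfg = match_config()) {
  stopifnot(inherits(a, "normalized_variant"),
            inherits(b, "normalized_variant"))
  if (a$level != b$level) return(FALSE)
  if (a$hgvs == b$hgvs) return(TRUE)
  if (cfg$del_length_equivalence) {
    da <- parse_del(a$hgvs)
    db <- parse_del(b$hgvs)
    if (!is.null(da) && !is.null(db) && da$range == db$range &&
        !is.na(da$len) && !is.na(db$len) && da$len == db$len) {
      return(TRUE)
    }
  }
  alts <- function(v) {
    use <- switch(ifelse(is.na(v$provenance), "other", v$provenance),
                  codon = cfg$codon_expansion,
                  rsid = cfg$rsid_expansion,
                  other = TRUE,
                  TRUE)
    if (use) c(v$hgvs, v$alternates) else v$hgvs
  }
  length(intersect(alts(a), alts(b))) > 0L
}
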
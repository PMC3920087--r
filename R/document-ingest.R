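# Document ingestion: abstract XML, simplified JATS-style full text,
# delimited supplementary files, and pre-extracted PDF text are parsed
# into a uniform per-source representation that the mention scanner
# consumes.

SOURCE_KINDS <- c("abstract", "body", "table", "pdf_text", "supplement")

#' Create a document section
#'
#' A document section is one unit of scannable text from a single source
#' of an article: its abstract, its narrative body, a linearized table,
#' pre-extracted PDF text, or a supplementary file. Section text is
#' always plain: no markup tags and no XML character entities.
#'
#' @param source_kind One of `"abstract"`, `"body"`, `"table"`,
#'   `"pdf_text"`, `"supplement"`.
#' @param text Plain unicode text of the section.
#' @param origin Optional provenance label (table id, supplement
#'   filename).
#' @return A one-row tibble with columns `source_kind`, `text`, `origin`.
#' @export
document_section <- function(source_kind, text, origin = NA_character_) {
  source_kind <- match.arg(source_kind, SOURCE_KINDS)
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("&(gt|lt|amp);", text) || grepl("<[A-Za-z/!?]", text)) {
    stop("section text must not contain XML tags or character entities",
         call. = FALSE)
  }
  tibble::tibble(source_kind = source_kind, text = text,
                 origin = as.character(origin))
}

#' Bundle the sections of one article
#'
#' @param doc_id Non-empty article identifier (e.g. a PMID-like string).
#' @param sections A tibble of sections as produced by
#'   [document_section()], row-bound; at most one abstract section.
#' @return An object of class `document_bundle`.
#' @export
document_bundle <- function(doc_id, sections) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (is.null(sections)) {
    sections <- tibble::tibble(source_kind = character(),
                               text = character(), origin = character())
  }
  stopifnot(all(c("source_kind", "text", "origin") %in% names(sections)))
  if (sum(sections$source_kind == "abstract") > 1L) {
    stop("a bundle may carry at most one abstract section", call. = FALSE)
  }
  structure(list(doc_id = doc_id, sections = sections),
            class = "document_bundle")
}

#' @export
print.document_bundle <- function(x, ...) {
  cat("<document_bundle> ", x$doc_id, ": ", nrow(x$sections),
      " section(s) [", paste(unique(x$sections$source_kind), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Create a table grid
#'
#' A rectangular table extracted from a full-text article: a caption, a
#' character matrix of cells, and the set of footnote-mark characters
#' that may decorate cell payloads. Footnote marks are declared, not
#' auto-detected; the renderer that produced the table knows which
#' characters it used (typically Unicode superscript letters).
#'
#' @param caption Table caption (may be `""`).
#' @param cells Character matrix (rows x columns).
#' @param footnote_marks Character vector of single-character marks.
#' @param origin Optional table identifier.
#' @return An object of class `table_grid`.
#' @export
table_grid <- function(caption, cells, footnote_marks = character(),
                       origin = NA_character_) {
  stopifnot(is.character(caption), length(caption) == 1L)
  if (is.list(cells)) {
    lens <- lengths(cells)
    if (length(unique(lens)) > 1L) {
      stop("ragged table: all rows must have the same number of cells",
           call. = FALSE)
    }
    cells <- matrix(unlist(cells), nrow = length(cells), byrow = TRUE)
  }
  stopifnot(is.matrix(cells), is.character(cells) || length(cells) == 0L)
  stopifnot(all(nchar(footnote_marks) == 1L))
  structure(list(caption = caption, cells = cells,
                 footnote_marks = unique(footnote_marks),
                 origin = as.character(origin)),
            class = "table_grid")
}

collapse_ws <- function(x) {
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Parse a MEDLINE-style abstract XML document
#'
#' Finds the `Abstract` element, strips any inline markup, decodes XML
#' character entities (so `A-&gt;T` becomes `A->T`), and collapses
#' whitespace runs to single spaces.
#'
#' @param xml_text A string of well-formed XML containing an `Abstract`
#'   element.
#' @return An abstract [document_section()].
#' @export
parse_abstract_xml <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text),
                  error = function(e) stop("malformed abstract XML: ",
                                           conditionMessage(e), call. = FALSE))
  node <- xml2::xml_find_first(doc, "//Abstract|//AbstractText|//abstract")
  if (inherits(node, "xml_missing")) {
    stop("no abstract element found in document", call. = FALSE)
  }
  document_section("abstract", collapse_ws(xml2::xml_text(node)))
}

#' Parse a simplified JATS-style full-text XML document
#'
#' Recognized elements: `article` root, `body` with `p` paragraphs
#' (grouped into one body section), `table-wrap` with `caption` and
#' `table`/`tr`/`td|th` rows, and an optional `footnote-marks` attribute
#' on `table-wrap` declaring mark characters. Reference lists
#' (`ref-list`) are excluded. Unrecognized elements are ignored with a
#' warning. A document whose body holds no paragraph text is flagged
#' `body_missing` (title-and-abstract-only articles).
#'
#' @param xml_text A string of well-formed XML.
#' @return A list with `sections` (tibble of body sections), `tables`
#'   (list of [table_grid()]), and `body_missing` (logical).
#' @export
parse_fulltext_xml <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text),
                  error = function(e) stop("malformed full-text XML: ",
                                           conditionMessage(e), call. = FALSE))
  known <- c("article", "front", "abstract", "body", "sec", "p",
             "table-wrap", "caption", "table", "tr", "td", "th",
             "supplementary-material", "ref-list", "ref", "title")
  seen <- unique(xml2::xml_name(xml2::xml_find_all(doc, "//*")))
  unknown <- setdiff(seen, known)
  if (length(unknown)) {
    warning("ignoring unrecognized element(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }

  paras <- xml2::xml_find_all(
    doc, "//body//p[not(ancestor::table-wrap) and not(ancestor::ref-list)]")
  para_text <- collapse_ws(vapply(paras, xml2::xml_text, character(1)))
  para_text <- para_text[nzchar(para_text)]
  body_missing <- length(para_text) == 0L
  sections <- if (body_missing) {
    tibble::tibble(source_kind = character(), text = character(),
                   origin = character())
  } else {
    document_section("body", paste(para_text, collapse = " "))
  }

  wraps <- xml2::xml_find_all(doc, "//table-wrap")
  tables <- lapply(wraps, function(w) {
    cap <- xml2::xml_find_first(w, ".//caption")
    caption <- if (inherits(cap, "xml_missing")) "" else
      collapse_ws(xml2::xml_text(cap))
    rows <- xml2::xml_find_all(w, ".//tr")
    cells <- lapply(rows, function(r) {
      collapse_ws(vapply(xml2::xml_find_all(r, "./td|./th"),
                         xml2::xml_text, character(1)))
    })
    cells <- cells[lengths(cells) > 0L]
    marks <- xml2::xml_attr(w, "footnote-marks")
    marks <- if (is.na(marks)) character() else
      strsplit(marks, "", fixed = TRUE)[[1]]
    if (!length(cells)) {
      return(table_grid(caption, matrix(character(), 0, 0), marks,
                        origin = xml2::xml_attr(w, "id")))
    }
    table_grid(caption, cells, marks, origin = xml2::xml_attr(w, "id"))
  })

  list(sections = sections, tables = tables, body_missing = body_missing)
}

#' Linearize a table grid into a scannable section
#'
#' Emits the caption first, then the cells in row-major order, joined by
#' tab characters. The tab separator cannot occur inside any supported
#' variant mention, so linearization never creates or destroys mentions.
#' Declared footnote-mark characters are stripped from cell payloads
#' before joining (so `1704_1705delᵉAGᵇ` with marks
#' \{ᵉ,ᵇ\} yields `1704_1705delAG`).
#'
#' @param grid A [table_grid()].
#' @return A table [document_section()].
#' @export
linearize_table <- function(grid) {
  stopifnot(inherits(grid, "table_grid"))
  cells <- as.character(t(grid$cells))
  if (length(grid$footnote_marks)) {
    cls <- paste0("[", paste(grid$footnote_marks, collapse = ""), "]")
    cells <- gsub(cls, "", cells)
  }
  parts <- c(grid$caption, cells)
  parts <- parts[nzchar(parts)]
  document_section("table", paste(parts, collapse = "\t"),
                   origin = grid$origin)
}

#' Read a delimited supplementary file into a section
#'
#' Field boundaries are preserved as tab separators in the section text;
#' quoting follows the named dialect (CSV fields may carry embedded,
#' quoted commas). An empty file yields an empty supplement section.
#'
#' @param text Raw file content as a single string, or a path via
#'   `file`.
#' @param dialect `"tsv"` or `"csv"`.
#' @param file Optional path to read instead of `text`.
#' @param origin Provenance label, defaulting to `file` when given.
#' @return A supplement [document_section()].
#' @export
read_delimited_supplement <- function(text = NULL, dialect = c("tsv", "csv"),
                                      file = NULL, origin = NULL) {
  dialect <- match.arg(dialect)
  if (!is.null(file)) {
    raw <- readBin(file, what = "raw", n = file.size(file))
    txt <- rawToChar(raw)
    Encoding(txt) <- "UTF-8"
    if (is.null(origin)) origin <- basename(file)
  } else {
    txt <- text
  }
  bad <- !validUTF8(txt)
  if (any(bad)) {
    off <- which(!validUTF8(vapply(seq_len(nchar(txt, type = "bytes")),
                                   function(i) substr(txt, 1, i), "")))[1]
    stop("undecodable bytes in supplement near offset ", off, call. = FALSE)
  }
  if (is.null(origin)) origin <- NA_character_
  if (!nzchar(trimws(txt))) {
    return(document_section("supplement", "", origin = origin))
  }
  if (dialect == "csv") {
    rows <- utils::read.csv(text = txt, header = FALSE,
                            colClasses = "character",
                            blank.lines.skip = TRUE)
    lines <- apply(rows, 1L, paste, collapse = "\t")
    txt <- paste(lines, collapse = "\n")
  } else {
    txt <- gsub("\r\n?", "\n", txt)
    txt <- sub("\n+$", "", txt)
  }
  document_section("supplement", txt, origin = origin)
}

#' Read a pre-extracted PDF text file into a section
#'
#' The package never parses PDF bytes; full-text articles available only
#' as PDF are supplied as pre-extracted plain text.
#'
#' @param text Plain text content.
#' @param origin Provenance label.
#' @return A pdf_text [document_section()].
#' @export
pdf_text_section <- function(text, origin = NA_character_) {
  document_section("pdf_text", text, origin = origin)
}

#' Read an article bundle from a manifest entry
#'
#' A corpus manifest is a JSON array of entries with fields `doc_id` and
#' `sources`, where each source lists `source_kind` and `path` (relative
#' to the manifest's directory). Abstract and full-text paths are parsed
#' as XML; supplements as TSV/CSV by extension; pdf_text as plain text.
#'
#' @param entry One manifest entry (a list).
#' @param dir Directory against which paths are resolved.
#' @return A [document_bundle()].
#' @export
read_bundle <- function(entry, dir = ".") {
  secs <- list()
  tabs <- list()
  for (src in entry$sources) {
    path <- file.path(dir, src$path)
    kind <- src$source_kind
    if (kind == "abstract") {
      secs[[length(secs) + 1L]] <-
        parse_abstract_xml(paste(readLines(path, encoding = "UTF-8",
                                           warn = FALSE), collapse = "\n"))
    } else if (kind == "body") {
      ft <- parse_fulltext_xml(paste(readLines(path, encoding = "UTF-8",
                                               warn = FALSE), collapse = "\n"))
      if (!ft$body_missing) secs[[length(secs) + 1L]] <- ft$sections
      for (g in ft$tables) {
        secs[[length(secs) + 1L]] <- linearize_table(g)
      }
    } else if (kind == "supplement") {
      dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
      secs[[length(secs) + 1L]] <-
        read_delimited_supplement(file = path, dialect = dialect)
    } else if (kind == "pdf_text") {
      secs[[length(secs) + 1L]] <-
        pdf_text_section(paste(readLines(path, encoding = "UTF-8",
                                         warn = FALSE), collapse = "\n"),
                         origin = basename(path))
    } else {
      stop("unknown source_kind in manifest: ", kind, call. = FALSE)
    }
  }
  sections <- if (length(secs)) dplyr::bind_rows(secs) else NULL
  document_bundle(entry$doc_id, sections)
}

#' Read a whole corpus from its manifest
#'
#' @param manifest_path Path to the JSON bundle manifest.
#' @return A list of [document_bundle()] objects, named by `doc_id`.
#' @export
read_corpus <- function(manifest_path) {
  entries <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  bundles <- lapply(entries, read_bundle, dir = dir)
  names(bundles) <- vapply(bundles, function(b) b$doc_id, character(1))
  bundles
}
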
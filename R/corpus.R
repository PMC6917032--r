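#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows distinct n row_number desc across all_of
#' @importFrom tibble tibble as_tibble
NULL

SECTION_LABELS <- c(
  "title", "abstract", "introduction", "methods",
  "results", "discussion", "other"
)

#' Normalize a free-text section label to the closed section vocabulary
#'
#' @param x character vector of raw section labels.
#' @return character vector drawn from the closed set `title`, `abstract`,
#'   `introduction`, `methods`, `results`, `discussion`, `other`.
#' @keywords internal
normalize_section_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "other"
  # common synonyms seen in section headers
  x[x %in% c("front", "article-title")] <- "title"
  x[x %in% c("abstract", "abs")] <- "abstract"
  x[grepl("^intro", x)] <- "introduction"
  x[grepl("^(method|material)", x)] <- "methods"
  x[grepl("^result", x)] <- "results"
  x[grepl("^(discussion|conclu)", x)] <- "discussion"
  x[!x %in% SECTION_LABELS] <- "other"
  x
}

#' Recompute passage offsets for a passage table
#'
#' Document coordinates are 0-based half-open over the concatenation of
#' passages joined by a single newline; the newline is owned by the
#' preceding passage.
#'
#' @param passages tibble with at least `doc_id` and `text`, in passage order.
#' @return the same tibble with an `offset` column (re)computed.
#' @keywords internal
recompute_offsets <- function(passages) {
  passages |>
    group_by(.data$doc_id) |>
    mutate(offset = cumsum(c(0L, head(nchar(.data$text) + 1L, -1L)))) |>
    ungroup()
}

#' Assemble a document corpus tibble from passage data
#'
#' A corpus is a plain tibble with one row per passage and columns
#' `doc_id`, `section`, `offset`, `text`, `title`, `journal`, `year`,
#' `pmcid`. All downstream spans index the per-document string obtained by
#' joining a document's passages with single newlines (see
#' [corpus_text()]).
#'
#' @param doc_id character vector, one entry per passage.
#' @param section section labels (normalized to the closed vocabulary).
#' @param text passage text; must be non-empty.
#' @param title,journal,year,pmcid per-passage document metadata (recycled
#'   scalars are fine for a single document).
#' @return a corpus tibble.
#' @examples
#' corpus <- pgx_corpus(
#'   doc_id = c("d1", "d1"),
#'   section = c("title", "abstract"),
#'   text = c("Test", "Body.")
#' )
#' corpus$offset # 0 and 5
#' @export
pgx_corpus <- function(doc_id, section, text, title = NA_character_,
                       journal = NA_character_, year = NA_integer_,
                       pmcid = NA_character_) {
  n <- length(text)
  if (length(doc_id) == 1) doc_id <- rep(doc_id, n)
  stopifnot(length(doc_id) == n)
  out <- tibble(
    doc_id = as.character(doc_id),
    section = normalize_section_label(section),
    text = as.character(text),
    title = as.character(title),
    journal = as.character(journal),
    year = as.integer(year),
    pmcid = as.character(pmcid)
  )
  if (any(is.na(out$text) | out$text == "")) {
    stop("corpus passages must have non-empty text", call. = FALSE)
  }
  out <- recompute_offsets(out)
  out[, c("doc_id", "section", "offset", "text",
          "title", "journal", "year", "pmcid")]
}

#' Reconstruct full document text from a corpus
#'
#' @param corpus a corpus tibble (see [pgx_corpus()]).
#' @return tibble with one row per document: `doc_id`, `text`; `text` is
#'   the newline-joined passage concatenation that all spans index.
#' @export
corpus_text <- function(corpus) {
  corpus |>
    group_by(.data$doc_id) |>
    summarise(text = paste(.data$text, collapse = "\n"), .groups = "drop")
}

#' Read documents from BioC XML or a plain passage TSV
#'
#' @param path input file path.
#' @param format `"bioc"` (BioC XML) or `"plain_tsv"` (columns `doc_id`,
#'   `section`, `text` and optional `title`, `journal`, `year`, `pmcid`).
#' @return a corpus tibble; empty input yields a zero-row corpus.
#' @details Passage-level section labels are taken from the `section` infon,
#'   falling back to the `type` infon; unknown labels map to `"other"`.
#'   Offsets are recomputed on read so document coordinates are always
#'   0-based half-open over newline-joined passages.
#' @export
read_documents <- function(path, format = c("bioc", "plain_tsv")) {
  format <- match.arg(format)
  if (format == "plain_tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    if (nrow(df) == 0) return(empty_corpus())
    for (col in c("title", "journal", "year", "pmcid")) {
      if (!col %in% names(df)) df[[col]] <- NA_character_
    }
    corpus <- pgx_corpus(df$doc_id, df$section, df$text,
                         df$title, df$journal, as.integer(df$year), df$pmcid)
  } else {
    corpus <- read_bioc(path)
  }
  check_no_duplicate_docs(corpus)
  corpus
}

empty_corpus <- function() {
  pgx_corpus(character(), character(), character())[0, ]
}

check_no_duplicate_docs <- function(corpus) {
  # a document's passages must be contiguous rows; a doc_id reappearing
  # after another document indicates a duplicate document record
  ids <- rle(corpus$doc_id)$values
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate doc_id in document file: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  invisible(corpus)
}

read_bioc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed BioC XML in '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  documents <- xml2::xml_find_all(doc, ".//document")
  if (length(documents) == 0) return(empty_corpus())
  rows <- purrr::map(documents, function(d) {
    id <- xml2::xml_text(xml2::xml_find_first(d, "./id"))
    if (is.na(id) || id == "") {
      stop("malformed BioC document: missing <id>", call. = FALSE)
    }
    doc_infons <- bioc_infons(d)
    passages <- xml2::xml_find_all(d, "./passage")
    if (length(passages) == 0) {
      stop("malformed BioC document '", id, "': no passages", call. = FALSE)
    }
    purrr::map(passages, function(p) {
      infons <- bioc_infons(p)
      text <- xml2::xml_text(xml2::xml_find_first(p, "./text"))
      if (is.na(text)) {
        stop("malformed BioC passage in document '", id, "': missing <text>",
             call. = FALSE)
      }
      tibble(
        doc_id = id,
        section = infons[["section"]] %||% infons[["type"]] %||% "other",
        text = text,
        title = doc_infons[["title"]] %||% NA_character_,
        journal = doc_infons[["journal"]] %||% NA_character_,
        year = doc_infons[["year"]] %||% NA_character_,
        pmcid = doc_infons[["pmcid"]] %||% NA_character_
      )
    }) |> bind_rows()
  }) |> bind_rows()
  pgx_corpus(rows$doc_id, rows$section, rows$text,
             rows$title, rows$journal, suppressWarnings(as.integer(rows$year)),
             rows$pmcid)
}

bioc_infons <- function(node) {
  infons <- xml2::xml_find_all(node, "./infon")
  vals <- xml2::xml_text(infons)
  names(vals) <- xml2::xml_attr(infons, "key")
  as.list(vals)
}

#' Write documents to BioC XML or a plain passage TSV
#'
#' Round-trips with [read_documents()]: reading a written file reproduces
#' the input corpus exactly, and writing the same corpus twice is
#' byte-stable.
#'
#' @param corpus a corpus tibble.
#' @param path output file path.
#' @param format `"bioc"` or `"plain_tsv"`.
#' @return `path`, invisibly.
#' @export
write_documents <- function(corpus, path, format = c("bioc", "plain_tsv")) {
  format <- match.arg(format)
  if (format == "plain_tsv") {
    readr::write_tsv(
      corpus[, c("doc_id", "section", "text", "title", "journal", "year", "pmcid")],
      path
    )
    return(invisible(path))
  }
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", "pgxmine")
  for (id in unique(corpus$doc_id)) {
    rows <- corpus[corpus$doc_id == id, ]
    d <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(d, "id", id)
    meta <- rows[1, ]
    add_infon(d, "title", meta$title)
    add_infon(d, "journal", meta$journal)
    add_infon(d, "year", meta$year)
    add_infon(d, "pmcid", meta$pmcid)
    for (i in seq_len(nrow(rows))) {
      p <- xml2::xml_add_child(d, "passage")
      add_infon(p, "section", rows$section[i])
      xml2::xml_add_child(p, "offset", as.character(rows$offset[i]))
      xml2::xml_add_child(p, "text", rows$text[i])
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

add_infon <- function(node, key, value) {
  if (is.na(value)) return(invisible(NULL))
  child <- xml2::xml_add_child(node, "infon", as.character(value))
  xml2::xml_set_attr(child, "key", key)
  invisible(NULL)
}

ENTITY_CLASSES <- c("chemical", "gene", "variant", "star_allele")

#' Read entity annotation records from a four-column TSV
#'
#' The dialect is headerless and tab-separated with columns `doc_id`,
#' `entity_class`, `mention_text`, `normalized_id`. Records are offset-free:
#' they name the mention substring but not its position ([align_mentions()]
#' recovers positions). File order is preserved and records are not
#' deduplicated. An empty id column is read as `NA`, not `""`.
#'
#' @param path input TSV path.
#' @return tibble with columns `doc_id`, `entity_class`, `mention_text`,
#'   `normalized_id`.
#' @export
read_annotations <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0) return(empty_annotations())
  fields <- stringr::str_split(lines, stringr::fixed("\t"))
  n_fields <- lengths(fields)
  bad <- which(n_fields != 4)
  if (length(bad) > 0) {
    stop("annotation parse error at line ", bad[1], ": expected 4 tab-separated ",
         "fields, found ", n_fields[bad[1]], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- tibble(
    doc_id = m[, 1],
    entity_class = m[, 2],
    mention_text = m[, 3],
    normalized_id = dplyr::na_if(m[, 4], "")
  )
  bad_class <- !out$entity_class %in% c("chemical", "gene", "variant")
  if (any(bad_class)) {
    stop("annotation parse error at line ", which(bad_class)[1],
         ": unknown entity_class '", out$entity_class[which(bad_class)[1]], "'",
         call. = FALSE)
  }
  if (any(out$mention_text == "")) {
    stop("annotation parse error at line ", which(out$mention_text == "")[1],
         ": empty mention_text", call. = FALSE)
  }
  out
}

empty_annotations <- function() {
  tibble(doc_id = character(), entity_class = character(),
         mention_text = character(), normalized_id = character())
}

#' Write annotation records to the four-column TSV dialect
#'
#' @param annotations tibble as produced by [read_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  lines <- paste(
    annotations$doc_id,
    annotations$entity_class,
    annotations$mention_text,
    ifelse(is.na(annotations$normalized_id), "", annotations$normalized_id),
    sep = "\t"
  )
  readr::write_lines(lines, path)
  invisible(path)
}
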
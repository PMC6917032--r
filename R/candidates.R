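# tokens that commonly end with a period mid-sentence
SENTENCE_ABBREVIATIONS <- c(
  "i.e", "e.g", "vs", "cf", "ca", "al", "et", "fig", "figs", "eq",
  "dr", "mr", "mrs", "prof", "st", "no", "vol", "approx", "resp"
)

#' Build the allowed-chemical id set from an allowlist table
#'
#' The allowlist maps chemical ids (e.g. MeSH) to preferred names and
#' `|`-separated category labels. Category exclusion (e.g. amino acids,
#' nucleotides, metals — biological molecules that are not relevant drugs)
#' is applied here, when the allowed set is built, not per mention.
#'
#' @param allowlist tibble with columns `mesh_id`, `name`, `categories`
#'   (see [read_chemical_allowlist()]).
#' @param excluded_categories character vector of category names to drop.
#' @return character vector of allowed chemical ids.
#' @export
build_chemical_allowlist <- function(allowlist, excluded_categories = character()) {
  cats <- stringr::str_split(dplyr::coalesce(allowlist$categories, ""), "\\|")
  excluded <- tolower(excluded_categories)
  keep <- purrr::map_lgl(cats, function(cc) {
    !any(tolower(trimws(cc)) %in% excluded)
  })
  unique(allowlist$mesh_id[keep])
}

#' Read a chemical allowlist TSV (`mesh_id`, `name`, `categories`)
#'
#' @param path file path; tab-separated with a header row.
#' @return tibble with the three columns.
#' @export
read_chemical_allowlist <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Filter chemical mentions to the allowed drug list
#'
#' Chemical mentions survive iff their normalized id is in the allowed set
#' and their text has at least `min_length` characters (short tokens such
#' as `"ATP"` are dominated by tagging noise). Non-chemical rows pass
#' through untouched.
#'
#' @param mentions mention tibble.
#' @param allowed_ids allowed chemical id set (see
#'   [build_chemical_allowlist()]).
#' @param min_length minimum mention length in characters (default 4).
#' @return filtered mention tibble.
#' @export
filter_chemicals <- function(mentions, allowed_ids, min_length = 4L) {
  stopifnot(min_length >= 1)
  is_chem <- mentions$entity_class == "chemical"
  ok <- !is_chem |
    (!is.na(mentions$normalized_id) &
       mentions$normalized_id %in% allowed_ids &
       nchar(mentions$mention_text) >= min_length)
  mentions[ok, , drop = FALSE]
}

#' Segment corpus passages into sentences
#'
#' An abbreviation-aware splitter: a run of `.`, `!` or `?` ends a
#' sentence when followed by whitespace and a letter, digit or
#' opening quote/bracket, unless the preceding token is a known
#' abbreviation (`i.e.`, `et al.`, `Fig.`, ...) or a single-letter
#' initial. Sentences never cross passage boundaries and inherit their
#' passage's section label.
#'
#' @param corpus a corpus tibble.
#' @return tibble with columns `doc_id`, `sentence_id`, `section`,
#'   `start`, `end` (document coordinates, 0-based half-open), `text`.
#' @export
segment_sentences <- function(corpus) {
  if (nrow(corpus) == 0) return(empty_sentences())
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    spans <- split_sentence_spans(corpus$text[i])
    if (nrow(spans) == 0) return(NULL)
    tibble(
      doc_id = corpus$doc_id[i],
      section = corpus$section[i],
      start = corpus$offset[i] + spans$start,
      end = corpus$offset[i] + spans$end,
      text = spans$text
    )
  }) |> bind_rows()
  if (nrow(rows) == 0) return(empty_sentences())
  rows |>
    arrange(.data$doc_id, .data$start) |>
    group_by(.data$doc_id) |>
    mutate(sentence_id = row_number()) |>
    ungroup() |>
    select("doc_id", "sentence_id", "section", "start", "end", "text")
}

empty_sentences <- function() {
  tibble(doc_id = character(), sentence_id = integer(), section = character(),
         start = integer(), end = integer(), text = character())
}

# sentence spans within one passage, passage-local 0-based half-open
split_sentence_spans <- function(text) {
  n <- nchar(text)
  if (n == 0 || !grepl("\\S", text)) {
    return(tibble(start = integer(), end = integer(), text = character()))
  }
  punct <- stringr::str_locate_all(text, "[.!?]+")[[1]]
  breaks <- integer(0)
  for (k in seq_len(nrow(punct))) {
    e <- punct[k, 2] # 1-based inclusive end of the punctuation run
    if (e >= n) next
    rest <- substr(text, e + 1L, n)
    if (!grepl("^\\s", rest)) next
    # sentence-initial tokens are frequently lower-case in this domain
    # (rs IDs, drug names), so any letter/digit/opening mark may follow;
    # the abbreviation list guards against over-splitting
    follow <- stringr::str_match(rest, "^\\s*([\\S])")[1, 2]
    if (is.na(follow) || !grepl("^[\\p{L}0-9(\"'\\[]$", follow, perl = TRUE)) next
    head_txt <- substr(text, 1L, e)
    prev_tok <- stringr::str_match(head_txt, "([A-Za-z]+(?:\\.[A-Za-z]+)*)[.!?]+$")[1, 2]
    if (!is.na(prev_tok)) {
      if (tolower(prev_tok) %in% SENTENCE_ABBREVIATIONS) next
      if (nchar(prev_tok) == 1 && grepl("[A-Z]", prev_tok)) next
    }
    breaks <- c(breaks, e)
  }
  bounds <- c(0L, breaks, n) # 0-based half-open sentence chunks
  out <- purrr::map(seq_len(length(bounds) - 1L), function(i) {
    s <- bounds[i]
    e <- bounds[i + 1L]
    chunk <- substr(text, s + 1L, e)
    lead <- nchar(stringr::str_extract(chunk, "^\\s*"))
    trail <- nchar(stringr::str_extract(chunk, "\\s*$"))
    s2 <- s + lead
    e2 <- e - trail
    if (e2 <= s2) return(NULL)
    tibble(start = s2, end = e2, text = substr(text, s2 + 1L, e2))
  }) |> bind_rows()
  out
}

#' Compile a pharmacogenomic keyword list into a matching regex
#'
#' Keywords match whole words, case-insensitively; a trailing `*` marks a
#' stem that matches any word with that prefix (`metaboli*` covers
#' metabolism, metabolizer, ...).
#'
#' @param keywords character vector of keywords/stems (see
#'   [read_term_list()]).
#' @return a single regex string, or `NA` if the list is empty.
#' @export
compile_keyword_pattern <- function(keywords) {
  keywords <- keywords[keywords != ""]
  if (length(keywords) == 0) return(NA_character_)
  parts <- vapply(keywords, function(k) {
    if (endsWith(k, "*")) {
      paste0("\\b", escape_regex(sub("\\*$", "", k)), "\\w*")
    } else {
      paste0("\\b", escape_regex(k), "\\b")
    }
  }, character(1), USE.NAMES = FALSE)
  paste0("(?i)(?:", paste(parts, collapse = "|"), ")")
}

#' Attach mentions to the sentences that contain them
#'
#' @param sentences sentence tibble from [segment_sentences()].
#' @param mentions mention tibble (document coordinates).
#' @return the mentions with sentence columns (`sentence_id`, sentence
#'   `section`, `sentence_start`, `sentence_end`, `sentence_text`) joined
#'   on span containment; mentions crossing sentence boundaries are
#'   dropped.
#' @export
attach_mentions <- function(sentences, mentions) {
  joined <- dplyr::inner_join(
    mentions,
    sentences |>
      dplyr::rename(sentence_start = "start", sentence_end = "end",
                    sentence_text = "text", sentence_section = "section"),
    by = "doc_id", relationship = "many-to-many"
  )
  filter(joined,
         .data$start >= .data$sentence_start,
         .data$end <= .data$sentence_end)
}

#' Select candidate chemical-variant sentence pairs
#'
#' A sentence is eligible iff it contains at least one surviving chemical
#' mention and one surviving variant mention, and either contains a
#' pharmacogenomic keyword or mentions a dbSNP-kind variant (specific rs
#' IDs are strong pharmacogenomic signals on their own, so they bypass
#' the keyword gate; set `exempt_kinds` to also exempt star alleles).
#' Every (chemical, variant) cross-pair in an eligible sentence becomes
#' one candidate. Candidates where the variant is an rs ID or star allele
#' form `group1`; DNA/protein/other variants form `group2`.
#'
#' @param sentences sentence tibble.
#' @param mentions classified mention tibble ([classify_variants()] must
#'   have been applied; chemical rows need `normalized_id`).
#' @param keywords keyword list (see [compile_keyword_pattern()]).
#' @param exempt_kinds variant kinds that bypass the keyword gate
#'   (default `"dbsnp"`).
#' @return candidate tibble, one row per (chemical, variant) pair, with
#'   sentence metadata, `chemical_*` and `variant_*` columns, and `group`.
#' @export
select_candidates <- function(sentences, mentions, keywords,
                              exempt_kinds = "dbsnp") {
  attached <- attach_mentions(sentences, mentions)
  chems <- filter(attached, .data$entity_class == "chemical")
  vars <- filter(attached,
                 .data$entity_class %in% c("variant", "star_allele"))
  if (nrow(chems) == 0 || nrow(vars) == 0) return(empty_candidates())
  pattern <- compile_keyword_pattern(keywords)
  pairs <- dplyr::inner_join(
    chems |>
      select("doc_id", "sentence_id", "sentence_section", "sentence_start",
             "sentence_end", "sentence_text",
             chemical_start = "start", chemical_end = "end",
             chemical_text = "mention_text", chemical_id = "normalized_id"),
    vars |>
      select("doc_id", "sentence_id",
             variant_start = "start", variant_end = "end",
             variant_text = "mention_text", variant_id = "variant_id",
             variant_kind = "variant_kind", rsid = "rsid", hgvs = "hgvs",
             gene_id = "gene_id"),
    by = c("doc_id", "sentence_id"), relationship = "many-to-many"
  )
  if (nrow(pairs) == 0) return(empty_candidates())
  has_kw <- if (is.na(pattern)) {
    rep(FALSE, nrow(pairs))
  } else {
    stringr::str_detect(pairs$sentence_text, pattern)
  }
  # sentence-level exemption: any exempt-kind variant in the sentence opens it
  exempt_sent <- vars |>
    group_by(.data$doc_id, .data$sentence_id) |>
    summarise(exempt = any(.data$variant_kind %in% exempt_kinds),
              .groups = "drop")
  pairs <- left_join(pairs, exempt_sent, by = c("doc_id", "sentence_id"))
  pairs <- filter(pairs, has_kw | .data$exempt)
  if (nrow(pairs) == 0) return(empty_candidates())
  pairs |>
    mutate(group = ifelse(.data$variant_kind %in% c("dbsnp", "star_allele"),
                          "group1", "group2")) |>
    select(-"exempt") |>
    arrange(.data$doc_id, .data$sentence_id,
            .data$chemical_start, .data$variant_start)
}

empty_candidates <- function() {
  tibble(
    doc_id = character(), sentence_id = integer(),
    sentence_section = character(), sentence_start = integer(),
    sentence_end = integer(), sentence_text = character(),
    chemical_start = integer(), chemical_end = integer(),
    chemical_text = character(), chemical_id = character(),
    variant_start = integer(), variant_end = integer(),
    variant_text = character(), variant_id = character(),
    variant_kind = character(), rsid = character(), hgvs = character(),
    gene_id = character(), group = character()
  )
}
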
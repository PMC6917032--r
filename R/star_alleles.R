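# Star-allele grammar: immediately after a gene mention (whitespace
# tolerated), an asterisk followed by a token that begins with a digit and
# may contain letters, digits and colons (colons capture HLA alleles).
# Additional alleles may follow, separated by whitespace, "/", ",", "and"
# or "or", each introduced by its own asterisk.
STAR_TOKEN_RE <- "^\\*([0-9][0-9A-Za-z:]*)"

#' Detect star alleles immediately after aligned gene mentions
#'
#' For each gene mention, the text just after the mention end is scanned
#' for `*<token>` where the token starts with a digit; continuation lists
#' (`CYP2C9*2/*3`, `CYP2D6 *1, *2 and *4`) yield one allele per token.
#' The normalized form is the gene name concatenated with `*` and the
#' allele label, whitespace removed; HLA-family genes are additionally
#' renormalized via [normalize_hla()]. Alleles duplicated at an identical
#' span are emitted once.
#'
#' @param corpus a corpus tibble.
#' @param mentions mention tibble from [align_mentions()]; only rows with
#'   `entity_class == "gene"` are scanned.
#' @return tibble with columns `doc_id`, `entity_class` (`"star_allele"`),
#'   `start`, `end` (span of the allele token, 0-based half-open),
#'   `mention_text` (the allele token), `normalized_id` (the normalized
#'   star allele, e.g. `"CYP2D6*2"`), `gene_name`, `gene_id`.
#' @examples
#' corpus <- pgx_corpus("d1", "abstract", "CYP2C9*2/*3 carriers need lower doses.")
#' genes <- tibble::tibble(
#'   doc_id = "d1", entity_class = "gene", start = 0L, end = 6L,
#'   mention_text = "CYP2C9", normalized_id = "1559", gene_id = NA_character_
#' )
#' find_star_alleles(corpus, genes)$normalized_id # "CYP2C9*2" "CYP2C9*3"
#' @export
find_star_alleles <- function(corpus, mentions) {
  genes <- filter(mentions, .data$entity_class == "gene")
  if (nrow(genes) == 0) return(empty_star_alleles())
  texts <- corpus_text(corpus)
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    text <- texts$text[texts$doc_id == g$doc_id]
    scan_star_alleles(text, g)
  }) |> bind_rows()
  if (nrow(out) == 0) return(empty_star_alleles())
  out |>
    distinct(.data$doc_id, .data$start, .data$end, .keep_all = TRUE) |>
    arrange(.data$doc_id, .data$start, .data$end)
}

empty_star_alleles <- function() {
  tibble(doc_id = character(), entity_class = character(),
         start = integer(), end = integer(), mention_text = character(),
         normalized_id = character(), gene_name = character(),
         gene_id = character())
}

# scan text after one gene mention for the star-allele list grammar
scan_star_alleles <- function(text, gene) {
  gene_name <- gene$mention_text
  pos <- gene$end # 0-based: first character after the mention
  rest <- substr(text, pos + 1L, nchar(text))
  # whitespace only is tolerated between the gene and the first "*"
  lead_ws <- stringr::str_extract(rest, "^\\s*")
  rest <- substr(rest, nchar(lead_ws) + 1L, nchar(rest))
  pos <- pos + nchar(lead_ws)
  alleles <- list()
  repeat {
    m <- stringr::str_match(rest, STAR_TOKEN_RE)
    if (is.na(m[1, 1])) break
    label <- m[1, 2]
    tok_start <- pos + 1L # skip the "*"
    tok_end <- tok_start + nchar(label)
    alleles[[length(alleles) + 1L]] <- tibble(
      doc_id = gene$doc_id,
      entity_class = "star_allele",
      start = tok_start,
      end = tok_end,
      mention_text = label,
      normalized_id = normalize_star_allele(gene_name, label),
      gene_name = gene_name,
      gene_id = gene$normalized_id
    )
    consumed <- nchar(m[1, 1])
    rest <- substr(rest, consumed + 1L, nchar(rest))
    pos <- pos + consumed
    # continuation: separators are whitespace, "/", ",", "and", "or",
    # and must be followed by another "*" to continue the list
    sep <- stringr::str_match(rest, "^(\\s*(?:/|,|\\band\\b|\\bor\\b)?\\s*)\\*")
    if (is.na(sep[1, 1])) break
    skip <- nchar(sep[1, 2])
    if (skip == 0) break # adjacency without a listed separator ends the list
    rest <- substr(rest, skip + 1L, nchar(rest))
    pos <- pos + skip
  }
  bind_rows(alleles)
}

#' Normalize a star allele from its gene name and allele label
#'
#' Concatenates gene name, `*` and allele label with all whitespace
#' removed; HLA-family genes (name beginning `HLA`, case-insensitive) are
#' renormalized with [normalize_hla()].
#'
#' @param gene_name gene symbol as mentioned (e.g. `"CYP2D6"`).
#' @param allele_label allele token (must begin with a digit).
#' @return normalized star allele string with exactly one `*`.
#' @export
normalize_star_allele <- function(gene_name, allele_label) {
  gene_name <- gsub("\\s+", "", gene_name)
  allele_label <- gsub("\\s+", "", allele_label)
  if (grepl("^hla", gene_name, ignore.case = TRUE)) {
    return(normalize_hla(gene_name, allele_label))
  }
  paste0(gene_name, "*", allele_label)
}

#' Renormalize an HLA allele label to colon-separated two-character fields
#'
#' HLA nomenclature separates numeric fields with colons but print forms
#' often run the digits together (`HLA-B*05701`). The label is stripped of
#' whitespace, colons and leading zeros, then colons are reinserted
#' between character pairs from the left, so `05701` becomes `57:01`. A
#' label of odd length after stripping keeps its final character as a
#' one-character field, with a warning (such labels are suspicious).
#'
#' @param gene_name HLA gene symbol (must start with `"HLA"`,
#'   case-insensitive).
#' @param allele_label raw allele label.
#' @return normalized string `gene_name*fields`; a label with no digits is
#'   returned unchanged with a warning.
#' @examples
#' normalize_hla("HLA-B", "05701") # "HLA-B*57:01"
#' normalize_hla("HLA-A", "3101") # "HLA-A*31:01"
#' @export
normalize_hla <- function(gene_name, allele_label) {
  stopifnot(grepl("^hla", gsub("\\s+", "", gene_name), ignore.case = TRUE))
  gene_name <- gsub("\\s+", "", gene_name)
  label <- gsub("[\\s:]+", "", allele_label, perl = TRUE)
  if (!grepl("[0-9]", label)) {
    warning("HLA allele label '", allele_label, "' contains no digits; ",
            "left unchanged", call. = FALSE)
    return(paste0(gene_name, "*", allele_label))
  }
  label <- sub("^0+", "", label)
  chars <- strsplit(label, "")[[1]]
  if (length(chars) %% 2 == 1 && length(chars) > 2) {
    warning("odd-length HLA allele label '", allele_label,
            "'; final character kept as a one-character field", call. = FALSE)
  }
  groups <- split(chars, ceiling(seq_along(chars) / 2))
  fields <- vapply(groups, paste, character(1), collapse = "")
  paste0(gene_name, "*", paste(fields, collapse = ":"))
}

#' Strip a suballele suffix from a normalized star allele
#'
#' Removes trailing alphabetic characters after the final digit run of
#' the allele label (`CYP3A5*3A` becomes `CYP3A5*3`), so suballeles
#' compare equal to their parent allele in knowledge-base lookups. HLA
#' alleles are returned unchanged: their colon fields are not suballeles.
#'
#' @param normalized normalized star allele string(s) (vectorised).
#' @return string(s) with any suballele suffix removed.
#' @examples
#' strip_suballele("CYP3A5*3A") # "CYP3A5*3"
#' strip_suballele("HLA-B*57:01") # unchanged
#' @export
strip_suballele <- function(normalized) {
  is_hla <- grepl("^hla", normalized, ignore.case = TRUE)
  out <- normalized
  out[!is_hla] <- sub("(\\*.*[0-9])[A-Za-z]+$", "\\1", out[!is_hla])
  out
}
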
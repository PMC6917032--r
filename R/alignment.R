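# Greek-letter equivalence: entity taggers translate text to ASCII, so a
# record may say "alpha" where the article prints the Greek character.
GREEK_LETTERS <- c(
  alpha = "α", beta = "β", gamma = "γ", delta = "δ",
  epsilon = "ε", zeta = "ζ", eta = "η", theta = "θ",
  iota = "ι", kappa = "κ", lambda = "λ", mu = "μ",
  nu = "ν", xi = "ξ", omicron = "ο", pi = "π",
  rho = "ρ", sigma = "σ", tau = "τ", upsilon = "υ",
  phi = "φ", chi = "χ", psi = "ψ", omega = "ω"
)

escape_regex <- function(x) {
  stringr::str_replace_all(x, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1")
}

#' Build an alignment pattern for one mention string
#'
#' Converts an offset-free mention substring into an ICU regular expression
#' that locates it in document text: the pattern is anchored at word
#' boundaries on both ends, any maximal whitespace run in the mention
#' matches any positive-length whitespace run in the text, each
#' spelled-out Greek letter name (alpha..omega, case-insensitive, both
#' letter cases) also matches the corresponding Greek character, and all
#' regex metacharacters (notably `*`, `(`, `)`, `+`, `.`) are literal.
#'
#' @param mention_text non-empty mention string as given by the annotator.
#' @return a single regex string for use with `stringr`.
#' @examples
#' p <- build_mention_pattern("TGF-alpha")
#' stringr::str_detect("TGF-α signalling", p) # TRUE
#' stringr::str_detect("CYP2D6x2", build_mention_pattern("CYP2D6*2")) # FALSE
#' @export
build_mention_pattern <- function(mention_text) {
  stopifnot(is.character(mention_text), length(mention_text) == 1,
            !is.na(mention_text), nchar(mention_text) > 0)
  # tokenize into whitespace runs, alphabetic runs, and single other chars
  tokens <- stringr::str_extract_all(
    mention_text, "\\s+|\\p{L}+|[^\\s\\p{L}]"
  )[[1]]
  pieces <- vapply(tokens, function(tok) {
    if (grepl("^\\s+$", tok)) return("\\s+")
    low <- tolower(tok)
    if (low %in% names(GREEK_LETTERS)) {
      ch <- GREEK_LETTERS[[low]]
      return(paste0("(?:(?i:", low, ")|[", ch, toupper(ch), "])"))
    }
    escape_regex(tok)
  }, character(1), USE.NAMES = FALSE)
  body <- paste(pieces, collapse = "")
  word_char <- "[\\p{L}\\p{N}_]"
  first <- substr(mention_text, 1, 1)
  last <- substr(mention_text, nchar(mention_text), nchar(mention_text))
  pre <- if (grepl("^[\\p{L}\\p{N}_]$", first, perl = TRUE)) {
    paste0("(?<!", word_char, ")")
  } else ""
  post <- if (grepl("^[\\p{L}\\p{N}_]$", last, perl = TRUE)) {
    paste0("(?!", word_char, ")")
  } else ""
  paste0(pre, body, post)
}

#' Align offset-free annotation records to exact character spans
#'
#' Each record's mention pattern (see [build_mention_pattern()]) is matched
#' against its document's text. Records are processed largest mention
#' first (ties broken lexicographically) and every match position is
#' accepted except spans strictly contained in an already-accepted span
#' that came from a longer mention, so no entity is mapped inside a larger
#' entity. Identical spans from different records are all kept. Records
#' whose pattern matches nowhere are dropped (not an error) and reported.
#'
#' @param corpus a corpus tibble (see [pgx_corpus()]).
#' @param annotations annotation tibble (`doc_id`, `entity_class`,
#'   `mention_text`, `normalized_id`).
#' @param quiet suppress the per-document unaligned-record message.
#' @return mention tibble with columns `doc_id`, `entity_class`, `start`,
#'   `end`, `mention_text`, `normalized_id`, `gene_id`, sorted by
#'   (`doc_id`, `start`, `end`); spans are 0-based half-open document
#'   coordinates. The dropped records are attached as attribute
#'   `"unaligned"`.
#' @export
align_mentions <- function(corpus, annotations, quiet = FALSE) {
  texts <- corpus_text(corpus)
  known <- annotations$doc_id %in% texts$doc_id
  if (!all(known)) {
    stop("annotations refer to unknown doc_id: ",
         paste(unique(annotations$doc_id[!known]), collapse = ", "),
         call. = FALSE)
  }
  per_doc <- split(annotations, annotations$doc_id)
  results <- purrr::imap(per_doc, function(recs, id) {
    align_one_document(texts$text[texts$doc_id == id], recs)
  })
  mentions <- bind_rows(purrr::map(results, "mentions"))
  unaligned <- bind_rows(purrr::map(results, "unaligned"))
  if (nrow(unaligned) > 0 && !quiet) {
    counts <- dplyr::count(unaligned, .data$doc_id)
    message("unaligned records dropped: ",
            paste0(counts$doc_id, " (", counts$n, ")", collapse = ", "))
  }
  if (nrow(mentions) == 0) mentions <- empty_mentions()
  mentions <- arrange(mentions, .data$doc_id, .data$start, .data$end)
  attr(mentions, "unaligned") <- unaligned
  mentions
}

empty_mentions <- function() {
  tibble(doc_id = character(), entity_class = character(),
         start = integer(), end = integer(), mention_text = character(),
         normalized_id = character(), gene_id = character())
}

align_one_document <- function(text, recs) {
  # largest-to-smallest with deterministic lexicographic tie-break
  ord <- order(-nchar(recs$mention_text),
               recs$mention_text, recs$entity_class, method = "radix")
  recs <- recs[ord, ]
  accepted <- list()
  acc_start <- integer(0)
  acc_end <- integer(0)
  acc_len <- integer(0)
  unaligned <- recs[0, ]
  for (i in seq_len(nrow(recs))) {
    mention <- recs$mention_text[i]
    len <- nchar(mention)
    pat <- build_mention_pattern(mention)
    loc <- stringr::str_locate_all(text, pat)[[1]]
    if (nrow(loc) == 0) {
      unaligned <- bind_rows(unaligned, recs[i, ])
      next
    }
    for (j in seq_len(nrow(loc))) {
      s <- unname(loc[j, 1]) - 1L # to 0-based half-open
      e <- unname(loc[j, 2])
      contained <- acc_len > len &
        acc_start <= s & acc_end >= e &
        !(acc_start == s & acc_end == e)
      if (any(contained)) next
      accepted[[length(accepted) + 1L]] <- tibble(
        doc_id = recs$doc_id[i],
        entity_class = recs$entity_class[i],
        start = s, end = e,
        mention_text = mention,
        normalized_id = recs$normalized_id[i],
        gene_id = NA_character_
      )
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
      acc_len <- c(acc_len, len)
    }
  }
  list(mentions = bind_rows(accepted), unaligned = unaligned)
}
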
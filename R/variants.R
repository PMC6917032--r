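# Three-letter to one-letter amino-acid codes (20 standard residues).
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V"
)
AA_ONE <- unname(AA_THREE_TO_ONE)

aa_from_three <- function(x) {
  key <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
  unname(AA_THREE_TO_ONE[key])
}

# tmVar-style component strings, e.g. "p|SUB|Q|192|R" or "c|SUB|G|93|A";
# an rsID may ride along as "...;RS#:662" or be the whole id ("rs662").
parse_component_id <- function(id) {
  if (is.na(id)) return(NULL)
  rs <- stringr::str_match(tolower(id), "rs#?:?\\s*([0-9]+)|\\brs([0-9]+)")
  rsid <- NA_character_
  if (!is.na(rs[1, 1])) {
    num <- ifelse(is.na(rs[1, 2]), rs[1, 3], rs[1, 2])
    rsid <- paste0("rs", num)
  }
  # component and rsID segments may ride in one id, ";"-separated
  segments <- strsplit(id, ";", fixed = TRUE)[[1]]
  comp_seg <- segments[grepl("|", segments, fixed = TRUE)]
  parts <- if (length(comp_seg) > 0) {
    strsplit(comp_seg[1], "|", fixed = TRUE)[[1]]
  } else character(0)
  comp <- NULL
  if (length(parts) >= 5 && toupper(parts[2]) == "SUB") {
    comp <- list(level = tolower(parts[1]), ref = parts[3],
                 pos = parts[4], alt = parts[5])
  }
  list(rsid = rsid, comp = comp)
}

classify_one_variant <- function(mention_text, normalized_id, entity_class) {
  if (identical(entity_class, "star_allele")) {
    return(list(variant_kind = "star_allele", rsid = NA_character_,
                hgvs = NA_character_))
  }
  parsed <- parse_component_id(normalized_id)
  rsid <- if (is.null(parsed)) NA_character_ else parsed$rsid
  text <- trimws(mention_text)

  # dbSNP identifier on the surface
  m <- stringr::str_match(text, stringr::regex("^rs([0-9]+)$", ignore_case = TRUE))
  if (!is.na(m[1, 1])) {
    return(list(variant_kind = "dbsnp", rsid = paste0("rs", m[1, 2]),
                hgvs = NA_character_))
  }

  # tmVar components resolve mentions whose surface form is prose; the
  # upstream parse is authoritative when present
  if (!is.null(parsed$comp)) {
    comp <- parsed$comp
    if (comp$level == "p" && comp$ref %in% AA_ONE && comp$alt %in% AA_ONE &&
        grepl("^[0-9]+$", comp$pos)) {
      return(list(variant_kind = "protein_sub", rsid = rsid,
                  hgvs = paste0("p.", comp$ref, comp$pos, comp$alt)))
    }
    if (comp$level %in% c("c", "g") && grepl("^[0-9]+$", comp$pos) &&
        grepl("^[ACGTacgt]$", comp$ref) && grepl("^[ACGTacgt]$", comp$alt)) {
      return(list(variant_kind = "dna_sub", rsid = rsid,
                  hgvs = paste0(comp$level, ".", comp$pos,
                                toupper(comp$ref), ">", toupper(comp$alt))))
    }
  }

  # protein substitution: one-letter (T790M / p.T790M) or three-letter
  m <- stringr::str_match(text, "^(?:p\\.)?([A-Z])([0-9]+)([A-Z])$")
  if (!is.na(m[1, 1]) && m[1, 2] %in% AA_ONE && m[1, 4] %in% AA_ONE) {
    return(list(variant_kind = "protein_sub", rsid = rsid,
                hgvs = paste0("p.", m[1, 2], m[1, 3], m[1, 4])))
  }
  m <- stringr::str_match(
    text, "^(?:p\\.)?([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$"
  )
  if (!is.na(m[1, 1])) {
    ref <- aa_from_three(m[1, 2])
    alt <- aa_from_three(m[1, 4])
    if (!is.na(ref) && !is.na(alt)) {
      return(list(variant_kind = "protein_sub", rsid = rsid,
                  hgvs = paste0("p.", ref, m[1, 3], alt)))
    }
  }

  # DNA substitution: c.93G>A, 93G>A, g.1234A>T
  m <- stringr::str_match(text, "^(?:([cg])\\.)?([0-9]+)([ACGTacgt])>([ACGTacgt])$")
  if (!is.na(m[1, 1])) {
    prefix <- ifelse(is.na(m[1, 2]), "c", tolower(m[1, 2]))
    return(list(variant_kind = "dna_sub", rsid = rsid,
                hgvs = paste0(prefix, ".", m[1, 3],
                              toupper(m[1, 4]), ">", toupper(m[1, 5]))))
  }

  # coordinate-bearing indels/duplications/frameshifts are kept as "other"
  # with the cleaned surface form as their hgvs
  m <- stringr::str_match(
    text, "^(?:[cgp]\\.)?[A-Za-z]{0,3}[0-9]+(?:_[0-9]+)?\\s*(?:del|ins|dup|fs)[A-Za-z0-9]*$"
  )
  if (!is.na(m[1, 1])) {
    return(list(variant_kind = "other", rsid = rsid,
                hgvs = gsub("\\s+", "", text)))
  }

  list(variant_kind = "other", rsid = rsid, hgvs = NA_character_)
}

#' Classify variant mentions and renormalize them to HGVS-like forms
#'
#' Entity taggers report variant mentions in many surface forms; this step
#' recognises dbSNP identifiers (`rs` + digits, case-insensitive), protein
#' substitutions in one-letter (`T790M`), three-letter (`Thr790Met`) and
#' prefixed (`p.T790M`) forms (emitted as one-letter HGVS `p.<ref><pos><alt>`),
#' and DNA substitutions (`c.93G>A`, `93G>A`, `g.1234A>T`, emitted with a
#' `c.`/`g.` prefix). When `normalized_id` carries an rsID or a
#' pipe-delimited component string (e.g. `p|SUB|Q|192|R`) from upstream
#' gene-context resolution, those components are used; prose mentions are
#' never re-parsed from surface text. Anything else is classified
#' `"other"` (coordinate-bearing indels keep their surface form as hgvs).
#'
#' @param mentions mention tibble; rows with `entity_class` of `"variant"`
#'   or `"star_allele"` are classified, other rows pass through with
#'   `variant_kind` `NA`.
#' @return the input with added columns `variant_kind` (one of `dbsnp`,
#'   `dna_sub`, `protein_sub`, `star_allele`, `other`), `rsid`, `hgvs`,
#'   and `variant_id` (the preferred key: rsid, else normalized star
#'   allele, else hgvs, else mention text).
#' @examples
#' m <- tibble::tibble(
#'   doc_id = "d", entity_class = "variant", start = 0L, end = 5L,
#'   mention_text = c("Q192R", "rs12979860", "c.G>A"),
#'   normalized_id = c("rs662", NA, NA), gene_id = NA_character_
#' )
#' classify_variants(m)[, c("variant_kind", "rsid", "hgvs")]
#' @export
classify_variants <- function(mentions) {
  if (nrow(mentions) == 0) {
    return(mutate(mentions, variant_kind = character(0), rsid = character(0),
                  hgvs = character(0), variant_id = character(0)))
  }
  res <- purrr::pmap(
    list(mentions$mention_text, mentions$normalized_id, mentions$entity_class),
    function(text, id, cls) {
      if (!cls %in% c("variant", "star_allele")) {
        return(list(variant_kind = NA_character_, rsid = NA_character_,
                    hgvs = NA_character_))
      }
      classify_one_variant(text, id, cls)
    }
  )
  out <- mentions
  out$variant_kind <- purrr::map_chr(res, "variant_kind")
  out$rsid <- purrr::map_chr(res, "rsid")
  out$hgvs <- purrr::map_chr(res, "hgvs")
  out$variant_id <- dplyr::case_when(
    out$variant_kind == "star_allele" ~ out$normalized_id,
    !is.na(out$rsid) ~ out$rsid,
    !is.na(out$hgvs) ~ out$hgvs,
    TRUE ~ out$mention_text
  )
  out
}

#' Does a classified variant mention carry a specific coordinate?
#'
#' Mentions without a locatable position (such as `c.G>A`) cannot be
#' matched to a knowledge base and are filtered out. A mention is specific
#' iff it has an rsID, is a star allele, or its HGVS form contains a
#' positive integer position.
#'
#' @param mentions classified mention tibble (see [classify_variants()]).
#' @return logical vector, one entry per row.
#' @export
has_specific_coordinate <- function(mentions) {
  !is.na(mentions$rsid) |
    mentions$variant_kind %in% "star_allele" |
    (!is.na(mentions$hgvs) & stringr::str_detect(mentions$hgvs, "[1-9]"))
}

#' Drop variant mentions whose text is a known non-variant term
#'
#' Variant taggers confuse cell-line names and similar tokens (e.g.
#' `T47D`) with protein substitutions; an editable exclusion list removes
#' them by exact, case-insensitive match on the full mention text.
#'
#' @param mentions mention tibble.
#' @param exclusion_words character vector of excluded terms (see
#'   [read_term_list()]; a default starter set ships with the package).
#' @param quiet suppress the removal-count message.
#' @return the mentions with excluded rows removed.
#' @export
apply_exclusion_words <- function(mentions, exclusion_words, quiet = FALSE) {
  if (length(exclusion_words) == 0 || nrow(mentions) == 0) return(mentions)
  drop <- tolower(mentions$mention_text) %in% tolower(exclusion_words)
  if (!quiet && any(drop)) {
    message(sum(drop), " variant mention(s) removed by exclusion words")
  }
  mentions[!drop, , drop = FALSE]
}

#' Read a one-term-per-line config list
#'
#' Blank lines and `#` comments are ignored; surrounding whitespace is
#' trimmed.
#'
#' @param path file path.
#' @return character vector of terms.
#' @export
read_term_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines[lines != ""]
}
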
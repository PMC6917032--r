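# shared in-code fixtures: tiny documents and mention tables

one_doc_corpus <- function(text, doc_id = "d1", section = "abstract") {
  pgx_corpus(doc_id = doc_id, section = section, text = text)
}

mention_row <- function(doc_id = "d1", entity_class = "variant", start = 0L,
                        end = 1L, mention_text = "x",
                        normalized_id = NA_character_,
                        gene_id = NA_character_) {
  tibble::tibble(doc_id = doc_id, entity_class = entity_class,
                 start = as.integer(start), end = as.integer(end),
                 mention_text = mention_text, normalized_id = normalized_id,
                 gene_id = gene_id)
}

annotation_row <- function(doc_id = "d1", entity_class = "chemical",
                           mention_text = "warfarin",
                           normalized_id = NA_character_) {
  tibble::tibble(doc_id = doc_id, entity_class = entity_class,
                 mention_text = mention_text, normalized_id = normalized_id)
}

# independent naive scanner: all literal occurrences of `needle`
naive_occurrences <- function(haystack, needle) {
  out <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(needle, substr(haystack, from, nchar(haystack)),
                   fixed = TRUE)
    if (hit == -1) break
    out <- c(out, from + hit - 2L) # 0-based
    from <- from + hit + attr(hit, "match.length") - 1L
  }
  out
}

# a small labeled candidate set, lexically separable, built by hand
make_separable_labeled <- function(n_pos = 20, n_neg = 20, group = "group2") {
  chems <- c("warfarin", "codeine", "clozapine", "omeprazole")
  make_one <- function(i, label) {
    chem <- chems[(i %% length(chems)) + 1]
    var <- paste0("A", 100 + i, "T")
    if (label) {
      text <- paste0(var, " strongly increased ", chem, " clearance.")
      vs <- 0L
      cs <- nchar(var) + 20L
    } else {
      text <- paste0(var, " was catalogued while ", chem,
                     " appeared in another genotype arm.")
      vs <- 0L
      cs <- nchar(var) + 22L
    }
    tibble::tibble(
      doc_id = paste0("doc", i), sentence_id = 1L,
      sentence_section = "abstract", sentence_start = 0L,
      sentence_end = nchar(text), sentence_text = text,
      chemical_start = cs, chemical_end = cs + nchar(chem),
      chemical_text = chem, chemical_id = "MESH:D000001",
      variant_start = vs, variant_end = vs + nchar(var),
      variant_text = var, variant_id = paste0("p.", var),
      variant_kind = "protein_sub", rsid = NA_character_,
      hgvs = paste0("p.", var), gene_id = NA_character_,
      group = group, label = label
    )
  }
  dplyr::bind_rows(
    purrr::map(seq_len(n_pos), make_one, label = TRUE),
    purrr::map(seq_len(n_neg) + n_pos, make_one, label = FALSE)
  )
}
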
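test_that("chemical filtering enforces allowlist membership and length", {
  m <- dplyr::bind_rows(
    mention_row("d1", "chemical", 0, 3, "ATP", "MESH:D000255"),
    mention_row("d1", "chemical", 4, 12, "warfarin", "MESH:D014859"),
    mention_row("d1", "chemical", 13, 20, "sucrose", "MESH:D013395"),
    mention_row("d1", "variant", 21, 26, "Q192R", NA)
  )
  allowed <- c("MESH:D000255", "MESH:D014859")
  kept <- filter_chemicals(m, allowed)
  expect_equal(kept$mention_text, c("warfarin", "Q192R")) # ATP: too short
})

test_that("category exclusion removes ids when the allowlist is built", {
  allowlist <- tibble::tibble(
    mesh_id = c("M1", "M2", "M3"),
    name = c("drugA", "metalB", "drugC"),
    categories = c("drug", "drug|metal", "drug")
  )
  allowed <- build_chemical_allowlist(allowlist, excluded_categories = "metal")
  expect_setequal(allowed, c("M1", "M3"))
})

test_that("allowlist survival matches a set-membership oracle at scale", {
  ids <- paste0("M", 1:200)
  allowed <- paste0("M", 1:160)
  m <- dplyr::bind_rows(purrr::map(1:200, function(i) {
    mention_row("d1", "chemical", i, i + 8, paste0("chemical", i), ids[i])
  }))
  kept <- filter_chemicals(m, allowed)
  expect_equal(nrow(kept), sum(ids %in% allowed))
  expect_equal(nrow(kept), 160)
})

test_that("sentence segmentation splits plainly and spares abbreviations", {
  expect_equal(nrow(segment_sentences(one_doc_corpus("A study. B study."))), 2)
  one <- segment_sentences(one_doc_corpus("We varied i.e. dose levels."))
  expect_equal(nrow(one), 1)
  # curated fixture list
  cases <- list(
    list(text = "Dosing rose (see Fig. 2) over time. Outcomes were stable.",
         n = 2),
    list(text = "Smith et al. reported this. We confirmed it.", n = 2),
    list(text = "Values were 3.5 and 4.2 overall.", n = 1),
    list(text = "Dr. Jones enrolled patients. Analysis followed.", n = 2),
    list(text = "rs662 was typed. warfarin dose varied.", n = 2)
  )
  for (case in cases) {
    expect_equal(nrow(segment_sentences(one_doc_corpus(case$text))), case$n,
                 info = case$text)
  }
})

test_that("sentences stay within passages and carry section labels", {
  corpus <- pgx_corpus("d1", c("title", "results"),
                       c("A title. With two parts.", "One result."))
  s <- segment_sentences(corpus)
  expect_equal(s$section, c("title", "title", "results"))
  txt <- corpus_text(corpus)$text
  for (i in seq_len(nrow(s))) {
    expect_equal(substr(txt, s$start[i] + 1, s$end[i]), s$text[i])
  }
})

test_that("keyword patterns are whole-word with stem support", {
  p <- compile_keyword_pattern(c("dose", "metaboli*"))
  expect_true(stringr::str_detect("the dose was reduced", p))
  expect_true(stringr::str_detect("Dose escalation", p))
  expect_false(stringr::str_detect("overdosed", p))
  expect_true(stringr::str_detect("poor metabolizers", p))
  expect_true(stringr::str_detect("hepatic metabolism", p))
})

candidate_fixture <- function(text, mentions, keywords = c("response",
                                                           "metabolism")) {
  corpus <- one_doc_corpus(text)
  sentences <- segment_sentences(corpus)
  mentions <- classify_variants(mentions)
  select_candidates(sentences, mentions, keywords)
}

test_that("a dbSNP mention exempts the sentence from the keyword gate", {
  text <- "rs662 modulates clopidogrel activity."
  m <- dplyr::bind_rows(
    mention_row("d1", "variant", 0, 5, "rs662", "rs662"),
    mention_row("d1", "chemical", 16, 27, "clopidogrel", "MESH:C055162")
  )
  cand <- candidate_fixture(text, m, keywords = c("response"))
  expect_equal(nrow(cand), 1)
  expect_equal(cand$group, "group1")
})

test_that("no keyword and no rsID yields no candidates", {
  text <- "T790M was sequenced in tumors; erlotinib was given later."
  m <- dplyr::bind_rows(
    mention_row("d1", "variant", 0, 5, "T790M", NA),
    mention_row("d1", "chemical", 31, 40, "erlotinib", "MESH:D000069347")
  )
  cand <- candidate_fixture(text, m, keywords = c("response", "metabolism"))
  expect_equal(nrow(cand), 0)
})

test_that("eligible sentences produce the full chemical x variant cross product", {
  text <- "warfarin and codeine response differed by Q192R and rs662 status."
  m <- dplyr::bind_rows(
    mention_row("d1", "chemical", 0, 8, "warfarin", "MESH:D014859"),
    mention_row("d1", "chemical", 13, 20, "codeine", "MESH:D003061"),
    mention_row("d1", "variant", 42, 47, "Q192R", NA),
    mention_row("d1", "variant", 52, 57, "rs662", "rs662")
  )
  cand <- candidate_fixture(text, m)
  expect_equal(nrow(cand), 4)
  # group assignment partitions candidates by variant kind
  expect_equal(sum(cand$group == "group1"), 2) # the two rs662 pairs
  expect_equal(sum(cand$group == "group2"), 2) # the two Q192R pairs
})

test_that("every candidate sentence has a keyword or an rsID variant", {
  out <- generate_corpus(corpus_config(seed = 8))
  m <- align_mentions(out$corpus, out$annotations, quiet = TRUE)
  stars <- find_star_alleles(out$corpus, m)
  m <- dplyr::bind_rows(m, dplyr::select(
    stars, "doc_id", "entity_class", "start", "end", "mention_text",
    "normalized_id", "gene_id"
  ))
  m <- classify_variants(m)
  sentences <- segment_sentences(out$corpus)
  keywords <- read_term_list(pgx_extdata("pgx_keywords.txt"))
  cand <- select_candidates(sentences, m, keywords)
  pattern <- compile_keyword_pattern(keywords)
  ok <- stringr::str_detect(cand$sentence_text, pattern) |
    cand$variant_kind == "dbsnp"
  expect_true(all(ok))
  # group is a partition
  expect_true(all(cand$group %in% c("group1", "group2")))
})
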
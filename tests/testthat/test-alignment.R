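test_that("mention patterns treat Greek names, whitespace and metacharacters", {
  p <- build_mention_pattern("TGF-alpha")
  expect_true(stringr::str_detect("TGF-alpha signalling", p))
  expect_true(stringr::str_detect("TGF-α signalling", p))
  expect_false(stringr::str_detect("TGF-alphabet", p))

  p2 <- build_mention_pattern("CYP2D6*2")
  expect_true(stringr::str_detect("carriers of CYP2D6*2 allele", p2))
  expect_false(stringr::str_detect("CYP2D6x2", p2))

  # word boundaries on both ends
  p3 <- build_mention_pattern("rs662")
  expect_false(stringr::str_detect("rs6621", p3))
  expect_false(stringr::str_detect("xrs662", p3))
})

test_that("whitespace runs match any whitespace: enumerated acceptance", {
  # hand-written acceptance predicate for the "vitamin  K" example
  accepts <- function(s) {
    grepl("^vitamin[ \t\n]+K$", s)
  }
  p <- build_mention_pattern("vitamin  K")
  candidates <- c("vitamin K", "vitamin  K", "vitamin\nK", "vitamin\t K",
                  "vitaminK", "vitamin-K")
  for (s in candidates) {
    expect_equal(stringr::str_detect(s, paste0("^", p, "$")), accepts(s),
                 info = s)
  }
})

test_that("exact substrings align at their exact offsets", {
  corpus <- one_doc_corpus("PON1 Q192R affects paraoxonase.")
  ann <- dplyr::bind_rows(
    annotation_row("d1", "gene", "PON1", "5444"),
    annotation_row("d1", "variant", "Q192R", "rs662")
  )
  m <- align_mentions(corpus, ann, quiet = TRUE)
  expect_equal(m$start, c(0L, 5L))
  expect_equal(m$end, c(4L, 10L))
  expect_equal(m$entity_class, c("gene", "variant"))
})

test_that("a shorter mention beside (not inside) a longer one is kept", {
  corpus <- one_doc_corpus("epidermal growth factor receptor (EGFR)")
  ann <- dplyr::bind_rows(
    annotation_row("d1", "gene", "epidermal growth factor receptor", "1956"),
    annotation_row("d1", "gene", "EGFR", "1956")
  )
  m <- align_mentions(corpus, ann, quiet = TRUE)
  expect_equal(nrow(m), 2)
  # brute-force interval containment oracle
  strictly_inside <- function(a, b) {
    b[1] <= a[1] && a[2] <= b[2] && !(a[1] == b[1] && a[2] == b[2])
  }
  expect_false(strictly_inside(c(34, 38), c(0, 32)))
  expect_true(any(m$start == 34 & m$end == 38))
})

test_that("a mention strictly inside a longer mention is suppressed", {
  corpus <- one_doc_corpus("epidermal growth factor receptor binding")
  ann <- dplyr::bind_rows(
    annotation_row("d1", "gene", "epidermal growth factor receptor", "1956"),
    annotation_row("d1", "chemical", "growth factor", NA)
  )
  m <- align_mentions(corpus, ann, quiet = TRUE)
  expect_equal(nrow(m), 1)
  expect_equal(m$mention_text, "epidermal growth factor receptor")
})

test_that("all occurrences are annotated, matching a naive scanner", {
  text <- "interferon was given; interferon response varied."
  corpus <- one_doc_corpus(text)
  ann <- annotation_row("d1", "chemical", "interferon", "MESH:D016898")
  m <- align_mentions(corpus, ann, quiet = TRUE)
  expect_equal(m$start, naive_occurrences(text, "interferon"))
  expect_equal(nrow(m), 2)
})

test_that("records that match nowhere are dropped and reported, not fatal", {
  corpus <- one_doc_corpus("Nothing to see here.")
  ann <- annotation_row("d1", "chemical", "warfarin", "X")
  expect_message(m <- align_mentions(corpus, ann), "unaligned")
  expect_equal(nrow(m), 0)
  expect_equal(nrow(attr(m, "unaligned")), 1)
})

test_that("annotations for unknown documents are an error", {
  corpus <- one_doc_corpus("text here.")
  ann <- annotation_row("ghost", "chemical", "text", NA)
  expect_error(align_mentions(corpus, ann, quiet = TRUE), "unknown doc_id")
})

test_that("planted mentions are recovered exactly across seeds", {
  for (seed in c(2, 13)) {
    out <- generate_corpus(corpus_config(seed = seed))
    m <- align_mentions(out$corpus, out$annotations, quiet = TRUE)
    gt <- out$ground_truth$mentions
    hits <- dplyr::inner_join(
      gt, m, by = c("doc_id", "entity_class", "mention_text", "start", "end")
    )
    expect_equal(nrow(hits), nrow(gt))
    expect_equal(nrow(m), nrow(gt)) # no spurious extra matches either
  }
})

test_that("no accepted span is strictly inside a longer mention's span", {
  out <- generate_corpus(corpus_config(seed = 4))
  m <- align_mentions(out$corpus, out$annotations, quiet = TRUE)
  per_doc <- split(m, m$doc_id)
  for (d in per_doc) {
    n <- nrow(d)
    if (n < 2) next
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        inside <- d$start[j] <= d$start[i] && d$end[i] <= d$end[j] &&
          !(d$start[i] == d$start[j] && d$end[i] == d$end[j])
        longer <- nchar(d$mention_text[j]) > nchar(d$mention_text[i])
        expect_false(inside && longer)
      }
    }
  }
})

test_that("alignment is idempotent", {
  out <- generate_corpus(corpus_config(seed = 6, n_documents = 5,
                                       n_positive = 8, n_negative = 8))
  m1 <- align_mentions(out$corpus, out$annotations, quiet = TRUE)
  m2 <- align_mentions(out$corpus, out$annotations, quiet = TRUE)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})
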
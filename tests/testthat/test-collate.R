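test_that("sentence HTML escapes markup and bolds exactly two spans", {
  out <- render_sentence_html("A<B affects rs1 & drugX", c(18, 23), c(12, 15))
  expect_equal(out, "A&lt;B affects <b>rs1</b> &amp; <b>drugX</b>")
  # no markup characters: only the tags change
  plain <- render_sentence_html("warfarin dose and rs662", c(0, 8), c(18, 23))
  expect_equal(plain, "<b>warfarin</b> dose and <b>rs662</b>")
  # spans at the string edges stay well-formed
  edge <- render_sentence_html("ab cd", c(0, 2), c(3, 5))
  expect_equal(edge, "<b>ab</b> <b>cd</b>")
})

test_that("overlapping or out-of-bounds spans are errors", {
  expect_error(render_sentence_html("abcdef", c(0, 4), c(2, 6)), "overlap")
  expect_error(render_sentence_html("abc", c(0, 5), c(1, 2)), "bounds")
})

test_that("collation counts distinct papers and sorts deterministically", {
  rows <- tibble::tibble(
    pmid = c("1", "1", "2"),
    chemical_id = "M1", chemical_text = "warfarin",
    variant_id = "rs662", variant_kind = "dbsnp", gene_id = NA_character_
  )
  col <- collate_associations(rows)
  expect_equal(nrow(col), 1)
  expect_equal(col$paper_count, 2)
  expect_equal(col$n_rows, 3)
  expect_equal(nrow(collate_associations(rows[0, ])), 0)
})

test_that("collation matches a brute-force group-by on 1,000 rows", {
  set.seed(99)
  rows <- tibble::tibble(
    pmid = as.character(sample(1:120, 1000, replace = TRUE)),
    chemical_id = sample(paste0("M", 1:12), 1000, replace = TRUE),
    chemical_text = "x",
    variant_id = sample(paste0("rs", 1:15), 1000, replace = TRUE),
    variant_kind = "dbsnp",
    gene_id = sample(c(NA, "g1", "g2"), 1000, replace = TRUE)
  )
  col <- collate_associations(rows)
  # independent oracle: base-R aggregate over the same key
  key <- paste(rows$chemical_id, rows$variant_id,
               ifelse(is.na(rows$gene_id), "<NA>", rows$gene_id))
  oracle <- tapply(rows$pmid, key, function(p) length(unique(p)))
  got <- stats::setNames(
    col$paper_count,
    paste(col$chemical_id, col$variant_id,
          ifelse(is.na(col$gene_id), "<NA>", col$gene_id))
  )
  expect_equal(length(got), length(oracle))
  expect_equal(got[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE)
  expect_true(all(diff(col$paper_count) <= 0))
  expect_equal(sum(col$n_rows), nrow(rows))
})

test_that("compound associations unfold to one pair per chemical", {
  assoc <- tibble::tibble(chemical_ids = c("A;B", "C"),
                          variant_key = c("rs1", "rs2"))
  pairs <- unfold_compound_associations(assoc)
  expect_equal(nrow(pairs), 3)
  expect_setequal(paste(pairs$chemical_id, pairs$variant_key),
                  c("A rs1", "B rs1", "C rs2"))
  # counting oracle on a random table
  set.seed(7)
  multis <- sample(1:4, 20, replace = TRUE)
  tbl <- tibble::tibble(
    chemical_ids = vapply(multis, function(k) {
      paste(sample(LETTERS, k), collapse = ";")
    }, character(1)),
    variant_key = paste0("rs", 1:20)
  )
  expect_equal(nrow(unfold_compound_associations(tbl)), sum(multis))
})

test_that("knowledge-base flags honor star/rs equivalence and stripping", {
  table <- read_pharmgkb_table(pgx_extdata("synthetic_pharmgkb_snapshot.tsv"))
  assoc <- tibble::tibble(
    chemical_id = c("MESH:D016559", "MESH:D016559", "MESH:C106538"),
    chemical_text = c("tacrolimus", "tacrolimus", "abacavir"),
    variant_id = c("CYP3A5*3A", "rs9923231", "HLA-B*57:01"),
    variant_kind = c("star_allele", "dbsnp", "star_allele"),
    gene_id = NA_character_, paper_count = 1L, n_rows = 1L,
    pmids = list("1", "2", "3")
  )
  flagged <- annotate_pharmgkb(assoc, table)
  # CYP3A5*3A strips to CYP3A5*3, which tacrolimus is curated against
  expect_true(flagged$in_pharmgkb_association[1])
  # rs9923231 is equivalent to VKORC1*2 but tacrolimus is not its partner
  expect_true(flagged$in_pharmgkb_variant[2])
  expect_false(flagged$in_pharmgkb_association[2])
  expect_true(flagged$in_pharmgkb_association[3])
})

test_that("star alleles mapping to an rs ID are found under either key", {
  table <- list(
    chemical_map = tibble::tibble(mesh_id = "MESH:X", kb_chemical_id = "PA1"),
    associations = tibble::tibble(chemical_ids = "PA1",
                                  variant_key = "rs1057868"),
    star_rs = tibble::tibble(star_allele = "POR*28", rsid = "rs1057868")
  )
  assoc <- tibble::tibble(
    chemical_id = "MESH:X", chemical_text = "x", variant_id = "POR*28",
    variant_kind = "star_allele", gene_id = NA_character_,
    paper_count = 1L, n_rows = 1L, pmids = list("1")
  )
  flagged <- annotate_pharmgkb(assoc, table)
  expect_true(flagged$in_pharmgkb_association)
})

test_that("an empty knowledge base leaves all flags false", {
  table <- list(
    chemical_map = tibble::tibble(mesh_id = character(),
                                  kb_chemical_id = character()),
    associations = tibble::tibble(chemical_ids = character(),
                                  variant_key = character()),
    star_rs = tibble::tibble(star_allele = character(), rsid = character())
  )
  assoc <- tibble::tibble(
    chemical_id = "MESH:X", chemical_text = "x", variant_id = "rs1",
    variant_kind = "dbsnp", gene_id = NA_character_, paper_count = 1L,
    n_rows = 1L, pmids = list("1")
  )
  flagged <- annotate_pharmgkb(assoc, table)
  expect_false(any(flagged$in_pharmgkb_chemical, flagged$in_pharmgkb_variant,
                   flagged$in_pharmgkb_association))
})

test_that("association flags imply both element flags (monotonicity)", {
  out <- generate_corpus(corpus_config(seed = 12))
  lab <- out$labeled_candidates
  lab$score <- ifelse(lab$label, 0.9, 0.1)
  rows <- build_relation_rows(lab, out$corpus)
  col <- collate_associations(rows)
  table <- read_pharmgkb_table(pgx_extdata("synthetic_pharmgkb_snapshot.tsv"))
  flagged <- annotate_pharmgkb(col, table)
  expect_true(all(!flagged$in_pharmgkb_association |
                    (flagged$in_pharmgkb_chemical &
                       flagged$in_pharmgkb_variant)))
})
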
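test_that("featurization is deterministic and sees the surface path", {
  lab <- make_separable_labeled(n_pos = 2, n_neg = 2)
  f1 <- featurize(lab)
  f2 <- featurize(lab)
  expect_identical(f1$features, f2$features)
  # the trigger lemma between the entities appears as a path feature,
  # and the token after the chemical as a right-window feature
  expect_true("path:increased" %in% names(f1$features[[1]]))
  expect_true("cr:clearance" %in% names(f1$features[[1]]))
})

test_that("different chemical partners in one sentence get different paths", {
  text <- "warfarin response improved but codeine response did not with rs662."
  base <- tibble::tibble(
    doc_id = "d", sentence_id = 1L, sentence_section = "abstract",
    sentence_start = 0L, sentence_end = nchar(text), sentence_text = text,
    chemical_text = c("warfarin", "codeine"),
    chemical_start = c(0L, 31L), chemical_end = c(8L, 38L),
    chemical_id = "M", variant_start = 61L, variant_end = 66L,
    variant_text = "rs662", variant_id = "rs662", variant_kind = "dbsnp",
    rsid = "rs662", hgvs = NA_character_, gene_id = NA_character_,
    group = "group1"
  )
  f <- featurize(base)
  expect_false(identical(f$features[[1]], f$features[[2]]))
})

test_that("training on separable data recovers labels on held-out data", {
  lab <- make_separable_labeled(n_pos = 40, n_neg = 40)
  sp <- split_labeled(lab, prop = 0.8, seed = 3)
  model <- train_relation_model(sp$train, "group2", seed = 3)
  scored <- score_candidates(sp$test, model)
  expect_equal(scored$score >= 0.5, scored$label)
})

test_that("training errors name degenerate inputs", {
  lab <- make_separable_labeled(n_pos = 5, n_neg = 5)
  expect_error(train_relation_model(lab[lab$label, ], "group2", seed = 1),
               "negative")
  expect_error(train_relation_model(lab[!lab$label, ], "group2", seed = 1),
               "positive")
  expect_error(train_relation_model(lab[0, ], "group2", seed = 1), "no labeled")
})

test_that("training is deterministic given the seed", {
  lab <- make_separable_labeled(n_pos = 15, n_neg = 15)
  m1 <- train_relation_model(lab, "group2", seed = 42)
  m2 <- train_relation_model(lab, "group2", seed = 42)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$intercept, m2$intercept)
})

test_that("scores are sigmoid-linear with a vocabulary contract", {
  lab <- make_separable_labeled(n_pos = 10, n_neg = 10)
  model <- train_relation_model(lab, "group2", seed = 1)
  # a candidate with no in-vocabulary features scores sigmoid(intercept)
  blank <- lab[1, ]
  blank$features <- list(c("zzz:neverseen" = 1))
  s <- score_candidates(blank, model)
  expect_equal(s$score, 1 / (1 + exp(-model$intercept)))
  # out-of-vocabulary features do not change a score
  one <- featurize(lab[1, ])
  with_extra <- one
  with_extra$features[[1]] <- c(one$features[[1]], "zzz:neverseen" = 3)
  expect_equal(score_candidates(one, model)$score,
               score_candidates(with_extra, model)$score)
  expect_true(all(dplyr::between(score_candidates(lab, model)$score, 0, 1)))
})

test_that("group mismatch between model and candidates errors", {
  lab <- make_separable_labeled(n_pos = 5, n_neg = 5)
  model <- train_relation_model(lab, "group2", seed = 1)
  other <- dplyr::mutate(lab, group = "group1")
  expect_error(score_candidates(other, model), "different group")
})

test_that("thresholding uses >= and nests across thresholds", {
  scored <- tibble::tibble(score = c(0.74, 0.75, 0.76))
  expect_equal(nrow(apply_threshold(scored, 0.75)), 2)
  expect_equal(nrow(apply_threshold(scored, 0)), 3)
  expect_equal(nrow(apply_threshold(scored, 1)), 0)
  lab <- make_separable_labeled(n_pos = 20, n_neg = 20)
  model <- train_relation_model(lab, "group2", seed = 2)
  scored <- score_candidates(lab, model)
  prev <- NULL
  for (t in seq(0, 1, by = 0.05)) {
    acc <- apply_threshold(scored, t)
    if (!is.null(prev)) {
      expect_true(all(paste(acc$doc_id, acc$variant_text) %in%
                        paste(prev$doc_id, prev$variant_text)))
    }
    prev <- acc
  }
})

test_that("cancer-chemical filtering only touches DNA/protein variants", {
  cand <- tibble::tibble(
    chemical_id = c("MESH:CANCER", "MESH:CANCER", "MESH:SAFE"),
    variant_kind = c("protein_sub", "dbsnp", "protein_sub"),
    score = 0.9
  )
  kept <- filter_cancer_chemicals(cand, "MESH:CANCER")
  expect_equal(nrow(kept), 2)
  expect_false(any(kept$chemical_id == "MESH:CANCER" &
                     kept$variant_kind == "protein_sub"))
  expect_equal(nrow(filter_cancer_chemicals(cand, character())), 3)
})

test_that("evaluation reports the precision-recall tradeoff correctly", {
  lab <- make_separable_labeled(n_pos = 25, n_neg = 25)
  sp <- split_labeled(lab, prop = 0.8, seed = 5)
  model <- train_relation_model(sp$train, "group2", seed = 5)
  curve <- evaluate_model(model, sp$test)
  athalf <- pr_at_threshold(curve, 0.5)
  expect_equal(athalf$precision, 1)
  expect_equal(athalf$recall, 1)
  # recall is monotone non-increasing in threshold
  expect_true(all(diff(curve$recall[order(curve$threshold)]) <= 0))
  # precision is absent, not zero, when nothing is predicted
  top <- curve[curve$n_predicted == 0, ]
  if (nrow(top) > 0) expect_true(all(is.na(top$precision)))
  expect_error(evaluate_model(model, dplyr::mutate(sp$test, label = FALSE)),
               "no positive")
})

test_that("models round-trip through JSON serialization", {
  lab <- make_separable_labeled(n_pos = 8, n_neg = 8)
  model <- train_relation_model(lab, "group2", seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$weights, model$weights)
  expect_equal(back$intercept, model$intercept)
  expect_equal(score_candidates(lab, back)$score,
               score_candidates(lab, model)$score)
})

test_that("tidy and glance summarise a model", {
  lab <- make_separable_labeled(n_pos = 8, n_neg = 8)
  model <- train_relation_model(lab, "group2", seed = 9)
  td <- tidy(model)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), length(model$vocab) + 1)
  gl <- glance(model)
  expect_equal(gl$n, 16)
  expect_equal(gl$group, "group2")
})

test_that("the PR curve autoplot builds without error", {
  lab <- make_separable_labeled(n_pos = 10, n_neg = 10)
  model <- train_relation_model(lab, "group2", seed = 2)
  curve <- evaluate_model(model, lab)
  p <- ggplot2::autoplot(curve)
  expect_s3_class(p, "ggplot")
})
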
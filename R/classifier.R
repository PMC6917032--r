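# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

tokenize_with_spans <- function(text) {
  loc <- stringr::str_locate_all(text, "[\\p{L}\\p{N}_]+")[[1]]
  if (nrow(loc) == 0) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  tibble(
    token = tolower(stringr::str_sub(text, loc[, 1], loc[, 2])),
    start = loc[, 1] - 1L, # sentence-local 0-based half-open
    end = loc[, 2]
  )
}

featurize_one <- function(sentence_text, chem_span, var_span) {
  toks <- tokenize_with_spans(sentence_text)
  feats <- character(0)
  overlaps <- function(span) {
    toks$start < span[2] & toks$end > span[1]
  }
  in_chem <- overlaps(chem_span)
  in_var <- overlaps(var_span)
  outside <- !(in_chem | in_var)
  feats <- c(feats, paste0("bow:", toks$token[outside]))
  # surface path: tokens strictly between the two entity spans
  lo <- min(chem_span[2], var_span[2])
  hi <- max(chem_span[1], var_span[1])
  between <- toks$start >= lo & toks$end <= hi & outside
  feats <- c(feats, paste0("path:", toks$token[between]))
  feats <- c(feats, paste0("pathlen:", min(sum(between), 5L)))
  feats <- c(feats, if (chem_span[1] <= var_span[1]) "order:chem_first"
                    else "order:var_first")
  window_feats <- function(inside, prefix_l, prefix_r) {
    idx <- which(inside)
    if (length(idx) == 0) return(character(0))
    left <- toks$token[idx[1] - (2:1)[idx[1] - (2:1) >= 1]]
    right_idx <- idx[length(idx)] + 1:2
    right <- toks$token[right_idx[right_idx <= nrow(toks)]]
    c(paste0(prefix_l, left), paste0(prefix_r, right))
  }
  feats <- c(feats,
             window_feats(in_chem, "cl:", "cr:"),
             window_feats(in_var, "vl:", "vr:"))
  tab <- table(feats)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Featurize candidate relations for classification
#'
#' Produces sparse count features per candidate: a bag of lower-cased
#' sentence tokens outside the entities, the surface-path tokens lying
#' strictly between the chemical and variant mentions, a bucketed path
#' length, entity order, and two-token windows flanking each entity. The
#' surface path plays the role dependency paths play in classic relation
#' extractors: the words that syntactically link the pair usually lie
#' between them in biomedical prose.
#'
#' @param candidates candidate tibble from [select_candidates()].
#' @return the input with a list-column `features` of named count vectors.
#' @export
featurize <- function(candidates) {
  if (nrow(candidates) == 0) {
    candidates$features <- list()
    return(candidates)
  }
  candidates$features <- purrr::pmap(
    list(candidates$sentence_text,
         candidates$chemical_start - candidates$sentence_start,
         candidates$chemical_end - candidates$sentence_start,
         candidates$variant_start - candidates$sentence_start,
         candidates$variant_end - candidates$sentence_start),
    function(text, cs, ce, vs, ve) {
      featurize_one(text, c(cs, ce), c(vs, ve))
    }
  )
  candidates
}

feature_matrix <- function(features, vocab) {
  ij <- purrr::imap(features, function(f, i) {
    j <- match(names(f), vocab)
    keep <- !is.na(j)
    list(i = rep(i, sum(keep)), j = j[keep], x = unname(f[keep]))
  })
  Matrix::sparseMatrix(
    i = unlist(purrr::map(ij, "i")),
    j = unlist(purrr::map(ij, "j")),
    x = unlist(purrr::map(ij, "x")),
    dims = c(length(features), length(vocab))
  )
}

#' Train a relation classifier for one candidate group
#'
#' Fits an L2-regularized logistic regression (ridge, single fixed
#' penalty) on featurized labeled candidates. The fit is deterministic;
#' the seed only shuffles row order and is recorded in the model
#' metadata. The model stores its feature vocabulary, so scoring ignores
#' features never seen in training.
#'
#' @param labeled candidate tibble with a logical `label` column
#'   (negative findings are labeled `TRUE`: a sentence stating that a
#'   variant does not affect a drug is still a pharmacogenomic
#'   association worth curating).
#' @param group `"group1"` (rs ID / star-allele variants) or `"group2"`
#'   (DNA/protein variants).
#' @param seed integer seed.
#' @param lambda ridge penalty (default 0.01).
#' @return a `pgx_model` object.
#' @export
train_relation_model <- function(labeled, group = c("group1", "group2"),
                                 seed = 1L, lambda = 0.01) {
  group <- match.arg(group)
  if (nrow(labeled) == 0) stop("no labeled candidates supplied", call. = FALSE)
  if (!is.logical(labeled$label)) stop("label column must be logical", call. = FALSE)
  if (all(labeled$label)) {
    stop("training data contain no negative examples", call. = FALSE)
  }
  if (!any(labeled$label)) {
    stop("training data contain no positive examples", call. = FALSE)
  }
  labeled <- with_local_seed(seed, labeled[sample.int(nrow(labeled)), ])
  if (!"features" %in% names(labeled)) labeled <- featurize(labeled)
  vocab <- sort(unique(unlist(purrr::map(labeled$features, names))))
  x <- feature_matrix(labeled$features, vocab)
  y <- as.integer(labeled$label)
  # glmnet warns on very small classes; small fixtures are legitimate here
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE,
                   thresh = 1e-10, maxit = 1e6)
  )
  beta <- as.numeric(fit$beta[, 1])
  names(beta) <- vocab
  structure(
    list(
      group = group,
      intercept = as.numeric(fit$a0[1]),
      weights = beta,
      vocab = vocab,
      lambda = lambda,
      metadata = list(n = nrow(labeled), n_positive = sum(labeled$label),
                      seed = as.integer(seed),
                      trained = format(Sys.Date()))
    ),
    class = "pgx_model"
  )
}

#' @export
print.pgx_model <- function(x, ...) {
  cat("<pgx_model> relation classifier for", x$group, "\n")
  cat("  features:", length(x$vocab),
      " lambda:", x$lambda,
      " trained on n =", x$metadata$n, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a relation classifier into a term/weight table
#'
#' @param x a `pgx_model`.
#' @param ... unused.
#' @return tibble with `term` and `estimate`, intercept first, then terms
#'   by decreasing absolute weight.
#' @export
tidy.pgx_model <- function(x, ...) {
  out <- tibble(term = c("(Intercept)", names(x$weights)),
                estimate = c(x$intercept, unname(x$weights)))
  out[c(1L, 1L + order(-abs(x$weights))), ]
}

#' One-row model summary
#'
#' @param x a `pgx_model`.
#' @param ... unused.
#' @return tibble with group, n, n_positive, n_features, lambda, seed.
#' @export
glance.pgx_model <- function(x, ...) {
  tibble(group = x$group, n = x$metadata$n,
         n_positive = x$metadata$n_positive,
         n_features = length(x$vocab), lambda = x$lambda,
         seed = x$metadata$seed)
}

#' Score candidates with a trained relation classifier
#'
#' @param candidates candidate tibble (featurized or not) for the model's
#'   group; rows of another group are an error.
#' @param model a `pgx_model`.
#' @return the candidates with a `score` column of probabilities in
#'   \[0, 1\] (logistic sigmoid of the linear score).
#' @export
score_candidates <- function(candidates, model) {
  stopifnot(inherits(model, "pgx_model"))
  if (nrow(candidates) == 0) {
    candidates$score <- numeric(0)
    return(candidates)
  }
  if ("group" %in% names(candidates) &&
      !all(candidates$group == model$group)) {
    stop("candidates contain rows for a different group than the model (",
         model$group, ")", call. = FALSE)
  }
  if (!"features" %in% names(candidates)) candidates <- featurize(candidates)
  x <- feature_matrix(candidates$features, model$vocab)
  eta <- as.numeric(x %*% model$weights) + model$intercept
  candidates$score <- 1 / (1 + exp(-eta))
  candidates
}

#' Keep candidates scoring at or above a probability threshold
#'
#' @param scored candidate tibble with a `score` column.
#' @param threshold acceptance threshold (default 0.75); accepted iff
#'   `score >= threshold`.
#' @return the accepted candidates.
#' @export
apply_threshold <- function(scored, threshold = 0.75) {
  stopifnot("score" %in% names(scored))
  filter(scored, .data$score >= threshold)
}

#' Remove cancer-drug candidates paired with DNA/protein variants
#'
#' A cancer-associated chemical co-mentioned with a raw DNA or protein
#' change is usually a somatic tumour event, not a germline
#' pharmacogenomic association, so such pairs are dropped. Candidates
#' whose variant is an rs ID or star allele (group1) are never removed by
#' this rule.
#'
#' @param candidates candidate tibble.
#' @param cancer_chemical_ids chemical ids flagged as cancer-associated.
#' @return filtered candidates.
#' @export
filter_cancer_chemicals <- function(candidates, cancer_chemical_ids) {
  if (length(cancer_chemical_ids) == 0 || nrow(candidates) == 0) {
    return(candidates)
  }
  drop <- candidates$chemical_id %in% cancer_chemical_ids &
    candidates$variant_kind %in% c("dna_sub", "protein_sub")
  candidates[!drop, , drop = FALSE]
}

#' Stratified train/test split of labeled candidates
#'
#' @param labeled labeled candidate tibble.
#' @param prop training proportion (default 0.8).
#' @param seed integer seed for the shuffle.
#' @return list with `train` and `test` tibbles; the split is stratified
#'   by label.
#' @export
split_labeled <- function(labeled, prop = 0.8, seed = 1L) {
  idx <- with_local_seed(seed, {
    pos <- sample(which(labeled$label))
    neg <- sample(which(!labeled$label))
    n_pos <- round(length(pos) * prop)
    n_neg <- round(length(neg) * prop)
    list(train = c(pos[seq_len(n_pos)], neg[seq_len(n_neg)]),
         test = c(pos[-seq_len(n_pos)], neg[-seq_len(n_neg)]))
  })
  list(train = labeled[sort(idx$train), ], test = labeled[sort(idx$test), ])
}

#' Evaluate a relation classifier on held-out labeled candidates
#'
#' @param model a `pgx_model`.
#' @param held_out labeled candidate tibble.
#' @param thresholds probability thresholds to sweep; defaults to the
#'   sorted unique held-out scores plus 0 and the default cutoff 0.75.
#' @return a `pgx_pr_curve` tibble with `threshold`, `n_predicted`,
#'   `precision` (NA where no candidate is predicted positive), `recall`.
#' @export
evaluate_model <- function(model, held_out, thresholds = NULL) {
  if (!any(held_out$label)) {
    stop("held-out set contains no positive labels; recall is undefined",
         call. = FALSE)
  }
  scored <- score_candidates(held_out, model)
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0, 0.75, scored$score)))
  }
  rows <- purrr::map(thresholds, function(t) {
    pred <- scored$score >= t
    tp <- sum(pred & scored$label)
    tibble(
      threshold = t,
      n_predicted = sum(pred),
      precision = if (sum(pred) == 0) NA_real_ else tp / sum(pred),
      recall = tp / sum(scored$label)
    )
  }) |> bind_rows()
  class(rows) <- c("pgx_pr_curve", class(rows))
  rows
}

#' Precision/recall at a single threshold
#'
#' @param curve a `pgx_pr_curve` from [evaluate_model()].
#' @param threshold the operating threshold.
#' @return one-row tibble. When the exact threshold was not swept, the
#'   smallest swept threshold above it is used: with every observed score
#'   in the sweep, that threshold predicts the identical candidate set.
#' @export
pr_at_threshold <- function(curve, threshold = 0.75) {
  exact <- curve[curve$threshold == threshold, ]
  if (nrow(exact) > 0) return(exact[1, ])
  above <- curve[curve$threshold >= threshold, ]
  if (nrow(above) > 0) return(above[which.min(above$threshold), ])
  # every score is below the requested threshold: nothing is predicted
  tibble(threshold = threshold, n_predicted = 0L,
         precision = NA_real_, recall = 0)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall curve
#'
#' @param object a `pgx_pr_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pgx_pr_curve <- function(object, ...) {
  df <- object[!is.na(object$precision), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = "Relation classifier precision-recall") +
    ggplot2::theme_minimal()
}

#' Serialize a trained relation classifier to JSON
#'
#' @param model a `pgx_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pgx_model"))
  payload <- list(
    group = model$group,
    intercept = model$intercept,
    lambda = model$lambda,
    weights = as.list(model$weights),
    metadata = model$metadata
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a relation classifier from JSON
#'
#' @param path path written by [write_model()].
#' @return a `pgx_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path)
  weights <- unlist(payload$weights)
  if (is.null(weights)) weights <- stats::setNames(numeric(0), character(0))
  structure(
    list(
      group = payload$group,
      intercept = as.numeric(payload$intercept),
      weights = weights,
      vocab = names(weights),
      lambda = as.numeric(payload$lambda),
      metadata = payload$metadata
    ),
    class = "pgx_model"
  )
}
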
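#' Path to a packaged starter config file
#'
#' The package ships editable starter configuration under `extdata`:
#' `pgx_keywords.txt` (keyword gate), `variant_exclusions.txt`
#' (non-variant terms), `chemical_allowlist.tsv`, `cancer_chemicals.txt`
#' and `synthetic_pharmgkb_snapshot.tsv` (a synthetic knowledge-base
#' snapshot in the [read_pharmgkb_table()] layout).
#'
#' @param file file name under `extdata`.
#' @return absolute path.
#' @export
pgx_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pgxmine", mustWork = FALSE)
  if (path == "") stop("no packaged config file '", file, "'", call. = FALSE)
  path
}

#' Assemble and validate a pipeline configuration
#'
#' Inputs may be in-memory objects (tibbles, `pgx_model`s, character
#' vectors) or file paths; paths are loaded up front so a missing input
#' fails before any stage runs.
#'
#' @param documents corpus tibble or BioC XML path.
#' @param annotations annotation tibble or TSV path.
#' @param model_group1,model_group2 `pgx_model` objects or JSON paths.
#' @param out_dir output directory for the three TSVs and the manifest.
#' @param threshold acceptance threshold (default 0.75).
#' @param keywords keyword vector or file; defaults to the packaged list.
#' @param exclusion_words variant exclusion vector or file; packaged
#'   default.
#' @param allowlist chemical allowlist tibble or TSV path; packaged
#'   default.
#' @param excluded_categories chemical categories dropped when building
#'   the allowed-id set.
#' @param cancer_chemicals cancer-associated chemical ids (vector or
#'   file); packaged default.
#' @param pharmgkb knowledge-base snapshot (list from
#'   [read_pharmgkb_table()] or TSV path), or `NULL` to skip flagging.
#' @param rsid_gene_map optional tibble or TSV (`rsid`, `gene_id`) used
#'   to fill in gene context for rs-ID variants.
#' @return a validated `pgx_pipeline_config` list.
#' @export
pipeline_config <- function(documents, annotations,
                            model_group1, model_group2, out_dir,
                            threshold = 0.75,
                            keywords = pgx_extdata("pgx_keywords.txt"),
                            exclusion_words = pgx_extdata("variant_exclusions.txt"),
                            allowlist = pgx_extdata("chemical_allowlist.tsv"),
                            excluded_categories = c("excipient", "amino acid",
                                                    "nucleotide", "metal"),
                            cancer_chemicals = pgx_extdata("cancer_chemicals.txt"),
                            pharmgkb = NULL,
                            rsid_gene_map = NULL) {
  load_path <- function(x, reader, what) {
    if (is.character(x) && length(x) == 1 && !what %in% "terms") {
      if (!file.exists(x)) stop("missing input file: ", x, call. = FALSE)
      return(reader(x))
    }
    if (what == "terms" && is.character(x) && length(x) == 1 && grepl("[/.]", x)) {
      if (!file.exists(x)) stop("missing input file: ", x, call. = FALSE)
      return(reader(x))
    }
    x
  }
  cfg <- list(
    corpus = load_path(documents, read_documents, "corpus"),
    annotations = load_path(annotations, read_annotations, "annotations"),
    model_group1 = load_path(model_group1, read_model, "model"),
    model_group2 = load_path(model_group2, read_model, "model"),
    threshold = threshold,
    keywords = load_path(keywords, read_term_list, "terms"),
    exclusion_words = load_path(exclusion_words, read_term_list, "terms"),
    allowlist = load_path(allowlist, read_chemical_allowlist, "allowlist"),
    excluded_categories = excluded_categories,
    cancer_chemicals = load_path(cancer_chemicals, read_term_list, "terms"),
    pharmgkb = if (is.null(pharmgkb)) NULL else {
      load_path(pharmgkb, read_pharmgkb_table, "pharmgkb")
    },
    rsid_gene_map = if (is.null(rsid_gene_map)) NULL else {
      load_path(rsid_gene_map,
                function(p) readr::read_tsv(p, show_col_types = FALSE,
                                            col_types = readr::cols(.default = "c")),
                "map")
    },
    out_dir = out_dir
  )
  stopifnot(inherits(cfg$model_group1, "pgx_model"),
            inherits(cfg$model_group2, "pgx_model"),
            cfg$model_group1$group == "group1",
            cfg$model_group2$group == "group2",
            is.numeric(cfg$threshold), cfg$threshold >= 0, cfg$threshold <= 1)
  structure(cfg, class = "pgx_pipeline_config")
}

#' Run the full extraction pipeline
#'
#' Executes align, star-allele detection, variant renormalization and
#' filtering, candidate selection, per-group scoring, cancer filtering,
#' thresholding, collation and knowledge-base flagging, then writes
#' `pgxmine_unfiltered.tsv`, `pgxmine_filtered.tsv`,
#' `pgxmine_collated.tsv` and a `manifest.json` with a config hash and
#' stage-wise record counts. The pipeline is a pure function of its
#' inputs: rerunning with identical inputs reproduces identical files
#' byte for byte. On a stage failure, partial outputs are removed and the
#' manifest records the failure point before the error propagates.
#'
#' @param config a `pgx_pipeline_config` from [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with `rows_unfiltered`, `rows_filtered`,
#'   `collated`, `counts` and the output `paths`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pgx_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  counts <- list()
  stage <- "start"
  say <- function(...) if (!quiet) message(...)

  result <- tryCatch({
    stage <- "align"
    say("aligning annotations")
    mentions <- align_mentions(config$corpus, config$annotations, quiet = quiet)
    counts$aligned_mentions <- nrow(mentions)
    counts$unaligned_records <- nrow(attr(mentions, "unaligned"))

    stage <- "star_alleles"
    stars <- find_star_alleles(config$corpus, mentions)
    counts$star_alleles <- nrow(stars)
    star_mentions <- stars |>
      select("doc_id", "entity_class", "start", "end",
             mention_text = "mention_text", normalized_id = "normalized_id",
             gene_id = "gene_id")
    # a variant tagger occasionally tags the same token the star-allele
    # scanner finds; prefer the star normalization on identical spans
    star_key <- paste(star_mentions$doc_id, star_mentions$start,
                      star_mentions$end)
    dup_var <- mentions$entity_class == "variant" &
      paste(mentions$doc_id, mentions$start, mentions$end) %in% star_key
    mentions <- bind_rows(mentions[!dup_var, ], star_mentions) |>
      arrange(.data$doc_id, .data$start, .data$end)

    stage <- "normalize_variants"
    mentions <- classify_variants(mentions)
    is_var <- mentions$entity_class %in% c("variant", "star_allele")
    counts$variant_mentions <- sum(is_var)
    var_rows <- apply_exclusion_words(mentions[is_var, ],
                                      config$exclusion_words, quiet = quiet)
    var_rows <- var_rows[has_specific_coordinate(var_rows), ]
    counts$variants_surviving <- nrow(var_rows)
    if (!is.null(config$rsid_gene_map) && nrow(var_rows) > 0) {
      gm <- stats::setNames(config$rsid_gene_map$gene_id,
                            config$rsid_gene_map$rsid)
      hit <- !is.na(var_rows$rsid) & is.na(var_rows$gene_id) &
        var_rows$rsid %in% names(gm)
      var_rows$gene_id[hit] <- unname(gm[var_rows$rsid[hit]])
    }

    stage <- "filter_chemicals"
    allowed <- build_chemical_allowlist(config$allowlist,
                                        config$excluded_categories)
    chem_rows <- filter_chemicals(
      mentions[mentions$entity_class == "chemical", ], allowed
    )
    counts$chemical_mentions <- sum(mentions$entity_class == "chemical")
    counts$chemicals_surviving <- nrow(chem_rows)
    surviving <- bind_rows(chem_rows, var_rows,
                           mentions[mentions$entity_class == "gene", ])

    stage <- "candidates"
    sentences <- segment_sentences(config$corpus)
    counts$sentences <- nrow(sentences)
    candidates <- select_candidates(sentences, surviving, config$keywords)
    counts$candidates <- nrow(candidates)

    stage <- "score"
    g1 <- score_candidates(filter(candidates, .data$group == "group1"),
                           config$model_group1)
    g2 <- score_candidates(filter(candidates, .data$group == "group2"),
                           config$model_group2)
    scored <- bind_rows(g1, g2) |>
      arrange(.data$doc_id, .data$sentence_id,
              .data$chemical_start, .data$variant_start)
    scored <- filter_cancer_chemicals(scored, config$cancer_chemicals)
    counts$after_cancer_filter <- nrow(scored)

    stage <- "collate"
    unfiltered <- build_relation_rows(scored, config$corpus)
    accepted <- apply_threshold(scored, config$threshold)
    filtered <- build_relation_rows(accepted, config$corpus)
    counts$unfiltered_rows <- nrow(unfiltered)
    counts$filtered_rows <- nrow(filtered)
    collated <- collate_associations(filtered)
    counts$collated_associations <- nrow(collated)

    stage <- "pharmgkb"
    if (!is.null(config$pharmgkb)) {
      collated <- annotate_pharmgkb(collated, config$pharmgkb)
      counts$in_pharmgkb_association <- sum(collated$in_pharmgkb_association)
    }

    stage <- "write"
    paths <- write_output_tables(unfiltered, filtered, collated,
                                 config$out_dir)
    list(rows_unfiltered = unfiltered, rows_filtered = filtered,
         collated = collated, paths = paths)
  }, error = function(e) {
    for (f in c("pgxmine_unfiltered.tsv", "pgxmine_filtered.tsv",
                "pgxmine_collated.tsv")) {
      unlink(file.path(config$out_dir, f))
    }
    jsonlite::write_json(
      list(status = "failed", failed_stage = stage,
           error = conditionMessage(e)),
      manifest_path, auto_unbox = TRUE
    )
    stop(e)
  })

  manifest <- list(
    tool = "pgxmine",
    version = as.character(utils::packageVersion("pgxmine")),
    status = "ok",
    config_hash = rlang::hash(list(
      threshold = config$threshold, keywords = config$keywords,
      exclusion_words = config$exclusion_words,
      excluded_categories = config$excluded_categories,
      cancer_chemicals = config$cancer_chemicals,
      model_group1 = config$model_group1[c("intercept", "weights", "lambda")],
      model_group2 = config$model_group2[c("intercept", "weights", "lambda")]
    )),
    model_seeds = list(group1 = config$model_group1$metadata$seed,
                       group2 = config$model_group2$metadata$seed),
    threshold = config$threshold,
    counts = counts
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(result, list(counts = counts, manifest = manifest)))
}
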
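escape_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a sentence with its relation entities highlighted
#'
#' HTML special characters in the sentence are escaped first, then the
#' two entity substrings are wrapped in `<b>` tags, so the tags are the
#' only markup in the output.
#'
#' @param sentence_text the sentence string.
#' @param chemical_span,variant_span sentence-local 0-based half-open
#'   integer spans `c(start, end)`; they must lie inside the sentence and
#'   must not overlap.
#' @return the escaped, highlighted sentence string.
#' @examples
#' render_sentence_html("A<B affects rs1 & drugX", c(17, 22), c(12, 15))
#' @export
render_sentence_html <- function(sentence_text, chemical_span, variant_span) {
  n <- nchar(sentence_text)
  spans <- list(chemical_span, variant_span)
  for (sp in spans) {
    if (sp[1] < 0 || sp[2] > n || sp[1] >= sp[2]) {
      stop("entity span out of sentence bounds", call. = FALSE)
    }
  }
  spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
  if (spans[[1]][2] > spans[[2]][1]) {
    stop("entity spans overlap; cannot highlight", call. = FALSE)
  }
  a <- spans[[1]]
  b <- spans[[2]]
  seg <- function(s, e) substr(sentence_text, s + 1L, e) # 0-based half-open
  paste0(
    escape_html(seg(0L, a[1])),
    "<b>", escape_html(seg(a[1], a[2])), "</b>",
    escape_html(seg(a[2], b[1])),
    "<b>", escape_html(seg(b[1], b[2])), "</b>",
    escape_html(seg(b[2], n))
  )
}

#' Build curator-facing relation rows from accepted candidates
#'
#' Joins document metadata, renders the highlighted sentence and flattens
#' each candidate into one output row.
#'
#' @param candidates scored candidate tibble.
#' @param corpus the corpus the candidates came from (for metadata).
#' @return tibble with document metadata, chemical/variant identifiers,
#'   `score` and `sentence_html`; embedded tabs/newlines in sentences are
#'   replaced by spaces so the TSV needs no quoting.
#' @export
build_relation_rows <- function(candidates, corpus) {
  meta <- corpus |>
    group_by(.data$doc_id) |>
    summarise(title = .data$title[1], journal = .data$journal[1],
              year = .data$year[1], .groups = "drop")
  if (nrow(candidates) == 0) {
    return(tibble(
      doc_id = character(), pmid = character(), title = character(),
      journal = character(), year = integer(), section = character(),
      chemical_id = character(), chemical_text = character(),
      variant_id = character(), variant_kind = character(),
      gene_id = character(), score = numeric(), sentence_html = character()
    ))
  }
  html <- purrr::pmap_chr(
    list(candidates$sentence_text,
         candidates$chemical_start - candidates$sentence_start,
         candidates$chemical_end - candidates$sentence_start,
         candidates$variant_start - candidates$sentence_start,
         candidates$variant_end - candidates$sentence_start),
    function(text, cs, ce, vs, ve) {
      render_sentence_html(text, c(cs, ce), c(vs, ve))
    }
  )
  candidates |>
    left_join(meta, by = "doc_id") |>
    mutate(
      pmid = .data$doc_id,
      section = .data$sentence_section,
      sentence_html = gsub("[\t\n]", " ", html)
    ) |>
    select("doc_id", "pmid", "title", "journal", "year", "section",
           "chemical_id", "chemical_text", "variant_id", "variant_kind",
           "gene_id", "score", "sentence_html")
}

#' Collate relation rows into ranked chemical-variant associations
#'
#' Groups by (chemical id, variant id, gene id) and counts distinct
#' supporting papers; the count is a rough importance metric that ranks
#' which frequently discussed associations deserve curation first. Ties
#' are broken by chemical name then variant id for a deterministic order.
#'
#' @param rows relation rows from [build_relation_rows()].
#' @return tibble of associations sorted by `paper_count` descending,
#'   with a list-column `pmids` of the distinct supporting papers and
#'   `n_rows`, the number of contributing relation rows.
#' @export
collate_associations <- function(rows) {
  if (nrow(rows) == 0) {
    return(tibble(chemical_id = character(), chemical_text = character(),
                  variant_id = character(), variant_kind = character(),
                  gene_id = character(), paper_count = integer(),
                  n_rows = integer(), pmids = list()))
  }
  rows |>
    group_by(.data$chemical_id, .data$variant_id, .data$gene_id) |>
    summarise(
      chemical_text = .data$chemical_text[1],
      variant_kind = .data$variant_kind[1],
      paper_count = dplyr::n_distinct(.data$pmid),
      n_rows = dplyr::n(),
      pmids = list(sort(unique(.data$pmid))),
      .groups = "drop"
    ) |>
    arrange(desc(.data$paper_count), .data$chemical_text, .data$variant_id) |>
    select("chemical_id", "chemical_text", "variant_id", "variant_kind",
           "gene_id", "paper_count", "n_rows", "pmids")
}

#' Unfold compound knowledge-base associations to single pairs
#'
#' Knowledge bases record compound associations linking several chemicals
#' to one variant; comparison requires one chemical per pair, so each
#' association is unfolded into its (chemical, variant) combinations.
#'
#' @param associations tibble with columns `chemical_ids` (either a
#'   list-column or `;`-separated strings) and `variant_key`.
#' @return tibble with one row per (chemical_id, variant_key) pair.
#' @export
unfold_compound_associations <- function(associations) {
  if (nrow(associations) == 0) {
    return(tibble(chemical_id = character(), variant_key = character()))
  }
  if (is.list(associations$chemical_ids)) {
    out <- tidyr::unnest(
      associations |> select("chemical_ids", "variant_key"),
      "chemical_ids"
    )
  } else {
    out <- associations |>
      select("chemical_ids", "variant_key") |>
      tidyr::separate_longer_delim("chemical_ids", delim = ";")
  }
  out |>
    mutate(chemical_id = trimws(.data$chemical_ids)) |>
    filter(.data$chemical_id != "") |>
    select("chemical_id", "variant_key")
}

#' Read a knowledge-base snapshot for association flagging
#'
#' The snapshot is a directory-free single TSV with three record types
#' distinguished by a `record` column: `chemical_mapping` (columns
#' `mesh_id`, `kb_chemical_id`), `association` (`kb_chemical_id`,
#' `variant_key`, possibly `;`-separated compound chemicals), and
#' `star_rs` (`star_allele`, `rsid` equivalences such as POR*28 and
#' rs1057868).
#'
#' @param path TSV path with header `record`, `field1`, `field2`.
#' @return a list with tibbles `chemical_map`, `associations`, `star_rs`
#'   suitable for [annotate_pharmgkb()].
#' @export
read_pharmgkb_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  list(
    chemical_map = df |>
      filter(.data$record == "chemical_mapping") |>
      select(mesh_id = "field1", kb_chemical_id = "field2"),
    associations = df |>
      filter(.data$record == "association") |>
      select(chemical_ids = "field1", variant_key = "field2"),
    star_rs = df |>
      filter(.data$record == "star_rs") |>
      select(star_allele = "field1", rsid = "field2")
  )
}

#' Flag collated associations against a curated knowledge base
#'
#' For each mined association: the chemical flag is true when its MeSH id
#' maps to a knowledge-base chemical that appears in at least one curated
#' association; the variant flag is true when any equivalent variant key
#' appears in a curated association; the association flag is true when
#' the (mapped chemical, equivalent variant) pair itself is curated.
#' Variant keys are compared after suballele stripping
#' ([strip_suballele()]), and star alleles that map to a single rs ID are
#' looked up under both keys (e.g. POR*28 and rs1057868).
#'
#' @param associations collated tibble from [collate_associations()].
#' @param table knowledge-base snapshot from [read_pharmgkb_table()]; its
#'   compound associations are unfolded internally.
#' @return the associations with logical columns `in_pharmgkb_chemical`,
#'   `in_pharmgkb_variant`, `in_pharmgkb_association`.
#' @export
annotate_pharmgkb <- function(associations, table) {
  pairs <- unfold_compound_associations(table$associations)
  pairs$variant_key <- strip_suballele(pairs$variant_key)
  kb_chems <- unique(pairs$chemical_id)
  kb_vars <- unique(pairs$variant_key)
  star_to_rs <- stats::setNames(table$star_rs$rsid, table$star_rs$star_allele)
  rs_to_star <- stats::setNames(table$star_rs$star_allele, table$star_rs$rsid)
  chem_map <- stats::setNames(table$chemical_map$kb_chemical_id,
                              table$chemical_map$mesh_id)
  pair_key <- paste(pairs$chemical_id, pairs$variant_key, sep = "\r")

  variant_keys <- function(variant_id) {
    key <- strip_suballele(variant_id)
    keys <- key
    if (key %in% names(star_to_rs)) keys <- c(keys, star_to_rs[[key]])
    if (key %in% names(rs_to_star)) keys <- c(keys, rs_to_star[[key]])
    unique(keys)
  }

  flags <- purrr::map(seq_len(nrow(associations)), function(i) {
    mapped_chem <- chem_map[associations$chemical_id[i]]
    keys <- variant_keys(associations$variant_id[i])
    chem_ok <- !is.na(mapped_chem) && mapped_chem %in% kb_chems
    var_ok <- any(keys %in% kb_vars)
    assoc_ok <- chem_ok &&
      any(paste(mapped_chem, keys, sep = "\r") %in% pair_key)
    tibble(in_pharmgkb_chemical = chem_ok,
           in_pharmgkb_variant = var_ok,
           in_pharmgkb_association = assoc_ok)
  }) |> bind_rows()
  if (nrow(associations) == 0) {
    associations$in_pharmgkb_chemical <- logical(0)
    associations$in_pharmgkb_variant <- logical(0)
    associations$in_pharmgkb_association <- logical(0)
    return(associations)
  }
  dplyr::bind_cols(associations, flags)
}

#' Write the three curator-facing output tables
#'
#' Writes `pgxmine_unfiltered.tsv` (all scored relation rows),
#' `pgxmine_filtered.tsv` (rows at or above the threshold) and
#' `pgxmine_collated.tsv` (ranked associations with knowledge-base
#' flags). Files are UTF-8, tab-separated with a header row and no
#' quoting; embedded tabs/newlines were removed upstream.
#'
#' @param unfiltered,filtered relation-row tibbles.
#' @param collated flagged association tibble.
#' @param out_dir output directory (created if missing).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_output_tables <- function(unfiltered, filtered, collated, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    unfiltered = file.path(out_dir, "pgxmine_unfiltered.tsv"),
    filtered = file.path(out_dir, "pgxmine_filtered.tsv"),
    collated = file.path(out_dir, "pgxmine_collated.tsv")
  )
  readr::write_tsv(unfiltered, paths[["unfiltered"]], escape = "none")
  readr::write_tsv(filtered, paths[["filtered"]], escape = "none")
  flat <- collated |>
    mutate(pmids = purrr::map_chr(.data$pmids, paste, collapse = ";"))
  readr::write_tsv(flat, paths[["collated"]], escape = "none")
  invisible(paths)
}

#' Plot the top collated associations by supporting-paper count
#'
#' @param collated collated association tibble.
#' @param n number of associations to show (default 10).
#' @return a ggplot bar chart.
#' @export
plot_top_associations <- function(collated, n = 10) {
  top <- utils::head(collated, n) |>
    mutate(label = paste(.data$chemical_text, .data$variant_id, sep = " / "))
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$label, .data$paper_count),
    y = .data$paper_count
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Supporting papers",
                  title = "Most-discussed chemical-variant associations") +
    ggplot2::theme_minimal()
}
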
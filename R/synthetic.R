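# Built-in entity lexicons for the synthetic corpus. Identifiers follow the
# shapes real annotators emit (MeSH-style chemical ids, Entrez-style gene
# ids) but documents, sentences and co-occurrences are fabricated.
default_lexicon <- function() {
  list(
    chemicals = tibble(
      name = c("warfarin", "clopidogrel", "simvastatin", "abacavir",
               "telmisartan", "carbamazepine", "azathioprine", "clozapine",
               "efavirenz", "omeprazole", "metoprolol", "tacrolimus",
               "codeine", "valproic acid", "mycophenolic acid",
               "interferon alpha", "interferon beta",
               "erlotinib", "gefitinib", "tamoxifen", "irinotecan",
               "fluorouracil"),
      mesh_id = c("MESH:D014859", "MESH:C055162", "MESH:D019821",
                  "MESH:C106538", "MESH:C084178", "MESH:D002220",
                  "MESH:D001379", "MESH:D003024", "MESH:C098320",
                  "MESH:D009853", "MESH:D008790", "MESH:D016559",
                  "MESH:D003061", "MESH:D014635", "MESH:D009173",
                  "MESH:D016898", "MESH:D016899",
                  "MESH:D000069347", "MESH:D000077156", "MESH:D013629",
                  "MESH:D000077146", "MESH:D005472"),
      cancer = c(rep(FALSE, 17), rep(TRUE, 5)),
      categories = "drug"
    ),
    decoy_chemicals = tibble(
      name = c("ATP", "sucrose"),
      mesh_id = c("MESH:D000255", "MESH:D013395"),
      categories = c("drug", "excipient")
    ),
    genes = tibble(
      symbol = c("CYP2D6", "CYP2C9", "CYP2C19", "CYP3A5", "CYP2A6",
                 "TPMT", "UGT1A1", "POR", "NAT2", "HLA-B", "HLA-A"),
      entrez = c("1565", "1559", "1557", "1577", "1548",
                 "7172", "54658", "5447", "10", "3106", "3105"),
      hla = c(rep(FALSE, 9), TRUE, TRUE)
    ),
    star_labels = c("1", "2", "3", "4", "17", "28", "2A", "3A", "4A"),
    hla_labels = c("5701", "3101", "1502", "5801"),
    exclusion_decoys = c("T47D", "HEK293", "U937", "K562", "A549"),
    excluded_categories = c("excipient", "amino acid", "nucleotide", "metal")
  )
}

POSITIVE_TEMPLATES <- c(
  "{VAR} carriers showed a markedly altered response to {CHEM}.",
  "{VAR} was associated with increased {CHEM} clearance.",
  "Patients with {VAR} required a lower dose of {CHEM}.",
  "{VAR} significantly increased the metabolism of {CHEM}.",
  "{VAR} predicted severe {CHEM} toxicity in treated patients.",
  # negative finding, still labeled TRUE: curators want these
  "{VAR} did not affect the metabolism of {CHEM}."
)

NEGATIVE_TEMPLATES <- c(
  "Patients received {CHEM} while the {VAR} genotype was recorded in a separate registry.",
  "{CHEM} was administered as comparator, and {VAR} allele frequencies were tabulated independently.",
  "The genotype panel covered {VAR}, whereas {CHEM} served as an internal standard.",
  "{VAR} appeared in the polymorphism screen; {CHEM} use was documented for another arm."
)

MULTI_TEMPLATE <- paste0(
  "Both {CHEM1} and {CHEM2} response rates were influenced by ",
  "{VAR1} and {VAR2} in the trial."
)

STAR_GRAMMAR_FORMS <- list(
  list(render = function(g) paste0(g, "*2/*3"), labels = c("2", "3")),
  list(render = function(g) paste0(g, " *1, *2 and *4"), labels = c("1", "2", "4")),
  list(render = function(g) paste0(g, "*1 or *17"), labels = c("1", "17")),
  list(render = function(g) paste0(g, "*3A"), labels = "3A")
)

FILLER_SENTENCES <- c(
  "The cohort was recruited from three tertiary centres.",
  "Baseline characteristics were similar across study arms.",
  "Median follow-up lasted twelve months.",
  "Samples were archived under standard conditions.",
  "Written informed consent was obtained from every participant."
)

#' Configuration for the synthetic-corpus generator
#'
#' Defaults describe a modest pharmacogenomics corpus: a few dozen
#' abstracts, roughly half with full text, balanced positive/negative
#' relation sentences split evenly between the rsID/star-allele group and
#' the DNA/protein group, a 20% rate of Greek-letter and whitespace
#' surface perturbation (annotation records keep the ASCII, single-space
#' form, mirroring how taggers translate articles to ASCII), and a
#' handful of each decoy type so every filtering rule has work to do.
#'
#' @param seed integer seed; the generator is deterministic given it.
#' @param n_documents number of documents.
#' @param n_positive,n_negative planted relation sentences with
#'   positive/negative labels (negative-finding phrasings are planted
#'   among the positives and labeled `TRUE`).
#' @param group1_fraction fraction of relation sentences whose variant is
#'   an rs ID or star allele.
#' @param star_fraction fraction of group1 relation sentences using a
#'   star allele (the rest use rs IDs).
#' @param hla_fraction fraction of star-allele relation sentences using
#'   an HLA gene.
#' @param dna_fraction fraction of group2 relation sentences using a DNA
#'   substitution (the rest are protein substitutions).
#' @param full_text_fraction fraction of documents with body passages.
#' @param greek_rate,whitespace_rate per-mention surface perturbation
#'   probabilities.
#' @param n_multi multi-entity sentences (2 chemicals x 2 variants, all
#'   four pairs labeled positive) exercising the many-pair failure mode.
#' @param n_cancer_decoys positive-phrased cancer-chemical/protein-variant
#'   sentences the cancer filter should remove.
#' @param n_exclusion_decoys,n_short_chemical_decoys,n_disallowed_decoys,n_nocoord_decoys
#'   counts of cell-line variant decoys, sub-4-character chemical decoys,
#'   disallowed-category chemical decoys, and coordinate-free variant
#'   decoys.
#' @param n_star_grammar star-allele list sentences (no chemical) cycling
#'   through the separator grammar forms.
#' @param lexicon entity lexicons (see `default_lexicon` in the sources).
#' @return a `pgx_corpus_config` list.
#' @export
corpus_config <- function(seed = 1L,
                          n_documents = 20L,
                          n_positive = 30L,
                          n_negative = 30L,
                          group1_fraction = 0.5,
                          star_fraction = 0.5,
                          hla_fraction = 0.2,
                          dna_fraction = 0.4,
                          full_text_fraction = 0.5,
                          greek_rate = 0.2,
                          whitespace_rate = 0.2,
                          n_multi = 2L,
                          n_cancer_decoys = 2L,
                          n_exclusion_decoys = 4L,
                          n_short_chemical_decoys = 4L,
                          n_disallowed_decoys = 3L,
                          n_nocoord_decoys = 4L,
                          n_star_grammar = 4L,
                          lexicon = default_lexicon()) {
  cfg <- list(
    seed = as.integer(seed), n_documents = as.integer(n_documents),
    n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
    group1_fraction = group1_fraction, star_fraction = star_fraction,
    hla_fraction = hla_fraction, dna_fraction = dna_fraction,
    full_text_fraction = full_text_fraction,
    greek_rate = greek_rate, whitespace_rate = whitespace_rate,
    n_multi = as.integer(n_multi),
    n_cancer_decoys = as.integer(n_cancer_decoys),
    n_exclusion_decoys = as.integer(n_exclusion_decoys),
    n_short_chemical_decoys = as.integer(n_short_chemical_decoys),
    n_disallowed_decoys = as.integer(n_disallowed_decoys),
    n_nocoord_decoys = as.integer(n_nocoord_decoys),
    n_star_grammar = as.integer(n_star_grammar),
    lexicon = lexicon
  )
  rates <- c(cfg$group1_fraction, cfg$star_fraction, cfg$hla_fraction,
             cfg$dna_fraction, cfg$full_text_fraction, cfg$greek_rate,
             cfg$whitespace_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (cfg$n_documents < 1) stop("need at least one document", call. = FALSE)
  if (nrow(lexicon$chemicals) == 0 || nrow(lexicon$genes) == 0) {
    stop("entity lexicons must be non-empty", call. = FALSE)
  }
  n_rel <- cfg$n_positive + cfg$n_negative + cfg$n_multi + cfg$n_cancer_decoys
  per_doc <- ceiling(n_rel / cfg$n_documents) + 2L # + decoys sharing the doc
  n_chem_needed <- per_doc + 2L * ceiling(cfg$n_multi / cfg$n_documents)
  if (n_chem_needed > sum(!lexicon$chemicals$cancer)) {
    stop("too many relation sentences per document for the chemical lexicon; ",
         "increase n_documents", call. = FALSE)
  }
  structure(cfg, class = "pgx_corpus_config")
}

# fill {SLOT} placeholders, returning the text and 0-based half-open
# spans of each slot value
fill_slots <- function(template, values) {
  out <- ""
  spans <- list()
  rest <- template
  pos <- 0L
  repeat {
    m <- stringr::str_locate(rest, "\\{[A-Z0-9]+\\}")
    if (is.na(m[1, 1])) {
      out <- paste0(out, rest)
      break
    }
    pre <- substr(rest, 1L, m[1, 1] - 1L)
    slot <- substr(rest, m[1, 1] + 1L, m[1, 2] - 1L)
    val <- values[[slot]]
    out <- paste0(out, pre, val)
    s <- pos + nchar(pre)
    spans[[slot]] <- c(s, s + nchar(val))
    pos <- s + nchar(val)
    rest <- substr(rest, m[1, 2] + 1L, nchar(rest))
  }
  list(text = out, spans = spans)
}

# surface perturbation of a chemical name; the record keeps the ASCII,
# single-space form while the document shows the perturbed form
perturb_surface <- function(name, greek_rate, whitespace_rate) {
  rendered <- name
  greek_hit <- stringr::str_detect(name, "\\b(alpha|beta|gamma)\\b")
  if (greek_hit && stats::runif(1) < greek_rate) {
    for (nm in c("alpha", "beta", "gamma")) {
      rendered <- stringr::str_replace_all(
        rendered, paste0("\\b", nm, "\\b"), GREEK_LETTERS[[nm]]
      )
    }
  } else if (grepl(" ", name) && stats::runif(1) < whitespace_rate) {
    rendered <- sub(" ", "  ", rendered, fixed = TRUE)
  }
  rendered
}

#' Generate a seeded synthetic corpus with planted ground truth
#'
#' Produces documents, offset-free annotation records (offsets are
#' deliberately withheld to exercise alignment), ground truth (planted
#' mention spans, planted star alleles, planted relation labels, and the
#' expected survivor count of every deterministic filter stage) and
#' labeled candidates ready for classifier training. Positive relation
#' sentences are lexically separable from negatives by trigger phrasing;
#' negative-finding sentences are planted among the positives and labeled
#' `TRUE`.
#'
#' @param config a `pgx_corpus_config` from [corpus_config()].
#' @return list with elements `corpus`, `annotations`, `ground_truth`
#'   (list: `mentions`, `star_alleles`, `relations`, `expected_counts`)
#'   and `labeled_candidates`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "pgx_corpus_config"))
  with_local_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  lex <- cfg$lexicon
  n_rel <- cfg$n_positive + cfg$n_negative
  # exact-count kind and label vectors, shuffled
  n_g1 <- round(n_rel * cfg$group1_fraction)
  n_star <- round(n_g1 * cfg$star_fraction)
  n_dna <- round((n_rel - n_g1) * cfg$dna_fraction)
  kinds <- sample(c(rep("star_allele", n_star), rep("dbsnp", n_g1 - n_star),
                    rep("dna_sub", n_dna),
                    rep("protein_sub", n_rel - n_g1 - n_dna)))
  labels <- sample(c(rep(TRUE, cfg$n_positive), rep(FALSE, cfg$n_negative)))

  specs <- c(
    purrr::map2(kinds, labels, ~ list(type = "relation", kind = .x, label = .y)),
    purrr::map(seq_len(cfg$n_multi), ~ list(type = "multi")),
    purrr::map(seq_len(cfg$n_cancer_decoys), ~ list(type = "cancer")),
    purrr::map(seq_len(cfg$n_star_grammar),
               ~ list(type = "grammar", form = ((.x - 1) %% length(STAR_GRAMMAR_FORMS)) + 1L)),
    purrr::map(seq_len(cfg$n_exclusion_decoys), ~ list(type = "excl")),
    purrr::map(seq_len(cfg$n_short_chemical_decoys), ~ list(type = "short")),
    purrr::map(seq_len(cfg$n_disallowed_decoys), ~ list(type = "disallowed")),
    purrr::map(seq_len(cfg$n_nocoord_decoys), ~ list(type = "nocoord"))
  )
  # round-robin assignment to documents
  doc_of <- rep(seq_len(cfg$n_documents), length.out = length(specs))
  rs_pool <- paste0("rs", sample.int(9989999, length(specs) + 10) + 10000L)
  rs_i <- 0L
  full_text <- seq_len(cfg$n_documents) <=
    round(cfg$n_documents * cfg$full_text_fraction)

  docs <- vector("list", cfg$n_documents)
  for (d in seq_len(cfg$n_documents)) {
    doc_id <- sprintf("%07d", 1000000L + d)
    doc_specs <- specs[doc_of == d]
    chem_pool <- sample(which(!lex$chemicals$cancer))
    cancer_pool <- sample(which(lex$chemicals$cancer))
    gene_pool <- sample(seq_len(nrow(lex$genes)))
    excl_pool <- sample(lex$exclusion_decoys)
    used_pos <- integer(0)

    draw_chem <- function(cancer = FALSE) {
      if (cancer) {
        i <- cancer_pool[1]
        cancer_pool <<- cancer_pool[-1]
      } else {
        i <- chem_pool[1]
        chem_pool <<- chem_pool[-1]
      }
      lex$chemicals[i, ]
    }
    draw_gene <- function(hla = FALSE) {
      ok <- which(lex$genes$hla[gene_pool] == hla)
      if (length(ok) == 0) ok <- seq_along(gene_pool) # pool exhausted: any gene
      i <- gene_pool[ok[1]]
      gene_pool <<- gene_pool[gene_pool != i]
      lex$genes[i, ]
    }
    draw_excl <- function() {
      w <- excl_pool[1]
      excl_pool <<- excl_pool[-1]
      w
    }
    draw_pos <- function() {
      repeat {
        p <- sample(10:999, 1)
        if (!p %in% used_pos) {
          used_pos <<- c(used_pos, p)
          return(p)
        }
      }
    }
    draw_rs <- function() {
      rs_i <<- rs_i + 1L
      rs_pool[rs_i]
    }

    sentences <- purrr::map(doc_specs, function(spec) {
      build_sentence(spec, cfg, draw_chem, draw_gene, draw_pos, draw_rs,
                     draw_excl)
    })
    # one filler sentence per document keeps prose varied
    sentences <- c(sentences, list(list(
      text = FILLER_SENTENCES[((d - 1) %% length(FILLER_SENTENCES)) + 1L],
      records = NULL, stars = NULL, relations = NULL
    )))
    docs[[d]] <- assemble_document(doc_id, sentences, full_text[d], d)
  }

  corpus <- bind_rows(purrr::map(docs, "passages"))
  corpus <- pgx_corpus(corpus$doc_id, corpus$section, corpus$text,
                       corpus$title, corpus$journal, corpus$year)
  mentions_gt <- bind_rows(purrr::map(docs, "mentions"))
  stars_gt <- bind_rows(purrr::map(docs, "stars"))
  relations_gt <- bind_rows(purrr::map(docs, "relations"))
  annotations <- mentions_gt |>
    select("doc_id", "entity_class", "mention_text", "normalized_id")

  labeled <- relations_gt |>
    mutate(sentence_id = NA_integer_) |>
    select("doc_id", "sentence_id", "sentence_section", "sentence_start",
           "sentence_end", "sentence_text", "chemical_start", "chemical_end",
           "chemical_text", "chemical_id", "variant_start", "variant_end",
           "variant_text", "variant_id", "variant_kind", "rsid", "hgvs",
           "gene_id", "group", "label", "cancer_decoy")

  expected <- list(
    n_records = nrow(annotations),
    n_aligned = nrow(annotations),
    n_chemical_mentions = sum(mentions_gt$entity_class == "chemical"),
    n_chemicals_surviving = sum(mentions_gt$entity_class == "chemical" &
                                  mentions_gt$survives_chemical_filter),
    n_variant_records = sum(mentions_gt$entity_class == "variant"),
    n_variants_surviving = sum(mentions_gt$entity_class == "variant" &
                                 mentions_gt$survives_exclusion &
                                 mentions_gt$survives_coordinate),
    n_star_alleles = nrow(stars_gt),
    n_candidates = nrow(relations_gt),
    n_after_cancer_filter = sum(!relations_gt$cancer_decoy),
    n_positive_labels = sum(relations_gt$label)
  )

  list(
    corpus = corpus,
    annotations = annotations,
    ground_truth = list(mentions = mentions_gt, star_alleles = stars_gt,
                        relations = relations_gt, expected_counts = expected),
    labeled_candidates = labeled
  )
}

# build one synthetic sentence with its records/ground-truth, spans
# sentence-local until assembly
build_sentence <- function(spec, cfg, draw_chem, draw_gene, draw_pos, draw_rs,
                           draw_excl) {
  lex <- cfg$lexicon
  mk_record <- function(entity_class, mention_text, normalized_id, span, role,
                        surv_chem = TRUE, surv_excl = TRUE, surv_coord = TRUE) {
    tibble(entity_class = entity_class, mention_text = mention_text,
           normalized_id = normalized_id, start = span[1], end = span[2],
           role = role, survives_chemical_filter = surv_chem,
           survives_exclusion = surv_excl, survives_coordinate = surv_coord)
  }

  if (spec$type %in% c("relation", "cancer")) {
    is_cancer <- spec$type == "cancer"
    kind <- if (is_cancer) "protein_sub" else spec$kind
    label <- if (is_cancer) TRUE else spec$label
    chem <- draw_chem(cancer = is_cancer)
    chem_rendered <- perturb_surface(chem$name, cfg$greek_rate, cfg$whitespace_rate)
    templates <- if (label) POSITIVE_TEMPLATES else NEGATIVE_TEMPLATES
    template <- sample(templates, 1)

    gene_rec <- NULL
    star_row <- NULL
    if (kind == "star_allele") {
      hla <- stats::runif(1) < cfg$hla_fraction
      gene <- draw_gene(hla = hla)
      lab <- if (hla) sample(lex$hla_labels, 1) else sample(lex$star_labels, 1)
      var_rendered <- paste0(gene$symbol, "*", lab)
      variant_id <- normalize_star_allele(gene$symbol, lab)
      rsid <- NA_character_
      hgvs <- NA_character_
      var_norm_id <- NA_character_
      gene_id <- gene$entrez
    } else if (kind == "dbsnp") {
      rsid <- draw_rs()
      var_rendered <- rsid
      variant_id <- rsid
      hgvs <- NA_character_
      var_norm_id <- rsid
      gene_id <- NA_character_
    } else if (kind == "protein_sub") {
      ref <- sample(AA_ONE, 1)
      alt <- sample(setdiff(AA_ONE, ref), 1)
      p <- draw_pos()
      var_rendered <- paste0(ref, p, alt)
      hgvs <- paste0("p.", ref, p, alt)
      rsid <- if (stats::runif(1) < 0.3) draw_rs() else NA_character_
      var_norm_id <- rsid
      variant_id <- if (is.na(rsid)) hgvs else rsid
      gene_id <- NA_character_
    } else { # dna_sub
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      p <- draw_pos()
      var_rendered <- paste0("c.", p, ref, ">", alt)
      hgvs <- var_rendered
      rsid <- NA_character_
      var_norm_id <- NA_character_
      variant_id <- hgvs
      gene_id <- NA_character_
    }

    filled <- fill_slots(template, list(CHEM = chem_rendered, VAR = var_rendered))
    chem_span <- filled$spans$CHEM
    var_span <- filled$spans$VAR
    records <- mk_record("chemical", chem$name, chem$mesh_id, chem_span,
                         "relation")
    if (kind == "star_allele") {
      gene_span <- c(var_span[1], var_span[1] + nchar(gene$symbol))
      records <- bind_rows(records,
        mk_record("gene", gene$symbol, gene_id, gene_span, "relation"))
      tok_start <- gene_span[2] + 1L # skip "*"
      star_row <- tibble(start = tok_start, end = var_span[2],
                         normalized = variant_id, gene_name = gene$symbol,
                         gene_id = gene_id)
      var_mention_span <- c(tok_start, var_span[2])
      var_text <- substr(filled$text, tok_start + 1L, var_span[2])
    } else {
      records <- bind_rows(records,
        mk_record("variant", var_rendered, var_norm_id, var_span, "relation"))
      var_mention_span <- var_span
      var_text <- var_rendered
    }
    relation <- tibble(
      sentence_text = filled$text,
      chemical_start = chem_span[1], chemical_end = chem_span[2],
      chemical_text = chem_rendered, chemical_id = chem$mesh_id,
      variant_start = var_mention_span[1], variant_end = var_mention_span[2],
      variant_text = var_text, variant_id = variant_id,
      variant_kind = kind, rsid = rsid, hgvs = hgvs, gene_id = gene_id,
      group = ifelse(kind %in% c("dbsnp", "star_allele"), "group1", "group2"),
      label = label, cancer_decoy = is_cancer
    )
    return(list(text = filled$text, records = records, stars = star_row,
                relations = relation))
  }

  if (spec$type == "multi") {
    chems <- bind_rows(draw_chem(), draw_chem())
    vars <- purrr::map(1:2, function(i) {
      ref <- sample(AA_ONE, 1)
      alt <- sample(setdiff(AA_ONE, ref), 1)
      p <- draw_pos()
      list(text = paste0(ref, p, alt), hgvs = paste0("p.", ref, p, alt))
    })
    filled <- fill_slots(MULTI_TEMPLATE, list(
      CHEM1 = chems$name[1], CHEM2 = chems$name[2],
      VAR1 = vars[[1]]$text, VAR2 = vars[[2]]$text
    ))
    records <- bind_rows(
      mk_record("chemical", chems$name[1], chems$mesh_id[1],
                filled$spans$CHEM1, "relation"),
      mk_record("chemical", chems$name[2], chems$mesh_id[2],
                filled$spans$CHEM2, "relation"),
      mk_record("variant", vars[[1]]$text, NA_character_,
                filled$spans$VAR1, "relation"),
      mk_record("variant", vars[[2]]$text, NA_character_,
                filled$spans$VAR2, "relation")
    )
    combos <- tidyr::expand_grid(ci = 1:2, vi = 1:2)
    relations <- purrr::pmap(combos, function(ci, vi) {
      cs <- filled$spans[[paste0("CHEM", ci)]]
      vs <- filled$spans[[paste0("VAR", vi)]]
      tibble(
        sentence_text = filled$text,
        chemical_start = cs[1], chemical_end = cs[2],
        chemical_text = chems$name[ci], chemical_id = chems$mesh_id[ci],
        variant_start = vs[1], variant_end = vs[2],
        variant_text = vars[[vi]]$text, variant_id = vars[[vi]]$hgvs,
        variant_kind = "protein_sub", rsid = NA_character_,
        hgvs = vars[[vi]]$hgvs, gene_id = NA_character_,
        group = "group2", label = TRUE, cancer_decoy = FALSE
      )
    }) |> bind_rows()
    return(list(text = filled$text, records = records, stars = NULL,
                relations = relations))
  }

  if (spec$type == "grammar") {
    form <- STAR_GRAMMAR_FORMS[[spec$form]]
    gene <- draw_gene(hla = FALSE)
    listing <- form$render(gene$symbol)
    template <- "Genotyping identified {LIST} across the cohort."
    filled <- fill_slots(template, list(LIST = listing))
    gene_span <- c(filled$spans$LIST[1], filled$spans$LIST[1] + nchar(gene$symbol))
    records <- mk_record("gene", gene$symbol, gene$entrez, gene_span, "grammar")
    # token spans: locate each "*<label>" in order within the listing
    offs <- filled$spans$LIST[1]
    stars <- purrr::map(seq_along(form$labels), function(i) {
      lab <- form$labels[i]
      # find the i-th asterisk in the listing
      ast <- stringr::str_locate_all(listing, "\\*")[[1]][i, 1]
      tibble(start = offs + ast, end = offs + ast + nchar(lab),
             normalized = normalize_star_allele(gene$symbol, lab),
             gene_name = gene$symbol, gene_id = gene$entrez)
    }) |> bind_rows()
    return(list(text = filled$text, records = records, stars = stars,
                relations = NULL))
  }

  if (spec$type == "excl") {
    word <- draw_excl()
    filled <- fill_slots("The {VAR} background was profiled separately.",
                         list(VAR = word))
    records <- mk_record("variant", word, NA_character_, filled$spans$VAR,
                         "decoy_exclusion", surv_excl = FALSE)
    return(list(text = filled$text, records = records, stars = NULL,
                relations = NULL))
  }
  if (spec$type == "short") {
    filled <- fill_slots("Cellular {CHEM} turnover was monitored during therapy.",
                         list(CHEM = lex$decoy_chemicals$name[1]))
    records <- mk_record("chemical", lex$decoy_chemicals$name[1],
                         lex$decoy_chemicals$mesh_id[1], filled$spans$CHEM,
                         "decoy_short", surv_chem = FALSE)
    return(list(text = filled$text, records = records, stars = NULL,
                relations = NULL))
  }
  if (spec$type == "disallowed") {
    filled <- fill_slots("The formulation contained {CHEM} as an excipient.",
                         list(CHEM = lex$decoy_chemicals$name[2]))
    records <- mk_record("chemical", lex$decoy_chemicals$name[2],
                         lex$decoy_chemicals$mesh_id[2], filled$spans$CHEM,
                         "decoy_disallowed", surv_chem = FALSE)
    return(list(text = filled$text, records = records, stars = NULL,
                relations = NULL))
  }
  if (spec$type == "nocoord") {
    filled <- fill_slots("A {VAR} substitution pattern was noted in controls.",
                         list(VAR = "c.G>A"))
    records <- mk_record("variant", "c.G>A", NA_character_, filled$spans$VAR,
                         "decoy_nocoord", surv_coord = FALSE)
    return(list(text = filled$text, records = records, stars = NULL,
                relations = NULL))
  }
  stop("unknown sentence spec type: ", spec$type)
}

# lay sentences into passages, lifting sentence-local spans to document
# coordinates (passages joined by "\n", sentences within a passage by " ")
assemble_document <- function(doc_id, sentences, full_text, d) {
  title_text <- sprintf("A pharmacogenetic cohort study (part %d).", d)
  n_s <- length(sentences)
  if (full_text && n_s >= 2) {
    half <- ceiling(n_s / 2)
    passage_plan <- list(abstract = sentences[seq_len(half)],
                         results = sentences[(half + 1):n_s])
  } else {
    passage_plan <- list(abstract = sentences)
  }
  journal <- c("J Pharmacogenomics", "Clin Transl Sci",
               "Drug Metab Res")[((d - 1) %% 3) + 1]
  year <- 2010L + (d %% 10)

  passages <- tibble(doc_id = doc_id, section = "title", text = title_text,
                     title = title_text, journal = journal, year = year)
  doc_offset <- nchar(title_text) + 1L
  mentions <- list()
  stars <- list()
  relations <- list()
  for (sec in names(passage_plan)) {
    sents <- passage_plan[[sec]]
    texts <- purrr::map_chr(sents, "text")
    passage_text <- paste(texts, collapse = " ")
    local_off <- cumsum(c(0L, head(nchar(texts) + 1L, -1L)))
    for (i in seq_along(sents)) {
      s <- sents[[i]]
      base <- doc_offset + local_off[i]
      if (!is.null(s$records)) {
        rec <- s$records
        rec$doc_id <- doc_id
        rec$start <- rec$start + base
        rec$end <- rec$end + base
        mentions[[length(mentions) + 1L]] <- rec
      }
      if (!is.null(s$stars)) {
        st <- s$stars
        st$doc_id <- doc_id
        st$start <- st$start + base
        st$end <- st$end + base
        stars[[length(stars) + 1L]] <- st
      }
      if (!is.null(s$relations)) {
        rel <- s$relations
        rel$doc_id <- doc_id
        rel$sentence_section <- sec
        rel$sentence_start <- base
        rel$sentence_end <- base + nchar(s$text)
        rel$chemical_start <- rel$chemical_start + base
        rel$chemical_end <- rel$chemical_end + base
        rel$variant_start <- rel$variant_start + base
        rel$variant_end <- rel$variant_end + base
        relations[[length(relations) + 1L]] <- rel
      }
    }
    passages <- bind_rows(passages, tibble(
      doc_id = doc_id, section = sec, text = passage_text,
      title = title_text, journal = journal, year = year
    ))
    doc_offset <- doc_offset + nchar(passage_text) + 1L
  }
  list(
    passages = passages,
    mentions = if (length(mentions)) {
      bind_rows(mentions) |>
        select("doc_id", dplyr::everything())
    } else NULL,
    stars = if (length(stars)) bind_rows(stars) else NULL,
    relations = if (length(relations)) bind_rows(relations) else NULL
  )
}

#' Build the chemical allowlist table matching the synthetic lexicon
#'
#' @param lexicon a lexicon list (default the built-in one).
#' @return allowlist tibble (`mesh_id`, `name`, `categories`) covering the
#'   lexicon chemicals and decoys.
#' @export
synthetic_allowlist <- function(lexicon = default_lexicon()) {
  bind_rows(
    tibble(mesh_id = lexicon$chemicals$mesh_id,
           name = lexicon$chemicals$name,
           categories = lexicon$chemicals$categories),
    tibble(mesh_id = lexicon$decoy_chemicals$mesh_id,
           name = lexicon$decoy_chemicals$name,
           categories = lexicon$decoy_chemicals$categories)
  )
}

#' Cancer-associated chemical ids of the synthetic lexicon
#'
#' @param lexicon a lexicon list.
#' @return character vector of MeSH-style ids.
#' @export
synthetic_cancer_chemicals <- function(lexicon = default_lexicon()) {
  lexicon$chemicals$mesh_id[lexicon$chemicals$cancer]
}
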
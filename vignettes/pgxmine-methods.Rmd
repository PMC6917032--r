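---
title: "Mining chemical-variant pharmacogenomic associations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining chemical-variant pharmacogenomic associations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxmine)
library(dplyr)
```

## The problem

Pharmacogenomics knowledge bases are curated by hand: experts read papers
and record which genetic variants change a drug's efficacy, metabolism,
concentration, toxicity or resistance. The literature grows faster than
curation teams do, so a triage tool that ranks candidate chemical-variant
associations by literature support — and flags which are already curated —
directly reduces curator workload. `pgxmine` implements such a pipeline
for annotated biomedical text: documents plus offset-free named-entity
records (chemical, gene, variant) of the kind large-scale taggers emit.

The pipeline runs in fixed stages: align entity records to exact character
spans; detect and normalize star alleles after gene mentions; renormalize
variant mentions to HGVS-like forms and drop those without a specific
coordinate; select sentences co-mentioning a chemical and a variant,
gated by pharmacogenomic keywords; score each chemical-variant pair with
one of two logistic-regression relation classifiers; and collate accepted
pairs into associations ranked by distinct-paper count, flagged against a
knowledge-base snapshot.

## Text alignment

Annotation records name the mention substring but not its position, and
they are ASCII-translated relative to the article. `build_mention_pattern()`
turns a mention into a regular expression that is anchored at word
boundaries, maps any whitespace run in the mention to any whitespace run
in the text, lets each spelled-out Greek letter name (alpha..omega,
case-insensitive) match the Greek character as well, and escapes all
regex metacharacters (`*`, `(`, `.` and so on, which are common in
nomenclature such as `CYP2D6*2`).

Records are processed largest mention first so that no entity is mapped
strictly inside a larger entity; ties in length are broken
lexicographically for determinism. All match positions are annotated,
identical spans from different records are all kept, and records that
match nowhere are dropped with a per-document count — ASCII translation
makes occasional misses expected, so they are never fatal. Coordinates
are 0-based half-open over the document string formed by joining passages
with single newlines (the newline belongs to the preceding passage); no
convention is standard here, so the package fixes one and uses it
everywhere.

## Star alleles

Star alleles (`CYP2D6*2`, suballeles like `CYP2A6*4A`) are searched
immediately after aligned gene mentions: an asterisk followed by a token
beginning with a digit, with digits, letters and colons permitted (colons
capture HLA alleles). Lists continue through whitespace, `/`, `,`, `and`
and `or`, each allele introduced by its own asterisk; a separator not
followed by an asterisk ends the list. Whitespace between the gene and
the first asterisk is tolerated (`CYP2D6 *1` is common in print); the
normalization step removes whitespace anyway. The normalized form is
gene name + `*` + allele label with whitespace removed.

HLA alleles are renormalized by stripping whitespace, colons and leading
zeros from the label and reinserting colons between character pairs from
the left, so `HLA-B*05701` becomes `HLA-B*57:01`. For odd-length labels
after stripping, the final character is kept as a one-character field and
a warning is raised — such labels are suspicious and worth a curator's
eye. For knowledge-base comparison, suballele suffixes (trailing letters
after the final digit run) are stripped, `CYP3A5*3A` → `CYP3A5*3`; HLA
colon fields are not suballeles and are left alone. Both operations are
idempotent.

## Variant renormalization and filtering

Variant taggers emit heterogeneous surface forms. `classify_variants()`
recognises dbSNP identifiers (`rs` + digits, case-insensitive), protein
substitutions in one-letter, three-letter and `p.`-prefixed forms
(emitted as one-letter HGVS), and DNA substitutions with or without a
`c.`/`g.` prefix. When the record's normalized id carries an rs ID or a
pipe-delimited component string (`p|SUB|Q|192|R`), those parsed
components take precedence — prose mentions ("glutamine-to-arginine
mutation at residue 192") are resolved only through upstream components,
never re-parsed from surface text. A deliberate consequence: an
ambiguous one-letter form like `C3435T` is read as a protein substitution
unless upstream components say otherwise.

Mentions without a specific coordinate (e.g. `c.G>A`) cannot be matched
to any knowledge base and are dropped: a mention survives iff it has an
rs ID, is a star allele, or its HGVS form contains an integer position.
Coordinate-bearing indels and frameshifts are classified `other` but keep
their surface form as the HGVS string, so the same coordinate rule keeps
them. A configurable exclusion list removes terms that look like variants
but are not — `T47D` and friends are cell lines.

## Candidate sentences

Chemicals are restricted to an allowlist of drug-like ids; category
exclusion (amino acids, nucleotides, metals, excipients) is applied when
the allowed set is built. Mentions shorter than 4 characters are dropped
regardless — short tokens are dominated by tagger noise.

Sentences are segmented with an abbreviation-aware splitter (a
hand-curated list covering `i.e.`, `et al.`, `Fig.` and similar, plus
single-letter initials); segmentation quality is enforced by a fixture
suite rather than by mandating a specific tool. A sentence becomes a
candidate source iff it contains at least one surviving chemical and one
surviving variant and either contains a pharmacogenomic keyword or
mentions a dbSNP-kind variant. Specific rs IDs are strong signals on
their own, which is why they bypass the keyword gate; the gate exempts
only dbSNP-kind variants by default, with `exempt_kinds` available to
widen it to star alleles. Keywords match whole words case-insensitively;
a trailing `*` marks a prefix stem (`metaboli*`). Every (chemical,
variant) pair in an eligible sentence is one candidate; candidates whose
variant is an rs ID or star allele form group 1, the rest group 2 — the
two populations have very different base rates of true associations, so
they get separate classifiers. Cross-sentence relations are out of
scope.

## Relation classifiers

Each candidate is featurized with sparse counts: a bag of lower-cased
sentence tokens, the tokens lying strictly between the two entities (the
surface path — in biomedical prose the words that link a pair
syntactically almost always lie between them, so this plays the role
dependency-path features play in classic relation extractors), a
bucketed path length, entity order, and two-token windows flanking each
entity. Sentences that fail tokenization degrade to bag-of-words
features only.

The classifier is an L2-regularized logistic regression (glmnet ridge at
a single fixed penalty, `lambda = 0.01`, chosen once as a mild default
for sparse count features; no recalibration is applied because the raw
sigmoid output is what gets thresholded). Training is deterministic; the
seed only shuffles row order and is stored in the model metadata. Each
group's model keeps its own vocabulary — scoring ignores unseen features
— and the two vocabularies are never shared. No class reweighting is
applied by default: the keyword gate already performs the enrichment.
Train/test splits are stratified by label, recorded in metadata.

Negative findings ("X does not affect the metabolism of Y") are labeled
*positive*: a documented absence of effect is still a pharmacogenomic
finding a curator wants.

Scored candidates are accepted at `score >= 0.75` by default — a
high-precision/low-recall operating point appropriate for curation
triage, configurable per group. Before thresholding, candidates pairing
a cancer-associated chemical with a raw DNA/protein variant are removed:
such pairs are usually somatic tumour events, not germline
pharmacogenomics. rs-ID and star-allele candidates are never removed by
this rule.

## Collation and knowledge-base flags

Accepted rows carry document metadata (id, title, journal, year,
section) and an HTML-escaped sentence with the two entities wrapped in
`<b>` tags (escaping happens first, so the tags are the only markup).
Rows are collated by (chemical id, variant id, gene id) and ranked by
the number of distinct supporting papers, with deterministic
tie-breaking; gene identity participates in the key where present, so
the same rs ID reached through different genes stays separate. Compound
knowledge-base associations (several chemicals against one variant) are
unfolded to single pairs before comparison. Variant lookup tries the
suballele-stripped key and its star/rs equivalent (`POR*28` ↔
`rs1057868`); the association flag requires the (mapped chemical,
equivalent variant) pair itself, and implies both element flags. Three
files are written — unfiltered, filtered, collated — plus a manifest
with a config hash and stage-wise counts; the whole pipeline is a pure
function of its inputs and reruns byte-identically.

## The synthetic corpus

Because the real corpus, tagger output and annotation sets are external
moving targets, the package ships a seeded generator that emulates the
statistical structure the pipeline assumes: documents with
title/abstract (half with body sections), planted chemical/gene/variant
records *without* offsets, a configurable fraction of surface
perturbation (Greek letters and doubled whitespace in the text while the
record keeps the ASCII single-space form — exactly the mismatch ASCII
translation produces), star-allele list sentences cycling the separator
grammar, and decoys for every filter: sub-4-character chemicals,
disallowed-category chemicals, cell-line variant decoys, coordinate-free
variants, and cancer-chemical/protein-variant sentences. Relation
sentences are built from templates whose trigger phrasing is lexically
separable between positive and negative labels, and every template
contains a gate keyword, so all deterministic stage counts are exact
bookkeeping. Multi-entity sentences (2 chemicals × 2 variants) are
generated at a configurable count to exercise the classic failure mode
of pairing a drug with a variant from a different clause.

Default conditions: 20 documents, 30 positive and 30 negative relation
sentences split evenly between the two groups, 20% Greek/whitespace
perturbation, a handful of each decoy. The classifier experiments use
100 documents with 500 labeled candidates per group, split 400/100,
averaged over 5 seeds. These sizes were chosen as the smallest that
exercise every rule with stable statistics.

What passing synthetic tests does *not* show: robustness to real tagger
error distributions, to genuinely ambiguous prose (the templates are
separable by construction), to diplotype/haplotype notation (each allele
is emitted independently; genotype objects like `*1/*2` are not
modelled), or to cross-sentence associations. Real-corpus precision and
recall will be materially lower than the synthetic recovery numbers;
the synthetic suite verifies the machinery, not the ambient difficulty
of the literature.

## Worked example

```{r example}
out <- generate_corpus(corpus_config(seed = 1))
lab <- out$labeled_candidates
m1 <- train_relation_model(filter(lab, group == "group1"), "group1", seed = 1)
m2 <- train_relation_model(filter(lab, group == "group2"), "group2", seed = 1)
glance(m1)

dir <- file.path(tempdir(), "pgxmine-vignette")
res <- run_pipeline(pipeline_config(
  documents = out$corpus, annotations = out$annotations,
  model_group1 = m1, model_group2 = m2, out_dir = dir,
  allowlist = synthetic_allowlist(),
  cancer_chemicals = synthetic_cancer_chemicals(),
  pharmgkb = read_pharmgkb_table(pgx_extdata("synthetic_pharmgkb_snapshot.tsv"))
))
str(res$counts)
head(res$collated, 5)
```

```{r plot, fig.width = 6, fig.height = 3.5}
plot_top_associations(res$collated)
```

## Numerical and design notes

- Coordinates are 0-based half-open everywhere; spans always index the
  newline-joined passage concatenation the readers produce.
- Tie-breaks are deterministic by construction (lexicographic mention
  order in alignment; chemical name then variant id in collation), so
  outputs are reproducible byte for byte.
- The odd-length HLA field rule (keep the final singleton, warn) is a
  package decision for an input the nomenclature does not define.
- The keyword, exclusion and category lists ship as editable starter
  config files, not code; real deployments should curate them.
- The knowledge-base snapshot bundled under `extdata` is synthetic (see
  its filename) and exists so examples and tests run offline.
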
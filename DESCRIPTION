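Package: pgxmine
Title: Mining Chemical-Variant Pharmacogenomic Associations from Annotated Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A literature-mining pipeline that extracts pharmacogenomic
    associations between chemicals and genetic variants (dbSNP identifiers,
    star alleles, DNA- and protein-level substitutions) from annotated
    biomedical text. Offset-free entity annotations are aligned to document
    text with word-boundary-, whitespace- and Greek-letter-aware regular
    expressions; star alleles are detected after gene mentions and normalized
    (including HLA colon-field renormalization and suballele stripping);
    variant mentions are renormalized to HGVS-like forms and filtered to those
    with specific coordinates; candidate sentences co-mentioning a chemical
    and a variant are gated by pharmacogenomic keywords; two thresholded
    logistic-regression relation classifiers score candidates; and accepted
    relations are collated into ranked knowledge-base-flagged curator-facing
    tables. A seeded synthetic-corpus generator with planted ground truth
    exercises every stage without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
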
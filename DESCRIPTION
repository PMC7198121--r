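Package: bloomlink
Title: Privacy-Preserving Probabilistic Record Linkage with Bloom Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links person records across two files that share no unique
    identifier. Records are harmonized, grouped into candidate blocks by a
    disjunctive predicate, anonymized into 180-bit Bloom filters built from
    character bigrams, and scored with a normalized Sorensen-Dice index
    under either a full-filter or a hybrid per-attribute comparison scheme.
    Pairs are classified as match, non-match, or dubious via upper/lower
    score cutoffs with an iterative second round, and linkage accuracy is
    assessed against a gold standard (sensitivity, specificity, PPV, ROC).
    A synthetic-cohort generator with a configurable corruption model makes
    the whole pipeline testable without access to restricted person-level
    data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    stringi,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
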
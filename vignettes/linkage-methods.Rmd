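---
title: "Methods: privacy-preserving probabilistic linkage with bloomlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: privacy-preserving probabilistic linkage with bloomlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomlink)
```

## The linkage problem

Two files of person records must be joined without a shared unique
identifier, using five quasi-identifiers: full name, mother's full name,
date of birth, municipality of residence code, and gender. Both files may
carry typos, dropped name tokens, digit errors in dates, and missing
values, so exact joining fails and a similarity-based (probabilistic)
approach is needed. Additionally, the attribute values themselves are
sensitive, so the compared representation should be anonymized: the
comparing party sees bit vectors, not names.

## Pipeline

### Harmonization

Raw values are normalized so that equal identities render equal strings:
uppercase, Unicode transliteration to ASCII (accent stripping), every
non-alphanumeric run replaced by a single space, whitespace trimmed.
Dates are canonicalized to `YYYYMMDD`; the input dialect is configurable
(`iso` for year-first, `dmy` for day-first). Under `dmy` the canonical
form is also accepted, with a plausibility window on the year
(1850–2100) so that the day-first reading can never mis-swallow a
canonical string; this makes harmonization idempotent, which the test
suite asserts by property. Unparseable dates are set to missing with a
warning rather than failing the run: a corrupted date should cost one
attribute, not the record. Missing values use the empty string as
sentinel internally and empty cells in CSV artifacts.

### Blocking

Comparing all cross-product pairs is quadratic and infeasible at registry
scale, so candidate pairs are restricted to records agreeing exactly on
at least one clause of

```
(name AND mother_name AND municipality_code)
  OR (surname AND mother_surname AND year_of_birth)
```

The two clauses are deliberately error-disjoint: a typo in the name
breaks clause 1 but usually not clause 2 (only when it hits the surname
token), and a municipality change breaks clause 1 only. A clause with any
missing attribute emits no key — keying on sentinels would create one
giant junk block of all-missing records. Records emitting no key at all
are reported as unblockable. Clause keys are the harmonized values joined
with the `\x1f` unit separator, which cannot occur in harmonized text, so
keys are collision-free by construction. Co-blocking is identical-key
only; no sorted-neighbourhood or similar approximate grouping is
attempted. An optional `block_cap` drops oversized blocks with a warning;
the default is no cap, because with exact five-attribute keys blocks stay
small naturally.

### Bloom-filter anonymization

Each attribute value is padded with one leading and one trailing space
and decomposed into bigrams (consecutive character pairs), so a value of
`k` characters yields `k + 1` bigrams; padding makes the first and last
characters as informative as interior ones. Each distinct bigram `g` sets
positions

```
(H1(g) + i * H2(g)) mod m,   i = 0 .. num_hashes - 1
```

of that attribute's segment of length `m`. `H1` and `H2` are FNV-1a
32-bit digests of the bigram bytes under two different offset bases —
deterministic, seedless, portable, and well distributed at bigram scale;
double hashing from two base hashes is the standard construction for
Bloom-filter linkage. Per-attribute segments are concatenated (name 50,
mother's name 50, date of birth 40, municipality code 20, gender 20 bits;
180 total) rather than overlaid on one shared array, because both the
per-attribute weights and the hybrid comparison require separable
segments. Dates and municipality codes go through the same bigram
pipeline as digit strings; gender contributes its single-character code
(two padded bigrams). Bigrams are inserted per-distinct-value, without
positional numbering. Missing values encode as all-zero segments.

The encoding has no false negatives: equal harmonized values give
bit-identical segments. The converse does not hold — distinct values can
collide — which is precisely what makes the representation both
privacy-preserving and usable for approximate matching.

### Comparison

Similarity of two equal-length bit vectors is the Sørensen–Dice index
`2h/(a+b)`, normalized to an integer score in `[0, 10000]`
(round-half-up). When both vectors are all-zero the score is defined as 0
and flagged as both-missing. Two modes:

* **full** — one Dice score over the entire 180-bit composite.
* **hybrid** — name, mother's name and date of birth are scored per
  segment and classified exact (10000), strong ([9000, 10000)), weak
  ([8000, 9000)) or unpaired (< 8000); municipality code and gender are
  matched exactly on their segments (10000 or 0). The combined score is
  the mean of the five attribute scores weighted by bit budget
  (50/50/40/20/20), keeping hybrid scores on the same 0–10000 scale as
  full scores so one set of cutoffs serves both modes. The exact
  per-category acceptance rule table this weighted mean stands in for is
  an open design point; the weights are pluggable through
  `compare_pairs(weights = )`.

Attributes missing on *both* sides are excluded from the weighted mean
(weights renormalized): shared absence is no evidence for or against a
match. One-sided absence, by contrast, scores 0 for that attribute —
disagreement. This asymmetry is deliberate and flagged per pair in the
output.

In the test suite's corruption simulations the hybrid score exceeds the
full-composite score for the large majority of true pairs carrying one
name typo: the full Dice implicitly weights attributes by their set-bit
counts, which under-weights the always-clean low-cardinality categorical
attributes, while the hybrid rule restores their fixed weight.

### Classification

Scores are labelled by two cutoffs: match at or above the upper cutoff
(default 9400), non-match below the lower (default 8800), dubious in
between; a score exactly at the lower cutoff is dubious. The boundary
convention (upper accepts) was chosen so that the printed default 9400 is
itself an accepting threshold. A second round re-examines dubious pairs
with the band narrowed by `shift_step` (default 100) per round on both
sides, for `max_rounds` (default 2) rounds total; earlier rounds' labels
are never overturned, and if shifting would invert the band the iteration
stops with a warning. Accepted matches are finally deduplicated to a
one-to-one assignment by greedy descending-score selection with
lexicographic tie-breaks — deterministic and near-optimal at linear-plus-
sort cost, rather than an optimal assignment solver.

### Evaluation

Against a gold standard of known true pairs the package computes
TP/FP/TN/FN, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and PPV
`TP/(TP+FP)`; undefined ratios are reported as `NA` with an explanatory
note, never silent NaNs. Specificity is computed over the evaluated pair
universe — the candidate pairs plus the gold pairs — not the full cross
product, where true negatives would be astronomically dominant and
specificity pinned at 1. The ROC sweep classifies `score >= t` as
accepted for each threshold on a grid (default 8000–10000 in steps of
100, matching the granularity at which cutoffs are usually quoted) and
selects the best cutoff by Youden's J (sensitivity + specificity − 1),
breaking ties toward the higher threshold; an alternative criterion
maximizes PPV subject to a sensitivity floor. Selection by Youden's J is
this package's choice of an explicit criterion for what is often done
visually from ROC plots.

## The synthetic-data generator

`generate_cohort()` emulates a cohort/registry extract: multi-token
accented Brazilian-style names, a mother's name sharing the family
surname, 7-digit municipality-style codes from a small pool, birth dates
over 1940–2010, and raw rendering noise (mixed case, stray punctuation,
double spaces) that harmonization must absorb. File A holds `n` persons;
a configurable fraction reappears in file B under new ids, corrupted per
a `corruption_config`; file B also receives unrelated noise persons
(default 20% of `n`).

Corruption probabilities default to an administrative extract of middling
quality: one typo in 5% of name fields, 2% missingness per field, 1%
token drops, 2% date-digit errors, 1% gender flips and municipality
changes. Typos draw from an alphabet including accented letters, so
corruption also exercises the harmonizer. All randomness flows from one
seed; identical configs give byte-identical files.

What the generator does **not** emulate: real name-frequency
distributions, nicknames and name abbreviations, household co-residence
beyond the mother–child surname link, duplicate records within one file,
or systematically missing fields (missingness is independent per field).
Passing tests on this generator therefore show the pipeline's mechanics
are correct under a plausible error model, not that the default cutoffs
are optimal for any particular real registry — on real data the cutoff
band should be re-examined with the ROC tools.

## Numerical choices and problem sizes

* Score normalization rounds half up; all scores are integers in
  `[0, 10000]`.
* Hash arithmetic runs in doubles with explicit mod-2^32 reduction (R
  has no unsigned 32-bit type); intermediates stay far below 2^53.
* Candidate-pair generation, encoding and scoring are vectorized over
  whole columns/pair sets; a cohort of 5000 true pairs plus noise links
  in about a second on one core.
* The test suite validates blocking against an exhaustive cross-product
  oracle on cohorts of ≤ 200 records, the Dice kernel against a
  position-loop oracle on 10,000 random vector pairs, and the end-to-end
  accuracy claims on 20 replicate cohorts of 5000 true pairs (accepted-
  pair precision) and 250 true pairs (ROC cutoff-band recovery, with
  corruption calibrated — typo rate 0.5, date-digit rate 0.3 — so true
  pair scores concentrate just above the dubious band while false
  candidates stay far below it).

## Known limitations

* No phonetic encoding, string-edit comparators or EM-based match-weight
  estimation; similarity is entirely bigram/Bloom-based.
* Exact-agreement blocking can miss a true pair whose errors hit both
  clauses at once; the synthetic experiments quantify this as the main
  sensitivity loss at higher corruption.
* The Bloom encoding is anonymizing but not hardened: no salting, keyed
  hashing or formal re-identification-risk analysis is provided.
* The hybrid combination rule is a weighted mean, not a learned or
  hand-crafted decision table; it is the documented default, not the only
  defensible choice.
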
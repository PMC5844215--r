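---
title: "Mining SNP-disease associations from abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining SNP-disease associations from abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpminer)
```

## The extraction problem

A GWAS abstract compresses its findings into a handful of formulaic
sentences. The quantities a curator wants — the variant (a dbSNP rsID),
its significance (P-value), its effect size (odds ratio), the cohort
composition (patients, controls, population) — are present but written
in inconsistent surface forms: three different minus signs, exponents as
`× 10(−18)`, `×10^−9^` or `e-18`, P markers as `P`, `p-value`,
`combined P` or `Pmeta`, counts with or without thousands separators.
`snpminer` treats extraction as a normalisation problem followed by a
small set of deterministic coupling rules, rather than as a learned
task. That buys exact reproducibility and full offline testability at
the cost of the coverage a trained model might add.

## Pipeline model and assumptions

**Record filtering.** Only abstracts are analysed, never full text. A
record is usable when its abstract is at least `min_abstract_chars`
characters (default 50 — long enough to exclude title-only stubs, short
enough that any real abstract passes), its metadata language tag, when
present, is English, and at least one rsID occurs in the title or
abstract. The rules are applied in that order and the first failing
rule is reported per record. Records without a language tag are kept:
a false exclusion costs an abstract, a false inclusion merely yields
rows the user can discard. Scanning the title as well as the abstract
for the relevance filter is a deliberate choice; titles often carry the
only rsID mention of short reports.

**Linguistic analysis.** Downstream stages consume a fixed contract —
sentence spans, tokens, numeric-modifier arcs, nationality entities —
through `nlp_analyze()`. Two deterministic rule-based backends
implement it. The `"syntactic"` backend derives a numeric-modifier arc
for every integer token by attaching it to the last word of the
contiguous content-word run that follows (the noun-phrase head:
`889 lung cancer cases` → head `cases`), and recognises nationality
entities from a demonym lexicon of about one hundred single-token
surface forms (extensible via `snp_config(extra_demonyms = ...)`). The
`"minimal"` backend supplies sentences and tokens only. It exists so
that the purely textual stages (rsID recognition, statistic parsing,
pairing) can be exercised with no syntactic machinery at all; cohort
extraction degrades gracefully under it by deriving candidates directly
from integer tokens, with a surrogate head from the same
token-adjacency run. The surrogate head is what lets compound noun
phrases ("889 *lung cancer* cases") expose their quantified noun even
without arcs — a two-word window alone cannot reach a keyword three
words away. All offsets everywhere are 1-based inclusive character
positions into the original text, the R string idiom, so
`substr(text, start, end)` recovers every surface form; this invariant
is asserted across the test suite.

Sentence boundaries are terminal punctuation followed by whitespace.
No capitalisation is required after the boundary because abstracts
routinely open sentences with lowercase rsIDs or gene symbols; the cost
is an occasional split after abbreviations like "vs.", which is
harmless here because extraction never crosses sentences anyway.

**rsID recognition** is pure text processing: case-insensitive `rs`, at
most one intervening space, one or more digits. One trailing base
letter (A/C/G/T) immediately adjacent to the digits and followed by a
non-alphanumeric boundary is captured as the reported allele and
stripped from the id; the adjacency and boundary requirements stop the
rule from chewing into gene symbols, and a trailing digit can never be
taken for an allele because alleles are letters. Bracketed alleles
(`rs5770917[C]`) are left outside the match. Submitted-SNP `ss` ids are
deliberately not matched — they are provisional identifiers that the
association literature essentially never uses as the primary key.
Duplicate mentions of one rsID within a sentence are collapsed into a
group carrying all spans.

**Statistic parsing.** Sentences are rewritten to a canonical form
before parsing, with a per-character offset map back to the original:
exponent dialects become e-notation *before* bracket stripping (the
brackets of `10(−18)` are syntax, not noise), marker variants collapse
to `P` and `OR`, then quotes, brackets and emphasis asterisks are
removed. The statistic grammar accepts only marker-bound numbers — a
marker, a comparator (`=`, `<`, `>`, `≤`, `≥`), and a number carrying a
decimal point or exponent. Two consequences are intended: bare integers
and thousands-separated counts are never statistic values, and in
"P = 0.045 and 0.032" only 0.045 is parsed, because the second number
has no marker. This is a known, reproduced failure mode of the
marker-bound design, not an accident; it trades recall on enumerated
values for precision everywhere else. Parsed values above 1 for P are
kept but flagged, since malformed texts exist. Spans of parsed values
are mapped back to original coordinates, so distance measurements and
evidence display always refer to the un-normalised sentence.

**Coupling.** Within a sentence, P-values and odds ratios are paired to
SNP groups independently, by the same two-regime procedure with
separate consumption pools:

* *Broadcast*: exactly one pairable value of the kind → every SNP group
  receives it. This reflects the common "rs1 and rs2 were associated
  (P = x)" pattern; it is also the source of known false positives when
  an author actually meant only one of the variants.
* *Nearest-unconsumed*: SNP groups in first-mention order each take the
  unconsumed value with the smallest character gap between nearest span
  edges (minimum over the group's mentions); consumed values are never
  reused. Character distance, not token distance, is used because token
  counts vary across tokenisers while character offsets do not. Ties
  prefer the value following the SNP, matching the dominant reporting
  style (statistic after variant).

Threshold values — `<`/`≤` comparators — are excluded from pairing when
equality values of the same kind coexist in the sentence; a sentence
whose only values carry `<` keeps them pairable, because many papers
report exact associations that way. This conditional rule is what
resolves the six-SNP worked example: the leading genome-wide threshold
is skipped and all six printed values land on their variant.

**Cohort extraction.** Candidates are numeric-modifier dependents that
parse as integers (thousands separators accepted, decimals rejected).
Each candidate's context — head token plus up to two word tokens on
each side — is matched against the keyword sets, case- and
plural-insensitively. Control keywords take precedence when both sets
match one candidate: "312 healthy subjects" is a control hit even
though "subject" is a patient stem. The first hit per set in abstract
order wins, which selects stated totals ("A total of 169 ED patients")
over subgroup breakdowns given later in parentheses. Ethnicity is a
frequency vote over nationality entities of at least
`min_nationality_chars` characters (default 4: long enough to drop
acronym noise, short enough to keep "Thai"), ties broken by earliest
occurrence; religious or political labels sharing the entity category
are not filtered by list — the majority vote is relied on instead.
Cohort fields are reported per abstract and copied onto every
association row from it.

**Scoring.** A prediction matches a gold annotation iff PMID and rsID
agree and every value present in the gold record agrees within relative
tolerance `rel_tol` (default 1e-6, covering float-formatting
differences, config-overridable). Matching is greedy over gold in input
order and one-to-one. Value agreement is required — a wrong-value
coupling is an error, not a hit — because mis-paired statistics are
precisely the failure mode worth measuring. Precision and recall are
defined as 0 on an empty denominator; F1 is 0 when both are 0.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `nlp_backend` | `"syntactic"` | linguistic backend (`"minimal"` for token-only) |
| `patient_keywords` | patient, case, subject | stems for the patient-group size |
| `control_keywords` | control, normal, healthy | stems for the control-group size |
| `min_nationality_chars` | 4 | length floor for ethnicity labels (characters) |
| `p_markers` | 14 variants | P-marker lexicon, extensible |
| `rel_tol` | 1e-6 | relative tolerance for gold matching |
| `retmax` | 3000 | PMIDs requested per query |
| `min_abstract_chars` | 50 | usable-abstract length floor (characters) |

The P-marker lexicon is deliberately a superset of the variants seen in
practice and is config-extensible, since no closed inventory of marker
spellings exists.

## The synthetic generator

`generate_synthetic_abstracts()` emulates exactly the conventions the
extractor targets: association sentences in three templates (single SNP
with optional OR; two SNPs with two values and "respectively"; two SNPs
sharing one value), P-values drawn log-uniformly in [1e-30, 0.05] and
rendered in a random dialect, ORs in [0.2, 3.5], a patients/controls
sentence, a nationality sentence, and distractors (a genome-wide
threshold sentence, bare counts, gene symbols). Every planted
association is listed in a gold table; generation is byte-deterministic
for a fixed seed and restores the caller's RNG state. An optional noise
mode plants the marker-less second value ("P = a and b"), which by
construction costs exactly one false negative per planted sentence.

What the generator does *not* emulate — and therefore what passing its
tests does not show about real abstracts: cross-sentence references,
range-valued P ("P = 0.01–0.03"), non-rsID variant nomenclature
(protein-level or HGVS forms), free-order clause structure, OCR noise,
and cohort descriptions spread over several sentences. Perfect recovery
on the synthetic corpus demonstrates the internal consistency of the
rules, not corpus-level performance; published-sentence worked examples
carry that part of the validation.

## Numerical and degenerate-input choices

* Distance is measured between nearest span edges in original-sentence
  coordinates; overlapping spans count as distance 0.
* Canonical rendering of a parsed value (`render_stat_value()`) prints
  enough digits for an exact double round-trip, and re-parsing is
  asserted to reproduce value and comparator exactly.
* Empty text analyses to zero sentences; sentences with no statistics,
  no mentions, or neither produce no pairs; records missing a sort key
  always sort last regardless of direction; rsid/pmid sort numerically
  by digit part.
* Duplicate PMIDs keep the first record with a warning; articles
  without a PMID are skipped with a warning.
* Floats in tabular output are rendered as `%.6e` (six significant
  decimal digits), read back to within 1 ulp at that precision.

## Problem sizes used by the test suite

The property-based checks run at sizes chosen to make the asserted
properties meaningful while keeping the suite fast on one CPU: 1000
random pairing instances (up to 5 SNP groups × 5 values) against a
brute-force sequential-consumption oracle; planted-truth recovery over
seeds 1–20 with 50 abstracts per seed, asserting aggregate precision
and recall of exactly 1.0; and 300 generated rsID mentions embedded in
filler text, asserting 100% recall of the recognition pattern.

## Known limitations

* Associations are extracted within single sentences only; a SNP named
  in one sentence and its statistic in the next are not linked.
* Range-valued P-values are not parsed (logged and skipped).
* The broadcast rule produces false positives when a single value
  genuinely applies to only one of several mentioned SNPs.
* Confidence or negation classification (positive/negative/neutral
  association) is out of scope; every reported value is surfaced and
  judgement is left to the reader, which is the design intent.
* The demonym lexicon is finite; population labels outside it are
  invisible to ethnicity extraction unless added via configuration.
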
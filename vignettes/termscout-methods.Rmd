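---
title: "Mining candidate search terms: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining candidate search terms: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termscout)
```

## The objective approach

Boolean search strategies for systematic reviews combine free-text
terms and controlled vocabulary (MeSH in PubMed/MEDLINE). The
*objective approach* derives those terms statistically from a *test
set* of records already known to be relevant, instead of brainstorming
them purely conceptually: terms that occur in the test set far more
often than in the database at large are good candidates for the
query.

termscout implements this as a comparison of document frequencies.
For a term occurring in $x$ of the $n$ test-set records, and with
probability $p_0$ of occurring in a random database record (estimated
from a *population set*, a random background sample of records), the
overrepresentation statistic is the normal approximation of the
binomial test, without continuity correction:

$$ z = \frac{x - n\,p_0}{\sqrt{n\,p_0\,(1 - p_0)}} $$

The uncorrected one-sample proportion score is the standard reading of
"normal approximation of a binomial distribution" and is what
commercial text-analysis tools report on the same data. Two sentinels
make the statistic total:

* a term **absent from the population set** cannot be tested and is
  maximally interesting — it receives $z = 10000$ and is always a
  candidate;
* a term present in **every** population record ($p_0 = 1$) gets
  $z = 0$ when $x = n$ and is otherwise clamped to $-10000$. This case
  cannot arise from a real corpus of any size worth using; the rule
  exists so the function is deterministic on degenerate inputs.

Terms with $z \ge 20$ are flagged as candidates. The cut-off is an
empirically established working threshold for this methodology, not a
significance level; it is exposed as `analysis_config(z_cutoff = )`.

## The term definition

A free-text term is a word **without hyphens**, **without Unicode
symbol or punctuation characters**, and that is **not a number**.
Concretely, `tokenize_freetext()`:

1. splits on whitespace and on the hyphen/dash inventory U+002D,
   U+2010–U+2015 and U+2212 (PubMed exports contain U+2010 and U+2013
   in practice), so "self-aware" becomes the two terms "self" and
   "aware" — matching how the major search platforms index hyphenated
   words;
2. strips characters of the Unicode `S*` and `P*` categories;
3. drops pieces consisting solely of decimal digits (after step 2 has
   removed signs and group separators). "p53", "cd4" and "40mg" are
   kept: they are not numbers;
4. folds case to lower. Case folding is our decision — it is required
   for frequency merging, and on-screen term lists in this field are
   conventionally lower-case. Diacritics and non-Latin letters (Greek
   β, µ-prefixed units) are left untouched; they are ordinary letters
   under this definition, which is precisely where this tokenizer is
   *stricter* than older commercial tools that silently drop them.

No stop-word list is applied: common words are ranked down naturally
by their z-scores, and hiding them would contradict the "all
identified terms are displayed" contract. `filter_rare()` is a pure
view filter (terms in fewer than 2 records **or** under 10 % of
records), never applied silently before export.

## Vocabularies and their tables

Keywords are parsed as `[*]descriptor[/qualifier]`: the leading `*`
(major topic) is stripped and recorded but not used in the v1 tables;
the first `/` separates the qualifier. Three tables partition the
material:

* **MeSH table** — descriptors found in the MeSH dictionary; counted
  once per record, so document frequency equals term frequency and the
  term-frequency column is omitted;
* **qualifier table** — subheadings (e.g. "therapy") found in the
  dictionary; these can attach to several descriptors in one record,
  so term frequency is reported separately. A listed qualifier counts
  even when its descriptor is unknown — the qualifier's evidential
  value does not depend on the descriptor being in our dictionary
  version;
* **all-keywords table** — every raw keyword string verbatim
  ("Neoplasms/diagnosis" and "Neoplasms/therapy" stay distinct), with
  plain frequencies and no z-scores. Non-MeSH keywords appear only
  here.

The dictionary is pluggable (`read_mesh_dictionary()` for plain-text
name lists, `read_mesh_xml()` for NLM descriptor XML); the bundled
`mini_mesh_dictionary()` is a ~30-descriptor synthetic miniature for
tests and examples, not a MeSH release. MeSH matching is
case-insensitive but reports the dictionary's casing.

Population counts are kept in three matched maps (free text, MeSH,
qualifier) so controlled-vocabulary z-scores use controlled-vocabulary
nulls. A population file missing a section loads with an empty map and
a warning; every term scored against an empty map receives the 10000
sentinel — loud, deliberate, and visible in the output.

## Splitting, reproducibility

`split_records()` draws a 2:1 development/validation partition.
Development size is `round_half_up(2n/3)` (the ratio statement leaves
rounding open; half-up is the least surprising rule). The PRNG is
pinned by the package — Mersenne-Twister with inversion and rejection
sampling, the R ≥ 3.6 sampling algorithm — rather than inherited from
the session, so a reported seed reproduces the split bit-identically
across platforms. Seeds from other implementations of this workflow
use different PRNG streams and will not reproduce here.

PMID lists are rendered for Ovid as `"(id1 or id2 or …).ui."` — the
unique-identifier field with lowercase connectors. The exact string
convention is ours; it is stated here because screenshots of the
interactive tools that inspired it are not machine-readable.

## Context views

`kwic()` tokenizes the query with the same term definition as the
tables, so "decision-making" and "decision making" are the same
2-token query; matches are contiguous token runs within a field, and
the context window (default 2 words) truncates at title/abstract
boundaries. Blank fields render as `NO_TITLE`/`NO_ABSTRACT`.

`skipgram_table()` counts ordered 2-word combinations per occurrence
(not per record): every token pair with at most `max_skip` (default 2)
intervening words, within a field. Direction matters — "shared making"
is a skip-1 gram of "shared decision making"; "making shared" is not
counted. No sentence segmentation is applied: a pair may straddle a
sentence boundary inside an abstract. That is the simplest
deterministic rule; segmenting would change counts only for windows
spanning sentence ends, and proximity operators in the target search
platforms do not respect sentence boundaries either.

## CSV export

The export dialect mirrors the Western European CSV convention:
semicolon field separator, comma decimal separator, CRLF. A standard
dialect (comma/dot/LF) is available. Reals are written with 4 decimal
places (display precision is an export decision; full precision is
kept internally), the 10000 sentinel prints as a bare integer, and
fields containing the separator are quoted. Headers are the on-screen
column names ("Candidate terms", "Documents", "Documents in %",
"Z-Score", "Term frequency").

## The synthetic generator, and what tests do and don't show

`generate_records()` builds records whose titles and abstracts are
space-joined samples from a planted vocabulary (per-record inclusion
probability, Poisson-shifted repeat counts), with keywords drawn from
a planted MeSH pool. It returns the **realized** counts alongside the
records, so table tests assert exact equality instead of statistical
closeness. The generator emulates the frequency structure the
analysis consumes — document and occurrence counts, overrepresented
terms, MeSH/qualifier combinations — and deliberately does not emulate
English prose, sentence structure, or PubMed's field conventions
beyond the RIS tags. Passing tests therefore demonstrate the counting,
scoring, splitting and round-trip machinery, not linguistic robustness
on real abstracts; the tokenizer's Unicode behaviour is covered
separately by property tests over adversarial random strings.

Test and acceptance runs use deliberately small corpora (record sets
of 5–30, population files of a few hundred): the statistics are
closed-form, so problem size adds confidence only through variety,
which the 100-seed property suites provide more cheaply.

The bundled acceptance script (`scripts/acceptance.R`) mines a
30-record synthetic test set against a 300-record synthetic
population. Under those conditions the term planted only in the test
set gets the 10000 sentinel and is the reliably flagged candidate,
while the strongest population-backed planted term reaches z ≈ 18–19
— just below the 20 cut-off, a realistic illustration that the
threshold is demanding at development-set sizes around 20.

## Known limitations

* Truncation/stemming, phrase ranking beyond raw frequency, Boolean
  recall of term *combinations*, and MeSH tree "explode" are out of
  scope; only single-term relative recall (= documents %) is shown.
* Precision and accuracy cannot be estimated: there is no set of
  known-irrelevant records in the workflow.
* The population builder counts whatever corpus it is given; sampling
  a fresh random background from a live database is the user's task
  (any RIS export works), and the quality of the z-scores is bounded
  by how representative that sample is.
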
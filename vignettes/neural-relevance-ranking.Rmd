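---
title: "Neural relevance ranking for biological record search: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural relevance ranking for biological record search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioranker)
```

## The ranking problem

A trait-centred search over biological fact databases returns records —
protein entries, ontology terms, genome annotations — whose usefulness to the
searcher depends on much more than lexical overlap with the query. This
package ranks each hit by a learned function of eleven per-hit properties
rather than by a single lexical statistic. The pipeline is:

1. tokenize and index all record attributes positionally;
2. expand the query (synonyms, optional spelling corrections);
3. extract an 11-dimensional feature vector per candidate hit;
4. score it with a feed-forward neural network trained on five-class graded
   user feedback;
5. present results with excerpts and evidence-sorted gene-annotation links.

A TF–IDF cosine ranker over the same index serves as the comparison baseline
throughout.

## Tokenization and indexing

Tokens are lowercased maximal alphanumeric runs of length ≥ 2; no stemming.
This keeps short gene symbols ("wus") intact while discarding single digits
from identifiers like EC numbers. Each attribute of each record is indexed
independently, with 0-based token positions, so that per-attribute features
(coverage, proximity, keyword context) are computable and excerpts can be
addressed. Ties in every ranking are broken by ascending record identifier,
which makes all orderings total and reproducible.

The baseline uses document weights `tf · (1 + ln(N/df))`, unit query weights,
and cosine similarity; records with score zero are omitted. This is the
classical vector-space formulation; it is deliberately simple enough to be
verified against brute-force dense-vector computation in the tests, and is
not a bug-for-bug clone of any particular search library's scoring.

## Query assistance

*Spelling.* Suggestions are vocabulary terms within restricted
Damerau–Levenshtein distance 1 (query terms of ≤ 4 characters) or 2 (longer
terms), ranked by distance, then collection frequency, then lexicographic
order. Transpositions are counted as single edits because adjacent-key and
letter-swap typos dominate misspelled biological terms. Corrections are
suggested, never silently applied: a corrected term enters the query only
when the caller opts in.

*Synonyms.* Expansion is one level deep (no transitive closure), each token
becoming an OR-group of itself plus its table synonyms; multi-word synonyms
match as contiguous token sequences. Synonym tables come from two-column TSV
or OBO 1.2 `[Term]` stanzas (`name:` + `synonym: "…"` lines; scope tags
ignored). Which lists to load is entirely the user's choice — no ontology
cross-products are computed.

*Hit estimation.* The "expected results" count uses AND-over-groups,
OR-within-group semantics — the tightest interpretation of an expanded
keyword query — while the candidate set that is actually ranked is the union
of records matching any group, so that partially matching records can still
be surfaced (their coverage feature reflects the missing groups).

## The eleven features

Each hit is summarised by eleven values in [0, 1], in fixed order:

| # | feature | definition |
|---|---------|------------|
| 1 | attribute_weight | configured weight of the best-matching attribute (0.5 if unmapped) |
| 2 | database_weight | configured weight of the source database (0.5 if unmapped) |
| 3 | term_frequency | occurrences of all query terms in the record ÷ record token count |
| 4 | cooccurrence | m / span of the minimal window covering all m matched terms; × 0.8 if no minimal window has them in query order |
| 5 | keyword_context | (1 + good − bad)/2 for good/bad keywords within 5 tokens of a match |
| 6 | organism_match | 1 query and record organism agree; 0 both named but differ; 0.5 either silent |
| 7 | sequence_length_norm | min(1, log10(1+len)/log10(1+Lmax)), 0 when absent; Lmax = 100 000 |
| 8 | text_position_coverage | distinct matched positions ÷ matched-attribute token count |
| 9 | synonym_origin | 1 if at least one exactly typed term matched, 0 for synonym-only hits |
| 10 | query_coverage | fraction of query term groups matched anywhere in the record |
| 11 | idf_weight | mean over matched terms of ln(N/df)/ln(N) (0 if N ≤ 1) |

Features 1–9 are the classical per-hit properties of this kind of engine
(attribute, database, frequency, co-occurrence, keyword, organism, sequence
length, text position, synonym). The stated input dimensionality of the
ranker is eleven, while only nine properties are enumerated by name in the
feature model; the identity of the remaining two is not recoverable, so this
implementation completes the vector with two standard IR signals — query
coverage and mean IDF — and documents them as extensions. They are ordinary
components of the vector and can be swapped out without touching the network
architecture.

Two scalar-encoding choices keep the input at exactly eleven: categorical
properties (attribute, database, organism) enter through configured weight
lookups rather than one-hot encodings, and the organism feature treats
"silent on either side" as the neutral 0.5 rather than a missing value.
Organism detection uses a small alias taxonomy (common names, genus/species
epithets for barley, Arabidopsis, rice, maize by default) — no named-entity
recognition. The synonym feature scores exact evidence 1 and synonym-only
evidence 0, since hits that exist only through expansion warrant lower
confidence. Term frequency is normalized by record length so the feature is
bounded and insensitive to trivial duplication (self-concatenating a record
changes neither it nor the coverage feature — a tested invariant).

## The neural ranker

The scoring network is feed-forward, 11 → 16 → 8 → 1, with a sigmoid at
every layer, so scores live strictly inside (0, 1). Training minimises mean
squared error by full-batch gradient descent with backpropagation; weights
initialise uniformly on [−0.5, 0.5] from a seeded generator. The original
engine's loss, optimiser and training regime are not documented anywhere,
so the simplest deterministic, testable choices were made here; learning
rate (default 0.5) and epochs (default 1500) are configurable. The
correctness anchor is a gradient check: analytic gradients must match
central-difference numerical gradients (h = 10⁻⁵) to < 10⁻⁶ relative error
over 100 random configurations.

Graded feedback maps to targets by equal spacing on [0, 1] in the printed
class order — no relevance 0, undecided 0.25, could be of relevance 0.5,
minor quality doubts 0.75, fully agree 1. Equal spacing is itself a design
decision (the class set is ordinal, not metric); any monotone mapping would
preserve the ranking semantics. Feedback is stored as an append-only TSV of
(profile, query, record, label, timestamp) and retraining is explicit —
there is no online learning. One network per named user profile, persisted
as a single JSON document with full-precision weights so that reload is
bit-exact.

## Annotation links

Mapping files (3-column TSV: gene, record, evidence) link genes to
annotation records. For a hit, *direct* links point at the hit record itself
and *indirect* links at records one cross-reference hop away — deeper
transitivity is deliberately excluded as unbounded and ambiguous. Links sort
direct-first, then by evidence class HC > LC > N/A, then by gene identifier;
a blank evidence column reads as N/A. Whether direct and indirect links
should instead interleave by evidence is unspecified in the engine this
models; segregation by directness was chosen so the nearest evidence is
always visible first.

## Evaluation protocol

The benchmark is a fixed set of 20 trait-centred keyword queries (shipped as
`inst/extdata/benchmark_queries.tsv`) spanning trait, biological-entity,
taxonomy, affiliation, metabolic and regulatory query classes. For each
query, up to 20 judged results are sampled seeded and without replacement —
20 × 20 = 400 judgments, matching the protocol's published size; the
original per-query quota and rank range were not stated, so uniform sampling
with quota 20 is a declared decision, not a reconstruction. Judged items
split 50/50 into a training and a held-out half; the network trains on the
training half and both rankers score the held-out half.

Separation is summarised two ways: per-class five-number summaries (the
boxplot view; type-7 sample quantiles) and the Mann–Whitney AUC of
"no relevance" versus all other classes, with ties counted ½ — a
threshold-free statistic that a brute-force pair count verifies in the
tests.

## The synthetic test bed

Real corpora of the original engine are living external databases, so every
experiment here runs on seeded synthetic corpora with *planted* graded
signal. For each benchmark query, records are generated in one of five
classes; a higher class raises, on average: the fraction of query terms
planted (0.30 → 0.90 by class), the probability the terms appear as one
contiguous in-order phrase (0.10 → 0.90), organism agreement with the query
(0.10 → 0.90), the probability of landing in the curated database
(0.10 → 0.70) and the first (highest-weighted) attribute (0.20 → 0.80), the
odds of a good rather than bad context keyword (0.10 → 0.90), mean log10
sequence length (1.0 → 4.2), and annotation evidence quality. A `noise`
parameter (default 0.1) shrinks all class profiles toward their means.
Filler text is drawn from a deterministic consonant-vowel pseudo-word
vocabulary that cannot collide with query terms, and every generated record
contains at least one query term so the whole class spectrum is retrievable
and judgeable.

These defaults were chosen once as a plausible graded-relevance landscape:
class signal is present in both lexical features (visible to TF–IDF) and
non-lexical features (invisible to it), which is precisely the structural
claim behind a feature-based neural ranker — and what the class-separation
experiment measures. What the generator does *not* emulate: real annotation
prose (no grammar, no entity structure), realistic vocabulary distributions
(no Zipf tail), inter-record redundancy, or database-scale corpora. Passing
tests therefore demonstrate that the implementation recovers planted signal
under the stated conditions, not that the trained network transfers to live
databases.

Problem sizes used by the test suite and the acceptance script: corpora of
1000 records (60–240 for unit fixtures, 4000 for generator statistics),
400 sampled judgments, 200 training examples, 1500 training epochs, five
seeds for the separation experiment. The full pipeline — generate, index,
extract, train, evaluate — completes in a few seconds per seed on one CPU.

## Numerical choices and degenerate inputs

* Ties everywhere break by ascending record identifier; shuffle-invariance
  is tested for annotation links.
* The minimal-window search enumerates candidate windows anchored at matched
  positions; when several minimal windows exist, the in-order bonus applies
  if *any* of them presents the terms in query order.
* Cosine values are clamped at 1 against floating-point overshoot on
  identical vectors; score equality in rankings is exact double comparison.
* Empty queries estimate 0 hits; a record with no match gets the no-match
  feature defaults (zeros for match-derived features, 0.5 for categorical
  unknowns) rather than an error.
* An empty training set returns the network unchanged; a non-finite loss
  aborts training; a user-supplied learning rate that increases the loss
  warns rather than fails.
* The XLSX exporter writes the workbook container itself (stored, CRC-32
  checked entries; inline strings) so exports carry exactly the CSV cell
  values; the CSV form is canonical and round-trips scores at full double
  precision via `%.17g` rendering.

## Known limitations

* The two extension features are principled but not canonical; with other
  choices the network input would differ while everything else stands.
* The TF–IDF baseline is one classical variant, not a faithful clone of any
  production scorer's normalisations.
* Organism matching depends entirely on the loaded alias taxonomy.
* Full-batch training on large feedback sets is O(examples × epochs); the
  intended regime is hundreds to thousands of judgments.
* The evaluation harness judges only records with known gold labels, which
  is the honest option on synthetic corpora but differs from pooling-based
  judgment collection on live systems.
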
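---
title: "Textual forma mentis networks: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Textual forma mentis networks: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfmn)
```

## The model

A textual forma mentis network (TFMN) approximates the organisation of
concepts in the mental lexicon of the authors of a text collection. Nodes
are stemmed content words; links come in two layers:

* a **syntactic layer**: within each sentence, dependency arcs among
  content words after *function-word contraction* — determiners,
  adpositions, auxiliaries, conjunctions, punctuation and non-negation
  particles are deleted as nodes and their dependency neighbours bridged
  pairwise, so chains of function words collapse into direct content
  links;
* a **synonym layer**: undirected links between corpus stems listed as
  synonyms in a user-supplied lexicon. The layer never introduces nodes
  that the corpus did not produce.

The two layers carry no weights and no inter-layer links, so every
distance-based measure here operates on the **aggregate graph** (the
simple union of the layers), to which multiplex closeness is equivalent.

Two modelling commitments deserve emphasis:

* **Negation is lexicalised.** The particle "not" survives contraction as
  a node. Downstream, concepts adjacent to "not" contribute their antonyms
  to emotional profiles, so "bias is not support" is read with both
  `support` and its listed antonym in scope.
* **Stemming happens at the network level.** Edges are extracted on
  lemmas, then endpoints are replaced by Porter stems and collapsed. The
  package implements the Porter (1980) algorithm directly
  (`porter_stem()`); it is deterministic, and its idempotence over the
  working vocabularies is enforced by tests. Any other deterministic
  stemmer can be passed wherever a `stemmer` argument appears.

## Valence and emotion labels

Word valence scores (any continuous scale) are averaged over words sharing
a stem, and stems are labeled by **quartiles of the stem-level
distribution**: strictly above the 75th percentile positive, strictly
below the 25th negative, otherwise neutral. Percentiles use linear
interpolation between order statistics (R's default type 7); ties fall to
neutral. These strict inequalities make the labeling conservative and
deterministic — with all-equal scores everything is neutral. Labeling
requires at least 4 stems, below which quartiles are not meaningful for a
three-way split.

Stems absent from the norms are kept in the graph as `unknown`: they count
as neutral in valence auras (an unrated neighbour is not evidence of
polarity) and are excluded from positive-versus-negative statistics, since
user-supplied norms cannot be assumed to cover the corpus.

The emotion lexicon maps words to subsets of the eight basic emotions.
Because network nodes are stems while emotion lexicons list surface forms,
lookups try the surface form first and fall back to the stemmed key.

## Cognitive measures

**Closeness.** `closeness_eq()` computes c(i) = N / Σ d_ij with N the size
of i's connected component; this component-size numerator is the package's
primary definition, with the conventional (N−1)/Σd available behind
`variant = "conventional"`. Scores from components of different sizes are
not comparable, so `closeness_ranking()` ranks only the largest connected
component. Ranking ties are broken lexicographically, making outputs
reproducible. Singleton components have Σd = 0; their score is flagged
undefined rather than coerced to 0.

**Valence aura.** The distribution of valence labels over a node's
neighbours and their mode; exact ties yield `mixed` rather than an
arbitrary winner.

**Emotional profile and flower.** For a frame (a focus word's
neighbourhood, or its Louvain community), the contributing set is the m
*distinct* words eliciting at least one emotion; fraction(e) is the share
of contributing words eliciting e. Fractions do not sum to 1 — a word may
elicit several emotions. The null model draws m words uniformly **without
replacement** from the emotion lexicon's eligible vocabulary (frames are
sets of distinct words, so a without-replacement draw matches the unit of
observation), 1,000 times by default, and z-scores standardise the
observed fractions. Significance is declared at z ≥ 1.96, the convention
of flower charts where the rejection disc has radius 1.96; this is
one-sided in practice and slightly conservative. When an emotion never
varies under the null (sd = 0) its z is reported as undefined and never
significant. `m = 0` frames yield a flagged profile, not an error.

## Null models and the benchmark

**Configuration model.** `rewire_configuration()` randomises a graph by
attempted double-edge swaps (10 × |E| attempts) that forbid self-loops and
multi-edges, preserving the exact degree sequence. Graphs whose degree
sequence has a unique simple realisation (stars, triangles) are returned
unchanged — a property the tests exploit. `null_clustering()` summarises
mean local clustering (degree < 2 contributes 0) over independent
rewirings.

**Topic benchmark.** `run_benchmark()` builds one TFMN per topic, takes
the top-k (default 10) closeness concepts, and measures their distance to
the topic on an independent reference association network. The null
re-runs the *entire ranking pipeline* on rewired graphs — reshuffling
links breaks the coupling between structure and meaning, so re-deriving
the ranking (rather than resampling words) is the null the comparison
needs. Empirical and pooled null distances are compared with a two-sided
Mann–Whitney location test. Distances are pooled per word across topics;
ranked words missing from the reference (or unreachable from the topic)
are skipped and counted, never imputed.

**Mann–Whitney.** Implemented in-package: exact two-sided p by enumeration
of all group assignments when m + n ≤ 10 (correct under ties), otherwise
the normal approximation with tie correction. `stats::wilcox.test` serves
as an independent cross-check in the tests, not as the implementation,
because it does not enumerate exactly in the presence of ties.

## Fixtures: what the generators emulate, and what they do not

`make_mini_lexicons()` plants valence classes sized so that quartile
labeling recovers them exactly (class bands [1,2], [4,6], [8,9]; specs
whose quartile positions land on a class boundary are rejected as
infeasible), emotion tags hitting exact per-emotion base rates with
unequal rates across emotions, and synonym pairs within a class /
antonym pairs across classes. `make_topic_corpus()` emits per-topic
documents of simple copular clauses ("the TOPIC is ASSOCIATE") plus a
reference network wiring associates at distance 1 from their topic and
fillers at distance 3. Defaults — 3 topics × 5 documents, 10 associates
and 15 fillers per topic, 40 valence words, 200 emotion words, 1,000 null
repetitions, 50 configuration-model realisations, top-10 rankings, 3-word
admission filter — are the study conditions all tests and the acceptance
script run under; they were fixed once, at sizes a desk-scale replication
of this design would use.

All vocabulary is pseudo-words verified to be their own Porter stems, so
surface forms, stems and reference vertices coincide. That is also the
generators' main departure from real data: fixture grammar is tiny
(SVO/copular clauses, determiners, prepositional phrases, negation), there
is no polysemy, no misspelling, no hashtag culture, and parsing is exact.
Passing tests therefore demonstrate the correctness of the machinery —
contraction, stemming, labeling, nulls, test statistics — not the
linguistic coverage of the bundled parser on natural text. Real corpora
should route through a proper UD parser supplied as `backend=`; the
rule-based `fallback_parse()` tags unknown tokens as nouns and never
fails, which is the right degradation for a fixture backend but not a
substitute for a trained parser.

## Numerical and degeneracy choices

* Quartiles: type-7 linear interpolation; strict inequalities; ties
  neutral.
* Duplicate valence rows: last wins, with a warning naming the words.
* Cleaning strips URLs, `#`/`@` marker characters (keeping the token
  text; `strip_mentions = TRUE` removes handles entirely — corpora differ
  on whether mentions are content), and pictographic codepoints; it is
  idempotent. Documents need ≥ 3 whitespace tokens after cleaning.
* The naive sentence splitter cuts after every `.`, `!`, `?` (so "Dr.
  Smith works." is two sentences); backends with real sentence splitting
  should split upstream.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; JSON artifacts contain a settings block and no
  timestamps, so equal seeds give byte-identical files.
* Louvain is run on a seeded permutation of vertices and mapped back,
  pinning down an otherwise order-dependent heuristic.

## Known limitations

* The bundled parser's closed verb list is small; out-of-list verbs parse
  as nouns, which preserves connectivity but can misdirect arcs. This is
  by design: fixtures must be deterministic, real parsing is pluggable.
* Quartile labeling on small vocabularies (tens of stems) is sensitive to
  single scores near the hinges; the generators avoid the hinges by
  construction, real lexicons should be large.
* Emotional-profile significance at z ≥ 1.96 is a fixed-threshold
  convention, not a multiple-comparison-corrected test across eight
  emotions.
* Reference-network distances treat all links as equally informative;
  weighted association strengths are out of scope.
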
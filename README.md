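# tfmn — textual forma mentis networks

`tfmn` reconstructs the *mindset* expressed by a collection of short texts
(tweets, paragraphs, survey answers) as a **textual forma mentis network
(TFMN)**: a multiplex lexical network whose nodes are stemmed concepts and
whose links are (i) syntactic dependencies extracted sentence by sentence
and (ii) synonym relations. Each concept carries a valence label
(positive / neutral / negative) from psycholinguistic norms, and network
neighbourhoods — *semantic frames* — are profiled for the eight basic
emotions (anger, anticipation, disgust, fear, joy, sadness, surprise,
trust) against a sampling null model.

It is aimed at cognitive network science and computational social science
work: quantifying how concepts such as "woman", "science" or "gap" are
framed in online discourse, which associates surround them, and whether
those associates carry more emotion than chance expectation.

## The method

**Construction.** Every sentence is dependency-parsed; function words
(determiners, prepositions, auxiliaries, conjunctions) are *contracted*:
removed as nodes and replaced by links between their content-word
neighbours. "love is weakness" yields the link love–weakness; "the cat sat
on the chair" links cat and chair through the content verb *sit*. Edges
are merged across sentences after network-level stemming ("weak" and
"weakness" become one node), a synonym layer is added between corpus
stems, and each stem is labeled by the quartile of its mean valence score:
above the 75th percentile positive, below the 25th negative, the
interquartile range neutral.

**Measures.** Semantic prominence is component-wise closeness centrality

c(i) = N / Σ_j d_ij

with N the size of i's connected component and d_ij the shortest-path
distance on the aggregate (syntactic + synonym) graph. A concept's
*valence aura* is the modal valence label among its neighbours. The
*emotional profile* of a frame is, per emotion, the fraction of frame
words eliciting it (concepts linked to "not" also contribute their
antonyms); it is standardised against the profile of m words sampled
uniformly from the emotion lexicon (1,000 repetitions), and emotions with
z ≥ 1.96 exceed chance — the petals of the "emotional flower". Structure
is benchmarked against degree-preserving configuration models: clustering
above the null, and a topic-relevance test in which top-10 closeness
concepts from per-topic networks sit closer to their topic on an
independent free-association reference network than the same statistic on
rewired networks (Mann–Whitney location test over 50 realisations).

Lexicon files (valence norms, word–emotion associations, synonym and
antonym pairs) are user-supplied two-column TSVs; licensed resources such
as full valence norms or WordNet exports are not redistributed here. A
deterministic rule-based dependency parser and seeded fixture generators
(mini-lexicons, planted-topic corpora with a matching reference network)
make the whole pipeline runnable offline; any UD-style parser can be
plugged in as a backend function.

## Worked example

```r
library(tfmn)
lex <- load_lexicons("valence.tsv", "emotions.tsv",
                     "synonyms.tsv", "antonyms.tsv")
docs <- c("the woman is a scientist. science is a career.",
          "women in science need support",
          "the gender gap is a problem. bias is not support.",
          "girls can work in science")
tfmn <- assemble_tfmn(docs, lex)
tfmn
#> <tfmn> 14 stemmed concepts, 12 links (11 syntactic + 1 synonym)
#>  valence: negative=2, neutral=4, positive=3, unknown=5
```

14 stems survive cleaning, contraction and stemming; the synonym link is
work–career, planted in the synonym lexicon and present in the corpus.
Closeness ranks the semantically prominent concepts:

```r
closeness_ranking(tfmn, k = 5)
#>      stem closeness
#> 1    need 0.6428571
#> 2  scienc 0.6000000
#> 3 support 0.5294118
#> 4    work 0.4736842
#> 5  career 0.4500000
```

How is "science" perceived? Its aura is the valence mix of its
neighbours, and its frame's emotional flower flags emotions above chance:

```r
valence_aura(tfmn, "scienc")$fractions
#>  positive   neutral  negative
#> 0.3333333 0.6666667 0.0000000
pr <- profile_concept(tfmn, "scienc", lex, reps = 1000, seed = 42)
pr$flower
#> <emotional_flower> z >= 1.96 marks significance
#>        anger anticipation      disgust         fear          joy ...
#>        -0.46         2.05        -0.46        -0.42        -0.70
#> significant: anticipation
```

Here one frame word (career) elicits anticipation, more than a random
1-word draw from this tiny emotion lexicon would (z = 2.05); emotions the
lexicon never lists (surprise) get an undefined z rather than a
significance claim.

The topic-relevance benchmark runs on a directory of per-topic documents
plus a reference association network (`run_benchmark()`), or from the
shell via the thin wrapper:

```sh
Rscript inst/cli/tfmn.R fixtures --out fx --seed 3
Rscript inst/cli/tfmn.R benchmark --input fx/topics --lexicons fx \
        --reference fx/reference.tsv --out bench --seed 3
```

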
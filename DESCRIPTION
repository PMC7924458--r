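Package: tfmn
Title: Textual Forma Mentis Networks from Short-Text Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multiplex lexical networks (textual forma mentis
    networks) from corpora of short documents: dependency parsing with
    function-word contraction, network-level stemming, a WordNet-style
    synonym layer, and quartile-based valence labels from psycholinguistic
    norms. Provides the cognitive measures used to read such networks:
    component-wise closeness centrality, valence auras, emotional profiles
    with a uniform-sampling null model ("emotional flowers"),
    configuration-model clustering comparisons, Louvain semantic frames,
    and a closeness-ranking topic-relevance benchmark against a reference
    free-association network. Ships deterministic fixture generators and a
    rule-based fallback dependency parser so the whole pipeline runs
    offline.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Encoding: UTF-8
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
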
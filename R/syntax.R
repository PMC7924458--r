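# Coarse POS classes whose tokens are contracted away: they connect content
# words but carry no lexical meaning of their own. The negation particle is
# the one PART kept as a node.
REMOVAL_POS <- c("ADP", "AUX", "DET", "PART", "PUNCT", "CCONJ", "SCONJ",
                 "SYM", "X")
NEGATION_LEMMAS <- c("not", "n't")

#' Parse a sentence into a dependency graph
#'
#' Thin dispatcher over a pluggable parser backend. A backend is a function
#' taking one sentence and returning a `depgraph`: a list with `tokens`
#' (data.frame: index, surface, lemma, pos — pos in the Universal
#' Dependencies coarse tag set) and `edges` (data.frame: head, dep, rel —
#' token indices plus relation label). The package ships [fallback_parse],
#' a deterministic rule-based backend, so the pipeline runs offline.
#'
#' @param sentence a single non-empty sentence.
#' @param backend parser backend function (default [fallback_parse]).
#' @return a `depgraph` object.
#' @export
parse_dependencies <- function(sentence, backend = fallback_parse) {
  if (length(sentence) != 1L || is.na(sentence) || !nzchar(trimws(sentence))) {
    stop("cannot parse an empty sentence", call. = FALSE)
  }
  if (!is.function(backend)) {
    stop("parser backend unavailable; pass a backend function, ",
         "e.g. backend = fallback_parse", call. = FALSE)
  }
  backend(sentence)
}

#' Contract function words out of a dependency graph
#'
#' Tokens whose POS is in the removal set (adpositions, auxiliaries,
#' determiners, conjunctions, punctuation, symbols, non-negation particles)
#' are deleted and their dependency neighbours bridged pairwise, so chains
#' of function words collapse: in "love is weakness" the copula disappears
#' and love–weakness remains; in "the cat sat on the chair" the preposition
#' is contracted so cat and chair connect through the verb. The negation
#' particle ("not"/"n't") is kept as a node.
#'
#' @param dep a `depgraph` (see [parse_dependencies]).
#' @return `content_edges`: a 2-column character matrix of unordered,
#'   unique lemma pairs (no self-pairs).
#' @export
contract_function_words <- function(dep) {
  tok <- dep$tokens
  n <- nrow(tok)
  if (n == 0L) return(empty_edges())
  lemma <- ifelse(is.na(tok$lemma) | !nzchar(tok$lemma),
                  tolower(tok$surface), tolower(tok$lemma))
  lemma[lemma %in% "n't"] <- "not"
  remove <- tok$pos %in% REMOVAL_POS & !(lemma %in% NEGATION_LEMMAS)

  # adjacency over token indices
  adj <- vector("list", n)
  if (nrow(dep$edges)) {
    for (r in seq_len(nrow(dep$edges))) {
      h <- dep$edges$head[r]; d <- dep$edges$dep[r]
      if (h == d) next
      adj[[h]] <- c(adj[[h]], d)
      adj[[d]] <- c(adj[[d]], h)
    }
  }
  adj <- lapply(adj, unique)

  # delete removed nodes one at a time, bridging their neighbours pairwise;
  # chains of removed nodes collapse transitively
  for (v in which(remove)) {
    nb <- setdiff(adj[[v]], v)
    for (u in nb) adj[[u]] <- setdiff(unique(c(adj[[u]], nb)), c(u, v))
    adj[[v]] <- integer(0)
  }

  keep <- which(!remove)
  pairs <- list()
  for (u in keep) {
    for (w in adj[[u]]) {
      if (w > u) pairs[[length(pairs) + 1L]] <- c(lemma[u], lemma[w])
    }
  }
  if (!length(pairs)) return(empty_edges())
  m <- do.call(rbind, pairs)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m <- unique(m[m[, 1] != m[, 2], , drop = FALSE])
  colnames(m) <- c("a", "b")
  m
}

empty_edges <- function() {
  matrix(character(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
}

#' Stem the endpoints of content edges
#'
#' Replaces edge endpoints by their stems ("network-level stemming"), drops
#' edges whose endpoints collapse onto the same stem, and merges duplicates.
#'
#' @param edges 2-column character matrix of lemma pairs.
#' @param stemmer stemming function (default [porter_stem]).
#' @return 2-column character matrix of unordered unique stem pairs.
#' @export
stem_edges <- function(edges, stemmer = porter_stem) {
  if (nrow(edges) == 0L) return(empty_edges())
  a <- stemmer(edges[, 1]); b <- stemmer(edges[, 2])
  m <- cbind(pmin(a, b), pmax(a, b))
  m <- unique(m[m[, 1] != m[, 2], , drop = FALSE])
  colnames(m) <- c("a", "b")
  m
}
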
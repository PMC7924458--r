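#' Load a reference association network
#'
#' Reads an undirected word network (e.g., a free-association network) from
#' a TSV edge list (word<TAB>word; `#` comments allowed). Vertices are
#' stored as stems so TFMN rankings and the reference can be matched.
#'
#' @param path TSV edge list path.
#' @param stemmer stemming function.
#' @return a simple undirected igraph on stems.
#' @export
load_reference_network <- function(path, stemmer = porter_stem) {
  p <- read_tsv2(path, "reference network")
  reference_network(cbind(tolower(p$v1), tolower(p$v2)), stemmer)
}

#' Build a reference network from an in-memory edge list
#'
#' @param edges 2-column character matrix of word pairs.
#' @param stemmer stemming function.
#' @return a simple undirected igraph on stems.
#' @export
reference_network <- function(edges, stemmer = porter_stem) {
  a <- stemmer(edges[, 1]); b <- stemmer(edges[, 2])
  keep <- a != b
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]),
                                   directed = FALSE)
  igraph::simplify(g)
}

#' Distances from ranked words to their topic on a reference network
#'
#' BFS distance on the reference network between each ranked word (stem)
#' and the topic. The topic itself is excluded; ranked words absent from
#' the reference, and words unreachable from the topic, are skipped and
#' counted in the `skipped` attribute.
#'
#' @param ranked_words character vector of stems (e.g., a top-k closeness
#'   ranking).
#' @param reference igraph reference network on stems.
#' @param topic topic stem; must be in the reference.
#' @return integer vector of distances (>= 1), with attribute `skipped`.
#' @export
topic_distances <- function(ranked_words, reference, topic) {
  vn <- igraph::V(reference)$name
  if (!topic %in% vn) {
    stop("topic '", topic, "' absent from reference network", call. = FALSE)
  }
  words <- setdiff(unique(ranked_words), topic)
  present <- intersect(words, vn)
  skipped <- length(words) - length(present)
  if (length(present) == 0L) {
    out <- integer(0)
    attr(out, "skipped") <- skipped
    return(out)
  }
  d <- as.numeric(igraph::distances(reference, v = topic, to = present))
  reachable <- is.finite(d)
  skipped <- skipped + sum(!reachable)
  out <- as.integer(d[reachable])
  attr(out, "skipped") <- skipped
  out
}

#' Null distribution of topic distances from randomised networks
#'
#' For each configuration-model realisation, every per-topic network is
#' rewired (degrees preserved), the top-k closeness ranking re-derived on
#' the rewired graph, and the ranked words mapped to reference distances.
#' All realisations' distances are pooled. Reshuffling links breaks the
#' coupling between network structure and meaning, so these distances are
#' the chance level the empirical ranking is compared against.
#'
#' @param tfmns named list topic -> `tfmn` (or igraph aggregate).
#' @param reference igraph reference network on stems.
#' @param k ranking depth (default 10).
#' @param realizations number of rewirings (default 50).
#' @param seed RNG seed.
#' @return integer vector of pooled null distances, attribute `skipped`.
#' @export
null_topic_distances <- function(tfmns, reference, k = 10,
                                 realizations = 50, seed = 1L) {
  if (realizations < 1) stop("realizations must be >= 1", call. = FALSE)
  graphs <- lapply(tfmns, function(x)
    if (inherits(x, "tfmn")) aggregate_graph(x) else x)
  topics <- names(tfmns)
  pooled <- integer(0); skipped <- 0L
  with_seed(seed, {
    for (r in seq_len(realizations)) {
      for (tp in topics) {
        rg <- rewire_once(graphs[[tp]])
        rk <- closeness_ranking(rg, k = k)
        d <- topic_distances(rk$stem, reference, tp)
        pooled <- c(pooled, d)
        skipped <- skipped + attr(d, "skipped")
      }
    }
  })
  attr(pooled, "skipped") <- skipped
  pooled
}

#' Topic-relevance benchmark of forma mentis networks
#'
#' The validation pipeline: one TFMN is built per topic from its documents;
#' the top-k concepts by closeness are extracted; their distances to the
#' topic are measured on an independent reference association network; the
#' same is done for degree-preserving randomisations of each network; and a
#' Mann-Whitney location test compares empirical against null distances.
#' If TFMN centrality picks up topic-relevant concepts, empirical distances
#' sit closer to the topic than the null.
#'
#' @param documents_by_topic named list topic -> character vector of raw
#'   documents (topic names must resolve in the reference after stemming).
#' @param lexicons a `lexicon_bundle`.
#' @param reference igraph reference network on stems.
#' @param k ranking depth (default 10).
#' @param realizations configuration-model realisations (default 50).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @param backend parser backend (default [fallback_parse]).
#' @return a `benchmark_result`: list with `empirical_distances`,
#'   `null_distances`, `U`, `p`, `median_empirical`, `median_null`,
#'   `significant`, `realizations`, `k`, `skipped`.
#' @export
run_benchmark <- function(documents_by_topic, lexicons, reference,
                          k = 10, realizations = 50, alpha = 0.05,
                          seed = 1L, backend = fallback_parse) {
  if (realizations < 1) stop("realizations must be >= 1", call. = FALSE)
  if (length(documents_by_topic) == 0L) {
    stop("no topics provided", call. = FALSE)
  }
  stemmer <- lexicons$stemmer
  topics <- stemmer(tolower(names(documents_by_topic)))
  vn <- igraph::V(reference)$name
  if (!all(topics %in% vn)) {
    stop("topic(s) absent from reference network: ",
         paste(setdiff(topics, vn), collapse = ", "), call. = FALSE)
  }
  tfmns <- lapply(documents_by_topic, assemble_tfmn, lexicons = lexicons,
                  backend = backend)
  names(tfmns) <- topics

  emp <- integer(0); emp_skip <- 0L
  for (tp in topics) {
    rk <- closeness_ranking(tfmns[[tp]], k = k)
    d <- topic_distances(rk$stem, reference, tp)
    emp <- c(emp, d)
    emp_skip <- emp_skip + attr(d, "skipped")
  }
  null <- null_topic_distances(tfmns, reference, k = k,
                               realizations = realizations, seed = seed)
  mw <- mann_whitney_u(emp, as.integer(null))
  structure(list(empirical_distances = as.integer(emp),
                 null_distances = as.integer(null),
                 U = mw$U, p = mw$p,
                 median_empirical = median(emp),
                 median_null = median(null),
                 significant = mw$p < alpha,
                 realizations = realizations, k = k,
                 skipped = c(empirical = emp_skip,
                             null = attr(null, "skipped"))),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n",
      " empirical: n = ", length(x$empirical_distances),
      ", median distance = ", x$median_empirical, "\n",
      " null     : n = ", length(x$null_distances),
      ", median distance = ", x$median_null,
      " (", x$realizations, " realizations)\n",
      " Mann-Whitney U = ", x$U, ", two-sided p = ",
      format(x$p, digits = 4),
      if (x$significant) "  (significant)" else "", "\n", sep = "")
  invisible(x)
}
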
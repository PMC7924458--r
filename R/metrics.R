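#' Shortest-path distance between two concepts
#'
#' Minimum number of links connecting `i` and `j` on an undirected graph
#' (any layer counts on an aggregate graph). Unreachable pairs give `Inf`.
#'
#' @param graph an igraph.
#' @param i,j vertex names.
#' @return a non-negative number, possibly `Inf`.
#' @export
shortest_path_distance <- function(graph, i, j) {
  vn <- igraph::V(graph)$name
  if (!i %in% vn || !j %in% vn) {
    stop("node absent from graph: ", if (!i %in% vn) i else j, call. = FALSE)
  }
  as.numeric(igraph::distances(graph, v = i, to = j))
}

#' Closeness centrality within a connected component
#'
#' Computes the component-wise closeness c(i) = N / sum_j d_ij, where N is
#' the size of i's connected component and the sum runs over the component.
#' This is the variant used throughout; the conventional
#' (N-1)/sum_j d_ij is available via `variant = "conventional"`. For a
#' singleton component the score is undefined (`defined = FALSE`).
#'
#' @param graph an igraph.
#' @param i vertex name.
#' @param variant "component-size" (default) or "conventional".
#' @return list with `node`, `value`, `component_size`, `sum_distance`,
#'   `defined`.
#' @export
closeness_eq <- function(graph, i,
                         variant = c("component-size", "conventional")) {
  variant <- match.arg(variant)
  if (!i %in% igraph::V(graph)$name) {
    stop("node absent from graph: ", i, call. = FALSE)
  }
  comp <- igraph::components(graph)
  members <- names(comp$membership)[comp$membership ==
                                      comp$membership[[i]]]
  N <- length(members)
  if (N < 2L) {
    return(list(node = i, value = NA_real_, component_size = N,
                sum_distance = 0L, defined = FALSE))
  }
  d <- igraph::distances(graph, v = i, to = members)
  sumd <- as.integer(sum(d))
  num <- if (variant == "component-size") N else N - 1L
  list(node = i, value = num / sumd, component_size = N,
       sum_distance = sumd, defined = TRUE)
}

#' Closeness ranking of the most central concepts
#'
#' Ranks nodes of the aggregate graph's largest connected component by
#' component-wise closeness (scores across different components are not
#' directly comparable, so only the largest component is ranked).
#' Descending score; ties broken lexicographically by stem.
#'
#' @param x a `tfmn` object or an igraph.
#' @param k how many top concepts to return (default 10); `k` larger than
#'   the component returns the full ranking.
#' @param variant see [closeness_eq].
#' @return data.frame with columns `stem`, `closeness`, ordered.
#' @export
closeness_ranking <- function(x, k = 10, variant = "component-size") {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  g <- if (inherits(x, "tfmn")) aggregate_graph(x) else x
  if (igraph::vcount(g) == 0L) stop("graph is empty", call. = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- names(comp$membership)[comp$membership == big]
  sub <- igraph::induced_subgraph(g, members)
  N <- length(members)
  d <- igraph::distances(sub)
  sums <- rowSums(d)
  num <- if (variant == "component-size") N else N - 1L
  val <- if (N < 2L) setNames(NA_real_, members) else num / sums
  nm <- igraph::V(sub)$name
  o <- order(-val, nm)
  head(data.frame(stem = nm[o], closeness = unname(val[o]),
                  row.names = NULL), k)
}

#' Valence aura of a concept
#'
#' Fractions of positive / neutral / negative labels among the aggregate
#' neighbours of `focus` ("unknown" labels count as neutral), and the modal
#' label; ties give aura "mixed".
#'
#' @param tfmn a `tfmn` object.
#' @param focus a stem with at least one neighbour.
#' @return list with `focus`, `fractions` (named numeric summing to 1),
#'   `aura`, `n_neighbors`.
#' @export
valence_aura <- function(tfmn, focus) {
  g <- aggregate_graph(tfmn)
  if (!focus %in% igraph::V(g)$name) {
    stop("focus '", focus, "' is not a node of the network", call. = FALSE)
  }
  nb <- igraph::neighbors(g, focus)$name
  if (length(nb) == 0L) {
    stop("focus '", focus, "' is isolated; aura undefined", call. = FALSE)
  }
  lab <- tfmn$valence[nb]
  lab[lab == "unknown"] <- "neutral"
  fr <- table(factor(lab, levels = c("positive", "neutral", "negative")))
  fractions <- as.numeric(fr) / length(nb)
  names(fractions) <- names(fr)
  top <- names(fractions)[fractions == max(fractions)]
  list(focus = focus, fractions = fractions,
       aura = if (length(top) > 1L) "mixed" else top,
       n_neighbors = length(nb))
}

#' Mean local clustering coefficient
#'
#' Average of per-node local clustering over all nodes; nodes of degree
#' below 2 contribute 0.
#'
#' @param graph an igraph.
#' @return value in [0, 1].
#' @export
mean_clustering <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("graph is empty", call. = FALSE)
  loc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  mean(loc)
}

#' Degree-preserving rewiring (configuration model)
#'
#' Randomises a graph by attempted double-edge swaps (10 x |E| attempts),
#' keeping the exact degree sequence and forbidding self-loops and
#' multi-edges. Graphs whose degree sequence admits a unique simple
#' realisation (stars, triangles) come back unchanged.
#'
#' @param graph an igraph with at least 2 edges.
#' @param seed RNG seed.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @return a rewired igraph on the same vertices.
#' @export
rewire_configuration <- function(graph, seed, swaps_per_edge = 10) {
  with_seed(seed, rewire_once(graph, swaps_per_edge))
}

rewire_once <- function(graph, swaps_per_edge = 10) {
  igraph::rewire(graph,
                 igraph::keeping_degseq(loops = FALSE,
                                        niter = swaps_per_edge *
                                          igraph::ecount(graph)))
}

#' Clustering of configuration-model null graphs
#'
#' Mean and standard deviation of [mean_clustering] over independent
#' degree-preserving rewirings of `graph`.
#'
#' @param graph an igraph.
#' @param realizations number of rewirings (>= 2).
#' @param seed RNG seed.
#' @return list with `mean`, `sd`, `realizations`, `values`.
#' @export
null_clustering <- function(graph, realizations = 50, seed = 1L) {
  if (realizations < 2) stop("need at least 2 realizations", call. = FALSE)
  vals <- with_seed(seed, vapply(seq_len(realizations), function(i)
    mean_clustering(rewire_once(graph)), numeric(1)))
  list(mean = mean(vals), sd = sd(vals), realizations = realizations,
       values = vals)
}

#' Louvain community detection
#'
#' Modularity-based Louvain partition on the undirected graph. Node order
#' is shuffled under the seed and the membership mapped back, making runs
#' reproducible.
#'
#' @param graph an igraph.
#' @param seed RNG seed.
#' @return named integer vector: node -> community id.
#' @export
detect_communities <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0L) stop("graph is empty", call. = FALSE)
  with_seed(seed, {
    perm <- sample(igraph::vcount(graph))
    g2 <- igraph::permute(graph, perm)
    cl <- igraph::cluster_louvain(g2)
    m <- igraph::membership(cl)
    m[igraph::V(graph)$name]
  })
}

#' Compare degree and closeness between positive and negative concepts
#'
#' Mann-Whitney location tests of aggregate-graph degree (all labeled
#' nodes) and component-wise closeness (largest component) between
#' positive- and negative-valence nodes. Unknown-valence nodes are
#' excluded.
#'
#' @param tfmn a `tfmn` object.
#' @return list with per-measure medians, U and two-sided p, plus class
#'   sizes.
#' @export
valence_class_comparison <- function(tfmn) {
  g <- aggregate_graph(tfmn)
  lab <- tfmn$valence
  pos <- names(lab)[lab == "positive"]
  neg <- names(lab)[lab == "negative"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("need at least one positive and one negative concept",
         call. = FALSE)
  }
  deg <- igraph::degree(g)
  mw_deg <- mann_whitney_u(deg[pos], deg[neg])

  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- names(comp$membership)[comp$membership == big]
  sub <- igraph::induced_subgraph(g, members)
  N <- length(members)
  clo <- N / rowSums(igraph::distances(sub))
  names(clo) <- igraph::V(sub)$name
  cp <- clo[intersect(pos, members)]
  cn <- clo[intersect(neg, members)]
  mw_clo <- if (length(cp) && length(cn)) mann_whitney_u(cp, cn) else NULL

  list(n_positive = length(pos), n_negative = length(neg),
       degree = list(median_positive = median(deg[pos]),
                     median_negative = median(deg[neg]),
                     U = mw_deg$U, p = mw_deg$p),
       closeness = if (is.null(mw_clo)) NULL else
         list(median_positive = median(cp), median_negative = median(cn),
              U = mw_clo$U, p = mw_clo$p))
}

#' Valence class frequency summary of a corpus
#'
#' After cleaning and stemming, counts content-token occurrences
#' (token_count) and distinct stems (type_count) per valence class.
#' Function words (determiners, adpositions, auxiliaries, conjunctions) are
#' excluded; stems without a valence label are reported separately under
#' `unknown`.
#'
#' @param corpus a `corpus` object or character vector of documents.
#' @param labelmap a `valence_labels` object ([assign_valence_labels]).
#' @param stemmer stemming function.
#' @return data.frame with rows positive/neutral/negative and columns
#'   `type_count`, `token_count`; attribute `unknown` holds the counts of
#'   unlabeled stems.
#' @export
valence_frequency_summary <- function(corpus, labelmap,
                                      stemmer = porter_stem) {
  if (is.character(corpus)) corpus <- as_corpus(corpus)
  fw <- c(FW_DET, FW_ADP, FW_AUX, FW_CCONJ, FW_SCONJ)
  toks <- character(0)
  for (doc in corpus) {
    t <- tolower(strsplit(doc$cleaned, "\\s+")[[1]])
    t <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", t)
    t <- t[nzchar(t) & !t %in% fw]
    toks <- c(toks, t)
  }
  classes <- c("positive", "neutral", "negative")
  if (length(toks) == 0L) {
    out <- data.frame(class = classes, type_count = 0L, token_count = 0L)
    attr(out, "unknown") <- c(type_count = 0L, token_count = 0L)
    return(out)
  }
  stems <- stemmer(toks)
  lab <- labelmap$labels[stems]
  known <- !is.na(lab)
  out <- data.frame(
    class = classes,
    type_count = vapply(classes, function(cl)
      length(unique(stems[known][lab[known] == cl])), 1L),
    token_count = vapply(classes, function(cl)
      sum(lab[known] == cl), 1L),
    row.names = NULL)
  attr(out, "unknown") <- c(type_count = length(unique(stems[!known])),
                            token_count = sum(!known))
  out
}

#' Mann-Whitney U test
#'
#' U statistic for sample `x` against `y` (number of (x, y) pairs with
#' x > y, plus half the ties) with a two-sided p-value: exact by
#' enumeration of all group assignments when m + n <= 10 (ties included),
#' otherwise a normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m <- length(x); n <- length(y)
  u_stat <- function(xs, ys) {
    sum(vapply(xs, function(v) sum(v > ys) + 0.5 * sum(v == ys),
               numeric(1)))
  }
  U <- u_stat(x, y)
  mu <- m * n / 2
  if (m + n <= 10L) {
    pool <- c(x, y)
    idx <- combn(m + n, m)
    us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    N <- m + n
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, n_x = m, n_y = n, method = method)
}
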
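#' Assemble a textual forma mentis network from a corpus
#'
#' Runs the three construction stages over every sentence of every admitted
#' document: (1) dependency parsing and function-word contraction into
#' content-word edges, (2) network-level stemming and union across
#' sentences and documents into the syntactic layer, enriched with a
#' synonym layer restricted to stems present in the corpus, and (3) valence
#' labels (positive / neutral / negative by quartile of the stem-level norm
#' distribution; "unknown" for stems absent from the norms).
#'
#' @param corpus a `corpus` object (see [read_corpus], [as_corpus]) or a
#'   character vector of raw documents.
#' @param lexicons a `lexicon_bundle` from [load_lexicons] or
#'   [make_mini_lexicons].
#' @param backend parser backend (default [fallback_parse]).
#' @return a `tfmn` object: list with `nodes` (character stems), `valence`
#'   (named character labels incl. "unknown"), `edges` (data.frame: from,
#'   to, layer in {"syntactic","synonym"}), and `labelmap` (the
#'   `valence_labels` object used).
#' @export
assemble_tfmn <- function(corpus, lexicons, backend = fallback_parse) {
  if (is.character(corpus)) corpus <- as_corpus(corpus)
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  stemmer <- lexicons$stemmer

  syn_edges <- empty_edges()
  for (doc in corpus) {
    for (s in doc$sentences) {
      dep <- parse_dependencies(s, backend)
      ce <- contract_function_words(dep)
      syn_edges <- rbind(syn_edges, stem_edges(ce, stemmer))
    }
  }
  syn_edges <- unique(syn_edges)
  if (nrow(syn_edges) == 0L) {
    warning("no content-word pairs could be extracted; network is empty",
            call. = FALSE)
  }
  nodes <- sort(unique(c(syn_edges[, 1], syn_edges[, 2])))

  syno <- synonym_layer(nodes, lexicons$synonyms, stemmer)

  stem_table <- stem_aggregate_valence(lexicons$valence, stemmer)
  labelmap <- assign_valence_labels(stem_table)
  valence <- labelmap$labels[nodes]
  valence[is.na(valence)] <- "unknown"
  names(valence) <- nodes

  edges <- rbind(
    if (nrow(syn_edges)) data.frame(from = syn_edges[, 1],
                                    to = syn_edges[, 2],
                                    layer = "syntactic"),
    if (nrow(syno)) data.frame(from = syno[, 1], to = syno[, 2],
                               layer = "synonym"))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        layer = character())
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, valence = valence, edges = edges,
                 labelmap = labelmap),
            class = "tfmn")
}

#' Synonym layer over a fixed node set
#'
#' Adds an undirected synonym edge for every synonym pair whose two stems
#' are both already nodes; the layer never introduces new nodes.
#'
#' @param nodes character vector of stems.
#' @param syn 2-column character matrix of synonym word pairs.
#' @param stemmer stemming function.
#' @return 2-column character matrix of unordered unique stem pairs.
#' @export
synonym_layer <- function(nodes, syn, stemmer = porter_stem) {
  if (is.null(syn) || nrow(syn) == 0L) return(empty_edges())
  a <- stemmer(syn[, 1]); b <- stemmer(syn[, 2])
  keep <- a != b & a %in% nodes & b %in% nodes
  if (!any(keep)) return(empty_edges())
  m <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
  colnames(m) <- c("a", "b")
  m
}

#' Aggregate graph of a multiplex network
#'
#' Collapses the syntactic and synonym layers into one simple undirected
#' igraph, the graph all distance-based measures run on (the layers carry
#' no weights or inter-layer links, so multiplex closeness equals
#' single-layer closeness on this aggregate).
#'
#' @param tfmn a `tfmn` object.
#' @return an igraph with vertex attribute `valence`.
#' @export
aggregate_graph <- function(tfmn) {
  g <- igraph::graph_from_data_frame(
    unique(tfmn$edges[, c("from", "to")]),
    directed = FALSE,
    vertices = data.frame(name = tfmn$nodes, valence = unname(tfmn$valence)))
  igraph::simplify(g)
}

#' Semantic frame of a concept
#'
#' The frame of a focal stem is its set of associates: in neighborhood mode
#' the aggregate-graph neighbours, in community mode the other members of
#' the focus's Louvain community.
#'
#' @param tfmn a `tfmn` object.
#' @param focus a stem present in the network.
#' @param mode "neighborhood" or "community".
#' @param seed RNG seed for community detection (community mode only).
#' @return a `frame` object: list with `focus`, `members`, `mode`.
#' @export
semantic_frame <- function(tfmn, focus,
                           mode = c("neighborhood", "community"),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (!focus %in% tfmn$nodes) {
    stop("focus '", focus, "' is not a node of the network", call. = FALSE)
  }
  g <- aggregate_graph(tfmn)
  members <- if (mode == "neighborhood") {
    igraph::neighbors(g, focus)$name
  } else {
    part <- detect_communities(g, seed = seed)
    setdiff(names(part)[part == part[[focus]]], focus)
  }
  structure(list(focus = focus, members = sort(members), mode = mode),
            class = "frame")
}

#' @export
print.tfmn <- function(x, ...) {
  nl <- table(factor(x$edges$layer, levels = c("syntactic", "synonym")))
  cat("<tfmn> ", length(x$nodes), " stemmed concepts, ",
      nrow(x$edges), " links (", nl[["syntactic"]], " syntactic + ",
      nl[["synonym"]], " synonym)\n", sep = "")
  cat(" valence: ",
      paste(names(table(x$valence)), table(x$valence),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.frame <- function(x, ...) {
  cat("<frame> focus '", x$focus, "' (", x$mode, "): ",
      length(x$members), " associates\n", sep = "")
  invisible(x)
}

#' Export a network to disk
#'
#' GraphML keeps the node attribute `valence` and edge attribute `layer`;
#' the edge list is a TSV with header `source<TAB>target<TAB>layer`; JSON
#' is a report with nodes, edges and labels matching the schema shipped in
#' `inst/extdata/tfmn-schema.json`. [import_network] inverts all three.
#'
#' @param tfmn a `tfmn` object.
#' @param format "graphml", "edgelist" or "json".
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_network <- function(tfmn, format = c("graphml", "edgelist", "json"),
                           path) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown export format: ",
                                              format[1], call. = FALSE))
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      tfmn$edges, directed = FALSE,
      vertices = data.frame(name = tfmn$nodes,
                            valence = unname(tfmn$valence)))
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    writeLines(c("source\ttarget\tlayer",
                 sprintf("%s\t%s\t%s", tfmn$edges$from, tfmn$edges$to,
                         tfmn$edges$layer)), path, useBytes = TRUE)
  } else {
    write_report_json(list(
      nodes = lapply(tfmn$nodes, function(n)
        list(name = n, valence = unname(tfmn$valence[[n]]))),
      edges = lapply(seq_len(nrow(tfmn$edges)), function(i)
        list(source = tfmn$edges$from[i], target = tfmn$edges$to[i],
             layer = tfmn$edges$layer[i]))), path)
  }
  invisible(path)
}

#' Import a network written by [export_network]
#'
#' @param path file path.
#' @param format "graphml", "edgelist" or "json".
#' @return a `tfmn` object (without a `labelmap`).
#' @export
import_network <- function(path, format = c("graphml", "edgelist", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        layer = igraph::edge_attr(g, "layer"))
    nodes <- igraph::V(g)$name
    valence <- setNames(igraph::V(g)$valence, nodes)
  } else if (format == "edgelist") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    edges <- data.frame(from = df$source, to = df$target, layer = df$layer)
    nodes <- sort(unique(c(edges$from, edges$to)))
    valence <- setNames(rep("unknown", length(nodes)), nodes)
  } else {
    rep <- jsonlite::read_json(path)
    nodes <- vapply(rep$nodes, function(n) n$name, "")
    valence <- setNames(vapply(rep$nodes, function(n) n$valence, ""), nodes)
    edges <- data.frame(
      from = vapply(rep$edges, function(e) e$source, ""),
      to = vapply(rep$edges, function(e) e$target, ""),
      layer = vapply(rep$edges, function(e) e$layer, ""))
  }
  o <- order(nodes)
  structure(list(nodes = nodes[o], valence = valence[nodes[o]],
                 edges = edges, labelmap = NULL), class = "tfmn")
}

#' Structural check of a JSON network report
#'
#' Verifies that a JSON file produced by [export_network] has the fields
#' the shipped schema (`inst/extdata/tfmn-schema.json`) requires: `nodes`
#' of {name, valence} and `edges` of {source, target, layer} with layers
#' drawn from {syntactic, synonym}.
#'
#' @param path JSON file path.
#' @return TRUE, or an error describing the violation.
#' @export
validate_network_json <- function(path) {
  rep <- jsonlite::read_json(path)
  if (!all(c("nodes", "edges") %in% names(rep))) {
    stop("report must contain 'nodes' and 'edges'", call. = FALSE)
  }
  ok_node <- vapply(rep$nodes, function(n)
    all(c("name", "valence") %in% names(n)) &&
      n$valence %in% c("positive", "neutral", "negative", "unknown"),
    logical(1))
  if (!all(ok_node)) stop("invalid node entry in report", call. = FALSE)
  ok_edge <- vapply(rep$edges, function(e)
    all(c("source", "target", "layer") %in% names(e)) &&
      e$layer %in% c("syntactic", "synonym"), logical(1))
  if (!all(ok_edge)) stop("invalid edge entry in report", call. = FALSE)
  TRUE
}
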
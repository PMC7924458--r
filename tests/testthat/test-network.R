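test_that("assembly merges stems and edges across sentences and documents", {
  tf <- assemble_tfmn(c("love is weakness today", "weakness defeats love"),
                      toy_bundle())
  expect_true(all(c("love", "weak", "defeat") %in% tf$nodes))
  syn <- tf$edges[tf$edges$layer == "syntactic", ]
  got <- apply(cbind(pmin(syn$from, syn$to), pmax(syn$from, syn$to)), 1,
               paste, collapse = "-")
  expect_true(all(c("love-weak", "defeat-weak") %in% got))
  # "love" appears in both documents but is a single node
  expect_equal(sum(tf$nodes == "love"), 1L)
})

test_that("assembly labels nodes from the norms, unknown when absent", {
  tf <- assemble_tfmn("the cat hate the dog now", toy_bundle())
  expect_equal(unname(tf$valence[["hate"]]), "negative")
  expect_equal(unname(tf$valence[["cat"]]), "neutral")
  tf2 <- assemble_tfmn("zork loves blug", toy_bundle())
  expect_true(all(tf2$valence[c("zork", "blug")] == "unknown"))
})

test_that("assembly rejects empty corpora and is order-invariant", {
  expect_error(assemble_tfmn(as_corpus(character(0)), toy_bundle()),
               "empty")
  docs <- c("love is weakness today", "weakness defeats love",
            "the cat sat on the chair")
  t1 <- assemble_tfmn(docs, toy_bundle())
  t2 <- assemble_tfmn(rev(docs), toy_bundle())
  expect_identical(t1$nodes, t2$nodes)
  key <- function(tf) sort(paste(pmin(tf$edges$from, tf$edges$to),
                                 pmax(tf$edges$from, tf$edges$to),
                                 tf$edges$layer))
  expect_identical(key(t1), key(t2))
})

test_that("node set equals the distinct stems of the edges", {
  tf <- assemble_tfmn(c("love is weakness today",
                        "the cat sat on the chair"), toy_bundle())
  expect_setequal(tf$nodes, unique(c(tf$edges$from, tf$edges$to)))
})

test_that("synonym layer links only stems already present", {
  syn <- rbind(c("famous", "notable"))
  stems <- porter_stem(c("famous", "notable"))
  expect_equal(nrow(synonym_layer(stems, syn)), 1L)
  expect_equal(nrow(synonym_layer(stems[1], syn)), 0L)
  expect_equal(nrow(synonym_layer(stems,
                                  matrix(character(0), ncol = 2))), 0L)
  # never introduces new nodes
  out <- synonym_layer(c(stems, "love", "joi"),
                       rbind(c("famous", "notable"), c("love", "hate")))
  expect_true(all(as.vector(out) %in% c(stems, "love", "joi")))
})

test_that("aggregate graph is the simple union of the layers", {
  tf <- toy_star_tfmn()
  tf$edges <- rbind(tf$edges,
                    data.frame(from = "x", to = "a", layer = "synonym"),
                    data.frame(from = "c", to = "d", layer = "synonym"))
  g <- aggregate_graph(tf)
  expect_equal(igraph::vcount(g), 6L)
  expect_equal(igraph::ecount(g), 6L)  # x-a collapsed, c-d new
  # matches a pair-set union oracle
  oracle <- unique(paste(pmin(tf$edges$from, tf$edges$to),
                         pmax(tf$edges$from, tf$edges$to)))
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  oracle)
})

test_that("frames give neighbourhoods and Louvain communities", {
  tf <- toy_star_tfmn()
  fr <- semantic_frame(tf, "x")
  expect_setequal(fr$members, c("a", "b", "c", "d", "e"))
  expect_false("x" %in% fr$members)
  expect_error(semantic_frame(tf, "zzz"), "not a node")

  # two cliques bridged at the focus: community mode returns its clique
  cl1 <- t(utils::combn(c("x", "p1", "p2", "p3", "p4"), 2))
  cl2 <- t(utils::combn(c("q0", "q1", "q2", "q3", "q4"), 2))
  tf2 <- structure(list(
    nodes = sort(unique(c(cl1, cl2))),
    valence = setNames(rep("neutral", 10), sort(unique(c(cl1, cl2)))),
    edges = data.frame(from = c(cl1[, 1], cl2[, 1], "x"),
                       to = c(cl1[, 2], cl2[, 2], "q0"),
                       layer = "syntactic"),
    labelmap = NULL), class = "tfmn")
  fr2 <- semantic_frame(tf2, "x", mode = "community", seed = 4)
  expect_setequal(fr2$members, c("p1", "p2", "p3", "p4"))
})

test_that("exports round-trip through graphml, edgelist and json", {
  dir <- withr::local_tempdir()
  tf <- assemble_tfmn(c("love is weakness today",
                        "the cat sat on the chair"), toy_bundle())

  p1 <- file.path(dir, "net.graphml")
  export_network(tf, "graphml", p1)
  back <- import_network(p1, "graphml")
  expect_setequal(back$nodes, tf$nodes)
  expect_identical(back$valence[tf$nodes], tf$valence)
  key <- function(x) sort(paste(pmin(x$edges$from, x$edges$to),
                                pmax(x$edges$from, x$edges$to),
                                x$edges$layer))
  expect_identical(key(back), key(tf))

  p2 <- file.path(dir, "net.tsv")
  export_network(tf, "edgelist", p2)
  lines <- readLines(p2)
  expect_equal(lines[1], "source\ttarget\tlayer")
  expect_equal(length(lines) - 1L, nrow(tf$edges))
  expect_identical(key(import_network(p2, "edgelist")), key(tf))

  p3 <- file.path(dir, "net.json")
  export_network(tf, "json", p3)
  expect_true(validate_network_json(p3))
  back3 <- import_network(p3, "json")
  expect_identical(key(back3), key(tf))
  expect_identical(back3$valence[tf$nodes], tf$valence)

  expect_error(export_network(tf, "dot", file.path(dir, "x")), "unknown")
})
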
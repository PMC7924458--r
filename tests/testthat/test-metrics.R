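star4 <- function() {
  g <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", "l1", "l2", "l3")
  g
}

test_that("shortest-path distances match definitions and the FW oracle", {
  g <- igraph::make_graph(~ a - b, b - c)
  expect_equal(shortest_path_distance(g, "a", "c"), 2)
  expect_equal(shortest_path_distance(g, "a", "a"), 0)
  expect_error(shortest_path_distance(g, "a", "zz"), "absent")

  for (s in 1:20) {
    g <- random_named_gnp(sample(5:30, 1), runif(1, 0.05, 0.3), seed = s)
    D <- fw_distances(g)
    ij <- sample(igraph::vcount(g), 2)
    expect_equal(shortest_path_distance(g, paste0("v", ij[1]),
                                        paste0("v", ij[2])),
                 unname(D[ij[1], ij[2]]))
  }
})

test_that("component-size closeness evaluates N over the distance sum", {
  g <- star4()
  hub <- closeness_eq(g, "hub")
  expect_equal(hub$value, 4 / 3)
  expect_equal(hub$component_size, 4L)
  expect_equal(hub$sum_distance, 3L)
  leaf <- closeness_eq(g, "l1")
  expect_equal(leaf$value, 4 / 5)
  expect_equal(leaf$sum_distance, 5L)
  # conventional variant
  expect_equal(closeness_eq(g, "hub", variant = "conventional")$value, 1)
  # singleton component is flagged undefined
  g2 <- igraph::add_vertices(g, 1, name = "alone")
  expect_false(closeness_eq(g2, "alone")$defined)
})

test_that("closeness agrees exactly with the brute-force oracle", {
  for (s in 1:25) {
    g <- random_named_gnp(sample(4:30, 1), runif(1, 0.05, 0.4), seed = 100 + s)
    v <- sample(igraph::V(g)$name, 1)
    got <- closeness_eq(g, v)
    ora <- fw_closeness(g, v)
    expect_identical(got$component_size, ora$N)
    expect_identical(got$sum_distance, ora$sumd)
    if (ora$N >= 2) expect_equal(got$value, ora$value)
  }
})

test_that("rankings run on the largest component, sorted with lexical ties", {
  g <- star4()
  rk <- closeness_ranking(g, k = 1)
  expect_equal(rk$stem, "hub")
  # k beyond the component returns the full ranking of that component
  rk_all <- closeness_ranking(g, k = 99)
  expect_equal(nrow(rk_all), 4L)
  expect_equal(rk_all$stem[1], "hub")
  expect_equal(rk_all$stem[-1], c("l1", "l2", "l3"))  # tie -> lexical
  # matches a per-node oracle sort
  g2 <- random_named_gnp(15, 0.25, seed = 77)
  rk2 <- closeness_ranking(g2, k = 99)
  comp <- igraph::components(g2)
  members <- names(comp$membership)[comp$membership ==
                                      which.max(comp$csize)]
  vals <- vapply(members, function(v) fw_closeness(
    igraph::induced_subgraph(g2, members), v)$value, numeric(1))
  o <- order(-vals, members)
  expect_equal(rk2$stem, members[o])
  expect_equal(rk2$closeness, unname(vals[o]))
  expect_error(closeness_ranking(igraph::make_empty_graph()), "empty")
  expect_error(closeness_ranking(star4(), k = 0), "k must be")
})

test_that("valence auras report neighbour fractions and the modal label", {
  tf <- toy_star_tfmn()   # 2 positive, 2 neutral, 1 negative neighbours
  aura <- valence_aura(tf, "x")
  expect_equal(unname(aura$fractions[["positive"]]), 0.4)
  expect_equal(sum(aura$fractions), 1)
  expect_equal(aura$aura, "mixed")  # positive ties neutral at 0.4

  tf$valence[["c"]] <- "positive"  # 3 pos, 1 neutral, 1 neg -> positive
  expect_equal(valence_aura(tf, "x")$aura, "positive")

  tf$valence[["a"]] <- "unknown"   # unknown counts as neutral
  aura3 <- valence_aura(tf, "x")
  expect_equal(unname(aura3$fractions[["neutral"]]), 0.4)

  tf_iso <- toy_star_tfmn()
  tf_iso$nodes <- c(tf_iso$nodes, "lonely")
  tf_iso$valence <- c(tf_iso$valence, lonely = "neutral")
  expect_error(valence_aura(tf_iso, "lonely"), "isolated")
})

test_that("mean clustering handles the textbook cases", {
  tri <- igraph::make_full_graph(3)
  expect_equal(mean_clustering(tri), 1.0)
  path4 <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(mean_clustering(path4), 0.0)
  k4me <- igraph::make_full_graph(4)
  k4me <- igraph::delete_edges(k4me, igraph::get_edge_ids(k4me, c(1, 2)))
  expect_equal(mean_clustering(k4me), 5 / 6)
  expect_error(mean_clustering(igraph::make_empty_graph()), "empty")
})

test_that("configuration rewiring preserves degrees and is seeded", {
  g <- random_named_gnp(20, 0.2, seed = 9)
  for (s in 1:10) {
    rg <- rewire_configuration(g, seed = s)
    expect_identical(igraph::degree(rg), igraph::degree(g))
    expect_equal(igraph::ecount(rg), igraph::ecount(g))
    expect_true(igraph::is_simple(rg))
  }
  # unique simple realisations come back unchanged
  st <- star4()
  rg <- rewire_configuration(st, seed = 3)
  expect_identical(sort(apply(igraph::as_edgelist(rg), 1,
                              function(e) paste(sort(e), collapse = "-"))),
                   sort(apply(igraph::as_edgelist(st), 1,
                              function(e) paste(sort(e), collapse = "-"))))
  # determinism
  r1 <- igraph::as_edgelist(rewire_configuration(g, seed = 42))
  r2 <- igraph::as_edgelist(rewire_configuration(g, seed = 42))
  expect_identical(r1, r2)
})

test_that("null clustering summarises rewired graphs", {
  tri <- igraph::make_full_graph(3)
  nc <- null_clustering(tri, realizations = 5, seed = 1)
  expect_equal(nc$mean, 1.0)
  expect_equal(nc$sd, 0.0)
  expect_error(null_clustering(tri, realizations = 1), "at least 2")

  n1 <- null_clustering(random_named_gnp(25, 0.25, seed = 2),
                        realizations = 10, seed = 5)
  n2 <- null_clustering(random_named_gnp(25, 0.25, seed = 2),
                        realizations = 10, seed = 5)
  expect_identical(n1$values, n2$values)

  # planted triangles: empirical clustering above configuration null
  tris <- lapply(0:9, function(i) igraph::make_full_graph(3))
  g <- Reduce(igraph::disjoint_union, tris)
  g <- igraph::add_edges(g, c(t(cbind(seq(1, 25, 3), seq(4, 28, 3)))))
  igraph::V(g)$name <- paste0("n", 1:30)
  nc2 <- null_clustering(g, realizations = 20, seed = 11)
  expect_gt(mean_clustering(g), nc2$mean)
})

test_that("community detection separates planted cliques, reproducibly", {
  cl1 <- igraph::make_full_graph(5)
  cl2 <- igraph::make_full_graph(5)
  g <- igraph::disjoint_union(cl1, cl2)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("w", 1:10)
  part <- detect_communities(g, seed = 2)
  expect_equal(length(unique(part)), 2L)
  expect_equal(length(unique(part[paste0("w", 1:5)])), 1L)
  expect_equal(length(unique(part[paste0("w", 6:10)])), 1L)
  expect_identical(part, detect_communities(g, seed = 2))

  g1 <- igraph::make_empty_graph(directed = FALSE)
  g1 <- igraph::add_vertices(g1, 1, name = "solo")
  expect_equal(length(unique(detect_communities(g1, seed = 1))), 1L)
  expect_error(detect_communities(igraph::make_empty_graph()), "empty")
})

test_that("valence class comparison separates planted structure", {
  # positive nodes form a clique, negatives hang off as leaves
  pos <- paste0("p", 1:6); neg <- paste0("n", 1:6)
  clique <- t(utils::combn(pos, 2))
  leaves <- cbind(pos, neg)
  tf <- structure(list(
    nodes = c(pos, neg),
    valence = setNames(rep(c("positive", "negative"), each = 6),
                       c(pos, neg)),
    edges = data.frame(from = c(clique[, 1], leaves[, 1]),
                       to = c(clique[, 2], leaves[, 2]),
                       layer = "syntactic"),
    labelmap = NULL), class = "tfmn")
  cmp <- valence_class_comparison(tf)
  expect_gt(cmp$degree$median_positive, cmp$degree$median_negative)
  expect_lt(cmp$degree$p, 0.05)
  expect_gt(cmp$closeness$median_positive, cmp$closeness$median_negative)

  # swapping labels exchanges the U statistics: U_x + U_y = m*n
  tf2 <- tf
  tf2$valence <- setNames(rep(c("negative", "positive"), each = 6),
                          c(pos, neg))
  cmp2 <- valence_class_comparison(tf2)
  expect_equal(cmp$degree$U + cmp2$degree$U, 36)

  tf3 <- tf
  tf3$valence[] <- "positive"
  expect_error(valence_class_comparison(tf3), "at least one")
})

test_that("frequency summary counts types and tokens per valence class", {
  lm <- assign_valence_labels(
    setNames(as.numeric(1:8),
             c("hate", "pain", "chair", "cat", "dog", "tree", "love",
               "joi")))
  out <- valence_frequency_summary(c("love love hate today",
                                     "the love of cat"), lm)
  expect_equal(out$token_count[out$class == "positive"], 3L)
  expect_equal(out$type_count[out$class == "positive"], 1L)
  expect_equal(out$token_count[out$class == "negative"], 1L)
  expect_equal(out$type_count[out$class == "neutral"], 1L)
  expect_true(all(out$token_count >= out$type_count))
  expect_equal(attr(out, "unknown")[["token_count"]], 1L)  # "today"

  empty <- valence_frequency_summary(as_corpus(character(0)), lm)
  expect_true(all(empty$token_count == 0L))
})

test_that("Mann-Whitney matches the enumeration oracle and wilcox.test", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)

  same <- mann_whitney_u(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$p, 1.0)

  x <- c(1.2, 3.4, 2.2, 8); y <- c(0.5, 6.1, 2.9)
  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U,
               length(x) * length(y))

  # tie-free small samples agree with wilcox.test's exact W and p
  set.seed(31)
  for (i in 1:5) {
    x <- sample(100, 4); y <- sample(100, 5)
    got <- mann_whitney_u(x, y)
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$U, unname(wt$statistic))
    expect_equal(got$p, wt$p.value)
  }

  # large samples with ties use the corrected normal approximation
  set.seed(32)
  x <- sample(1:5, 60, TRUE); y <- sample(2:6, 50, TRUE)
  got <- mann_whitney_u(x, y)
  wt <- stats::wilcox.test(x, y, correct = FALSE)
  expect_equal(got$p, wt$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})
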
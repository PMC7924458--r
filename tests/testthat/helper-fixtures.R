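# Shared fixtures and independent oracles for the test suite.

# In-memory lexicon bundle with hand-chosen scores: quartile labels are
# known by construction (8 scores 1..8 -> negative {1,2}, positive {7,8}).
toy_bundle <- function() {
  valence <- c(hate = 1, pain = 2, chair = 3, cat = 4,
               dog = 5, tree = 6, love = 7, joy = 8)
  emotions <- list(
    win = c("joy", "trust"), happy = c("joy", "trust"),
    hate = c("anger", "disgust"), pain = c("fear", "sadness"),
    joy = "joy", love = c("joy", "trust"), fear = "fear")
  structure(list(valence = valence, emotions = emotions,
                 synonyms = rbind(c("famous", "notable"),
                                  c("love", "joy")),
                 antonyms = rbind(c("love", "hate"),
                                  c("joy", "pain")),
                 stemmer = porter_stem),
            class = "lexicon_bundle")
}

# Hand-built tfmn: star of 5 neighbours around focus "x"
# (2 positive, 2 neutral, 1 negative), plus an isolated-ish tail.
toy_star_tfmn <- function() {
  nodes <- c("x", "a", "b", "c", "d", "e")
  valence <- c(x = "neutral", a = "positive", b = "positive",
               c = "neutral", d = "neutral", e = "negative")
  edges <- data.frame(from = "x", to = c("a", "b", "c", "d", "e"),
                      layer = "syntactic")
  structure(list(nodes = nodes, valence = valence, edges = edges,
                 labelmap = NULL), class = "tfmn")
}

# Floyd-Warshall all-pairs shortest paths: the independent distance oracle.
fw_distances <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

# Closeness oracle from Floyd-Warshall distances: exact integers N, sum d.
fw_closeness <- function(g, v) {
  D <- fw_distances(g)
  reach <- is.finite(D[v, ])
  N <- sum(reach)
  sumd <- sum(D[v, reach])
  list(N = N, sumd = as.integer(sumd),
       value = if (sumd > 0) N / sumd else NA_real_)
}

# Mann-Whitney enumeration oracle: U via the rank-sum identity, p by full
# enumeration of group assignments.
mw_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(ii) {
    rr <- rank(pool)
    sum(rr[ii]) - m * (m + 1) / 2
  })
  mu <- m * n / 2
  list(U = U_obs, p = mean(abs(us - mu) >= abs(U_obs - mu) - 1e-12))
}

with_seed_test <- function(seed, expr) tfmn:::with_seed(seed, expr)

random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}
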
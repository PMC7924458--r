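#' Fixture specification
#'
#' Parameters of the deterministic test-data generators. Defaults describe
#' a small but structured study: a vocabulary with planted valence classes
#' whose sizes the quartile labeling must recover exactly, an emotion
#' lexicon with unequal base rates (more fear/joy words than
#' anticipation/sadness, as in real emotion lexicons), planted synonym and
#' antonym pairs, and a topic corpus of simple copular sentences wiring
#' each topic to its associates.
#'
#' @param seed RNG seed.
#' @param n_positive,n_neutral,n_negative planted valence class sizes;
#'   feasible combinations put both quartiles strictly inside score gaps
#'   (e.g., classes of n/4, n/2, n/4).
#' @param emotion_base_rates named numeric in [0,1] over the 8 basic
#'   emotions: exact fraction of emotion-lexicon words tagged with each.
#' @param n_emotion_words emotion lexicon vocabulary size.
#' @param n_synonym_pairs,n_antonym_pairs planted pair counts.
#' @param n_topics,docs_per_topic,words_per_doc topic corpus shape.
#' @param n_associates,n_fillers per-topic planted associates (wired to the
#'   topic in the reference network, distance 1) and fillers (wired three
#'   hops away).
#' @param negation_rate fraction of corpus sentences negated with "not".
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_positive = 10L, n_neutral = 20L,
                         n_negative = 10L,
                         emotion_base_rates = c(
                           anger = 0.15, anticipation = 0.10,
                           disgust = 0.15, fear = 0.30, joy = 0.30,
                           sadness = 0.10, surprise = 0.15, trust = 0.25),
                         n_emotion_words = 200L,
                         n_synonym_pairs = 6L, n_antonym_pairs = 6L,
                         n_topics = 3L, docs_per_topic = 5L,
                         words_per_doc = 24L,
                         n_associates = 10L, n_fillers = 15L,
                         negation_rate = 0) {
  stopifnot(all(emotion_base_rates >= 0 & emotion_base_rates <= 1),
            all(names(emotion_base_rates) %in% EMOTIONS),
            n_positive >= 0, n_neutral >= 0, n_negative >= 0,
            negation_rate >= 0, negation_rate <= 1)
  structure(list(seed = seed, n_positive = n_positive,
                 n_neutral = n_neutral, n_negative = n_negative,
                 emotion_base_rates = emotion_base_rates,
                 n_emotion_words = n_emotion_words,
                 n_synonym_pairs = n_synonym_pairs,
                 n_antonym_pairs = n_antonym_pairs,
                 n_topics = n_topics, docs_per_topic = docs_per_topic,
                 words_per_doc = words_per_doc,
                 n_associates = n_associates, n_fillers = n_fillers,
                 negation_rate = negation_rate),
            class = "fixture_spec")
}

# Pseudo-words built from CV syllables plus a final consonant; each word is
# checked to be its own Porter stem so that surface forms, stems and
# reference-network vertices coincide in fixtures.
make_pseudo_words <- function(n, prefix = "") {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "z")
  vow <- c("a", "e", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    w <- paste0(prefix,
                sample(cons, need, TRUE), sample(vow, need, TRUE),
                sample(cons, need, TRUE), sample(vow, need, TRUE),
                sample(cons, need, TRUE))
    w <- w[porter_stem(w) == w]
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate a deterministic mini lexicon bundle
#'
#' Valence scores are drawn inside disjoint bands (negative in [1, 2],
#' neutral in [4, 6], positive in [8, 9]) sized so that quartile labeling
#' recovers the planted class sizes exactly; specs where a quartile falls
#' on a class boundary are rejected as infeasible. Emotion tags are
#' assigned to exactly `round(rate * n)` words per emotion. Synonym pairs
#' are planted within a valence class, antonym pairs across the
#' positive/negative classes.
#'
#' @param spec a [fixture_spec].
#' @return a `lexicon_bundle` with a `ground_truth` element (planted class
#'   membership, emotion counts, pairs).
#' @export
make_mini_lexicons <- function(spec = fixture_spec()) {
  n <- spec$n_positive + spec$n_neutral + spec$n_negative
  if (n < 4L) stop("infeasible spec: need at least 4 valence words",
                   call. = FALSE)
  # type-7 quantile positions must fall strictly between class boundaries
  h1 <- 1 + 0.25 * (n - 1); h3 <- 1 + 0.75 * (n - 1)
  if (!(h1 > spec$n_negative && h1 < spec$n_negative + 1) ||
      !(h3 > n - spec$n_positive && h3 < n - spec$n_positive + 1)) {
    stop("infeasible spec: quartiles fall on a planted class boundary ",
         "(use class sizes n/4, n/2, n/4)", call. = FALSE)
  }
  with_seed(spec$seed, {
    vocab <- make_pseudo_words(n)
    neg_w <- vocab[seq_len(spec$n_negative)]
    neu_w <- vocab[spec$n_negative + seq_len(spec$n_neutral)]
    pos_w <- vocab[spec$n_negative + spec$n_neutral +
                     seq_len(spec$n_positive)]
    valence <- c(setNames(round(runif(length(neg_w), 1, 2), 3), neg_w),
                 setNames(round(runif(length(neu_w), 4, 6), 3), neu_w),
                 setNames(round(runif(length(pos_w), 8, 9), 3), pos_w))

    emo_vocab <- make_pseudo_words(spec$n_emotion_words, prefix = "e")
    emotions <- setNames(vector("list", length(emo_vocab)), emo_vocab)
    for (e in names(spec$emotion_base_rates)) {
      k <- round(spec$emotion_base_rates[[e]] * length(emo_vocab))
      tagged <- sample(emo_vocab, k)
      for (w in tagged) emotions[[w]] <- sort(unique(c(emotions[[w]], e)))
    }
    emotions <- emotions[lengths(emotions) > 0L]

    pick_pairs <- function(pool_a, pool_b, k) {
      if (k == 0L) return(empty_edges())
      a <- sample(pool_a, k, replace = FALSE)
      b <- sample(setdiff(pool_b, a), k, replace = FALSE)
      m <- cbind(pmin(a, b), pmax(a, b))
      colnames(m) <- c("a", "b")
      m
    }
    synonyms <- pick_pairs(pos_w, pos_w, min(spec$n_synonym_pairs,
                                             length(pos_w) %/% 2))
    antonyms <- pick_pairs(pos_w, neg_w, min(spec$n_antonym_pairs,
                                             length(pos_w),
                                             length(neg_w)))

    structure(list(valence = valence, emotions = emotions,
                   synonyms = synonyms, antonyms = antonyms,
                   stemmer = porter_stem,
                   ground_truth = list(
                     positive = pos_w, neutral = neu_w, negative = neg_w,
                     emotion_counts = vapply(EMOTIONS, function(e)
                       sum(vapply(emotions, function(s) e %in% s,
                                  logical(1))), 1L))),
              class = "lexicon_bundle")
  })
}

#' Write a lexicon bundle as the four TSV files the loader reads
#'
#' @param bundle a `lexicon_bundle`.
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
write_lexicon_files <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(valence = file.path(dir, "valence.tsv"),
             emotions = file.path(dir, "emotions.tsv"),
             synonyms = file.path(dir, "synonyms.tsv"),
             antonyms = file.path(dir, "antonyms.tsv"))
  writeLines(sprintf("%s\t%s", names(bundle$valence),
                     format(bundle$valence, trim = TRUE)),
             paths[["valence"]], useBytes = TRUE)
  emo_rows <- unlist(lapply(names(bundle$emotions), function(w)
    sprintf("%s\t%s", w, bundle$emotions[[w]])))
  writeLines(emo_rows, paths[["emotions"]], useBytes = TRUE)
  writeLines(sprintf("%s\t%s", bundle$synonyms[, 1], bundle$synonyms[, 2]),
             paths[["synonyms"]], useBytes = TRUE)
  writeLines(sprintf("%s\t%s", bundle$antonyms[, 1], bundle$antonyms[, 2]),
             paths[["antonyms"]], useBytes = TRUE)
  paths
}

#' Generate a planted-topic corpus with its reference network
#'
#' Each topic gets `n_associates` associate words and `n_fillers` filler
#' words. Documents are simple copular sentences: every associate appears
#' in "the TOPIC is ASSOCIATE" (yielding a direct topic-associate link
#' after contraction), fillers attach to associates and to each other. The
#' emitted reference network wires associates at distance 1 from their
#' topic and fillers at distance 3 (via two bridge words), so a ranking
#' that prefers topic-adjacent concepts scores shorter reference distances
#' than a degree-preserving null.
#'
#' @param spec a [fixture_spec].
#' @return list with `documents_by_topic` (named list of character
#'   vectors), `reference` (igraph), `reference_edges` (matrix), `topics`,
#'   `associates`, `fillers` (named lists of character vectors).
#' @export
make_topic_corpus <- function(spec = fixture_spec()) {
  with_seed(spec$seed + 1L, {
    topics <- make_pseudo_words(spec$n_topics, prefix = "t")
    assoc <- list(); fill <- list(); ref <- list()
    documents_by_topic <- list()
    sentences_per_doc <- max(1L, spec$words_per_doc %/% 3L)

    for (tp in topics) {
      a <- make_pseudo_words(spec$n_associates, prefix = paste0(tp, "a"))
      f <- make_pseudo_words(spec$n_fillers, prefix = paste0(tp, "f"))
      assoc[[tp]] <- a; fill[[tp]] <- f

      sent <- c(
        sprintf("the %s is %s", tp, a),
        sprintf("%s is %s", sample(a, length(f), replace = TRUE), f),
        if (length(f) > 1L)
          sprintf("%s is %s", f[-length(f)], f[-1]))
      if (spec$negation_rate > 0) {
        flip <- runif(length(sent)) < spec$negation_rate
        sent[flip] <- sub(" is ", " is not ", sent[flip], fixed = TRUE)
      }
      sent <- sample(sent)
      docs <- split(sent, ceiling(seq_along(sent) / sentences_per_doc))
      docs <- vapply(docs, function(s) paste0(paste(s, collapse = ". "),
                                              "."), "")
      if (length(docs) > spec$docs_per_topic) {
        merged <- split(seq_along(docs),
                        cut(seq_along(docs), spec$docs_per_topic,
                            labels = FALSE))
        docs <- vapply(merged, function(ii)
          paste(docs[ii], collapse = " "), "")
      }
      documents_by_topic[[tp]] <- unname(docs)

      bridge <- make_pseudo_words(2L, prefix = paste0(tp, "b"))
      ref[[tp]] <- rbind(
        cbind(tp, a),
        cbind(tp, bridge[1]),
        cbind(bridge[1], bridge[2]),
        cbind(bridge[2], f))
    }
    reference_edges <- do.call(rbind, ref)
    colnames(reference_edges) <- c("a", "b")
    list(documents_by_topic = documents_by_topic,
         reference = reference_network(reference_edges),
         reference_edges = reference_edges,
         topics = topics, associates = assoc, fillers = fill)
  })
}
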
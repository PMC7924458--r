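#' Expand a frame with antonyms of negated concepts
#'
#' Concepts adjacent to a negation node ("not") in the network are read
#' with their meaning inverted, so each listed antonym of such a concept is
#' added to the frame (as a stem) alongside the original word. Words never
#' get removed; negated words with no listed antonym stay unchanged with a
#' warning.
#'
#' @param frame_words character vector of frame member stems.
#' @param tfmn the `tfmn` the frame came from (must retain "not" nodes).
#' @param antonyms 2-column character matrix of antonym word pairs.
#' @param stemmer stemming function used to match pairs to stems.
#' @return character vector: the input words plus antonym stems.
#' @export
expand_negated <- function(frame_words, tfmn, antonyms,
                           stemmer = porter_stem) {
  g <- aggregate_graph(tfmn)
  neg_nodes <- intersect(c("not"), igraph::V(g)$name)
  if (length(neg_nodes) == 0L || is.null(antonyms) ||
      nrow(antonyms) == 0L) {
    return(unique(frame_words))
  }
  negated <- unique(unlist(lapply(neg_nodes, function(nn)
    igraph::neighbors(g, nn)$name)))
  negated <- intersect(frame_words, negated)
  if (length(negated) == 0L) return(unique(frame_words))

  a <- stemmer(antonyms[, 1]); b <- stemmer(antonyms[, 2])
  added <- character(0); missing <- character(0)
  for (w in negated) {
    opp <- unique(c(b[a == w], a[b == w]))
    if (length(opp) == 0L) missing <- c(missing, w) else added <- c(added, opp)
  }
  if (length(missing)) {
    warning("no antonym listed for negated concept(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  unique(c(frame_words, added))
}

#' Emotional profile of a set of words
#'
#' For the distinct words that elicit at least one emotion (the
#' contributing set, of size m), the profile gives per emotion the fraction
#' of contributing words eliciting it. Fractions need not sum to 1: a word
#' can elicit several emotions. Lookup falls back to stems (see
#' [emotions_of]).
#'
#' @param words character vector (typically an expanded frame).
#' @param emolex named list word -> emotions (the `emotions` element of a
#'   lexicon bundle).
#' @param stemmer stemming function for lookup fallback.
#' @return an `emotional_profile`: list with `m`, `fractions` (named over
#'   the 8 basic emotions; NA when m = 0), `contributing`.
#' @export
emotional_profile <- function(words, emolex, stemmer = porter_stem) {
  idx <- stem_emotion_index(emolex, stemmer)
  words <- unique(tolower(words))
  emo_sets <- lapply(words, function(w) {
    hit <- idx[[w]]
    if (is.null(hit)) hit <- idx[[stemmer(w)]]
    if (is.null(hit)) character(0) else hit
  })
  has_emo <- lengths(emo_sets) > 0L
  m <- sum(has_emo)
  fractions <- if (m == 0L) {
    setNames(rep(NA_real_, length(EMOTIONS)), EMOTIONS)
  } else {
    counts <- table(factor(unlist(emo_sets[has_emo]), levels = EMOTIONS))
    setNames(as.numeric(counts) / m, EMOTIONS)
  }
  structure(list(m = m, fractions = fractions,
                 contributing = words[has_emo]),
            class = "emotional_profile")
}

#' Sampling null model for emotional profiles
#'
#' Draws `reps` random frames of m distinct words, uniformly without
#' replacement from the words of the emotion lexicon that elicit at least
#' one emotion, and records each frame's per-emotion fractions. The
#' resulting mean and standard deviation per emotion standardise observed
#' profiles, answering whether an emotion is prominent merely because the
#' lexicon lists many words for it.
#'
#' @param m number of contributing words to match (1 <= m <= eligible
#'   vocabulary size).
#' @param emolex named list word -> emotions.
#' @param reps number of random frames (default 1000).
#' @param seed RNG seed.
#' @return a `null_distribution`: list with `m`, `reps`, `mean`, `sd`
#'   (named over emotions), `seed`, `fractions` (reps x 8 matrix).
#' @export
sample_null <- function(m, emolex, reps = 1000, seed = 1L) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  eligible <- names(emolex)[lengths(emolex) > 0L]
  V <- length(eligible)
  if (m < 1 || m > V) {
    stop("m = ", m, " exceeds the eligible vocabulary (", V, " words)",
         call. = FALSE)
  }
  membership <- vapply(EMOTIONS, function(e)
    vapply(emolex[eligible], function(s) e %in% s, logical(1)),
    logical(V))
  fr <- with_seed(seed, {
    t(vapply(seq_len(reps), function(r) {
      s <- sample.int(V, m)
      colSums(membership[s, , drop = FALSE]) / m
    }, numeric(length(EMOTIONS))))
  })
  colnames(fr) <- EMOTIONS
  structure(list(m = m, reps = reps,
                 mean = colMeans(fr),
                 sd = apply(fr, 2, sd),
                 seed = seed, fractions = fr),
            class = "null_distribution")
}

#' Emotional flower: z-scores of a profile against its null
#'
#' Standardises each emotion fraction by the null mean and standard
#' deviation; emotions with z >= 1.96 exceed random expectation at the 0.05
#' level (the "petals" leaving the rejection disc of the flower chart).
#' Emotions with zero null variance get an undefined z (flagged). Ring
#' metadata for a plotting layer is attached: concentric rings mark z units
#' beyond 2.
#'
#' @param profile an `emotional_profile`.
#' @param null a `null_distribution` with the same m.
#' @return an `emotional_flower`: list with `z`, `significant` (named
#'   logicals), `threshold`, `undefined` (emotions with sd 0 or m 0),
#'   `rings`.
#' @export
emotional_flower <- function(profile, null) {
  if (profile$m != null$m) {
    stop("profile m (", profile$m, ") does not match null m (", null$m, ")",
         call. = FALSE)
  }
  z <- (profile$fractions - null$mean) / null$sd
  undefined <- names(z)[!is.finite(z)]
  z[!is.finite(z)] <- NA_real_
  significant <- !is.na(z) & z >= 1.96
  structure(list(z = z, significant = significant, threshold = 1.96,
                 undefined = undefined,
                 rings = list(start = 2, step = 1,
                              note = "concentric rings mark z units beyond 2")),
            class = "emotional_flower")
}

#' Full emotional profile of a concept's frame
#'
#' Convenience wrapper: frame extraction, negation-antonym expansion,
#' profile, null and flower in one call.
#'
#' @param tfmn a `tfmn` object.
#' @param focus a stem in the network.
#' @param lexicons a `lexicon_bundle`.
#' @param reps null-model repetitions (default 1000).
#' @param seed RNG seed.
#' @param mode frame mode, see [semantic_frame].
#' @return list with `frame`, `expanded`, `profile`, `null`, `flower`
#'   (`null`/`flower` are NULL when no frame word elicits any emotion).
#' @export
profile_concept <- function(tfmn, focus, lexicons, reps = 1000, seed = 1L,
                            mode = "neighborhood") {
  fr <- semantic_frame(tfmn, focus, mode = mode, seed = seed)
  expanded <- expand_negated(fr$members, tfmn, lexicons$antonyms,
                             lexicons$stemmer)
  prof <- emotional_profile(expanded, lexicons$emotions, lexicons$stemmer)
  if (prof$m == 0L) {
    return(list(frame = fr, expanded = expanded, profile = prof,
                null = NULL, flower = NULL))
  }
  null <- sample_null(prof$m, lexicons$emotions, reps = reps, seed = seed)
  list(frame = fr, expanded = expanded, profile = prof, null = null,
       flower = emotional_flower(prof, null))
}

#' @export
print.emotional_profile <- function(x, ...) {
  cat("<emotional_profile> m =", x$m, "\n")
  if (x$m > 0) print(round(x$fractions, 3))
  invisible(x)
}

#' @export
print.emotional_flower <- function(x, ...) {
  cat("<emotional_flower> z >=", x$threshold, "marks significance\n")
  print(round(x$z, 2))
  sig <- names(x$significant)[x$significant]
  cat("significant:", if (length(sig)) paste(sig, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
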
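# Closed word lists for the rule-based fallback parser. Intentionally tiny:
# the fixture grammar covers determiners, SVO clauses, copulas,
# prepositional phrases and negation. Real corpora should route through a
# UD parser backend; any function with the depgraph contract plugs in.
FW_DET <- c("the", "a", "an", "this", "that", "these", "those", "my",
            "your", "his", "her", "its", "our", "their", "some", "any",
            "no", "every", "each")
FW_ADP <- c("on", "in", "at", "of", "to", "with", "for", "from", "by",
            "about", "over", "under", "into", "onto", "through", "between",
            "against", "during", "without", "within", "across")
FW_AUX <- c("is", "am", "are", "was", "were", "be", "been", "being",
            "do", "does", "did", "will", "would", "can", "could", "shall",
            "should", "may", "might", "must", "has", "have", "had")
FW_CCONJ <- c("and", "or", "but", "nor", "yet")
FW_SCONJ <- c("because", "if", "while", "although", "since", "unless",
              "whereas")
FW_PRON <- c("i", "we", "you", "he", "she", "it", "they", "me", "us",
             "him", "them", "who", "what", "someone", "everyone")
FW_NEG <- c("not", "n't")

# copulas treated as AUX so that "love is weakness" contracts to a direct
# love-weakness link; content verbs like "sit" stay as nodes
AUX_LEMMA <- c(is = "be", am = "be", are = "be", was = "be", were = "be",
               been = "be", being = "be", does = "do", did = "do",
               has = "have", had = "have")

# small irregular/inflected verb lexicon with lemmas; regular nouns rely on
# stemming downstream instead of lemmatization
VERB_LEMMA <- c(
  sit = "sit", sits = "sit", sat = "sit", sitting = "sit",
  love = "love", loves = "love", loved = "love", loving = "love",
  like = "like", likes = "like", liked = "like",
  see = "see", sees = "see", saw = "see", seen = "see",
  need = "need", needs = "need", needed = "need",
  want = "want", wants = "want", wanted = "want",
  make = "make", makes = "make", made = "make",
  get = "get", gets = "get", got = "get",
  know = "know", knows = "know", knew = "know",
  say = "say", says = "say", said = "say",
  learn = "learn", learns = "learn", learned = "learn",
  work = "work", works = "work", worked = "work",
  help = "help", helps = "help", helped = "help",
  win = "win", wins = "win", won = "win",
  find = "find", finds = "find", found = "find",
  defeat = "defeat", defeats = "defeat", defeated = "defeat",
  annoy = "annoy", annoys = "annoy", annoyed = "annoy",
  go = "go", goes = "go", went = "go",
  run = "run", runs = "run", ran = "run",
  give = "give", gives = "give", gave = "give",
  take = "take", takes = "take", took = "take",
  become = "become", becomes = "become", became = "become",
  support = "support", supports = "support", supported = "support")

#' Deterministic rule-based dependency parser
#'
#' Offline stand-in for a full UD parser. Handles the fixture grammar:
#' optional determiners, subject–verb–object clauses, copular clauses,
#' prepositional phrases and the negation particle. Tokens outside the
#' closed lists are tagged NOUN, so the parser never fails. Produces UD-style
#' arcs: `nsubj`, `obj`, `cop`, `aux`, `case`, `det`, `obl`, `advmod`
#' (negation), `cc`, `dep`.
#'
#' @param sentence a single sentence.
#' @return a `depgraph`: list with `tokens` (index, surface, lemma, pos)
#'   and `edges` (head, dep, rel).
#' @export
fallback_parse <- function(sentence) {
  surf <- tolower(strsplit(trimws(sentence), "\\s+")[[1]])
  surf <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", surf)
  surf <- surf[nzchar(surf)]
  if (!length(surf)) {
    return(structure(list(
      tokens = data.frame(index = integer(), surface = character(),
                          lemma = character(), pos = character()),
      edges = data.frame(head = integer(), dep = integer(),
                         rel = character())), class = "depgraph"))
  }
  n <- length(surf)
  pos <- character(n); lemma <- surf
  for (i in seq_len(n)) {
    w <- surf[i]
    if (w %in% FW_NEG) { pos[i] <- "PART"; lemma[i] <- "not" }
    else if (w %in% FW_DET) pos[i] <- "DET"
    else if (w %in% FW_AUX) {
      pos[i] <- "AUX"
      lemma[i] <- if (w %in% names(AUX_LEMMA)) AUX_LEMMA[[w]] else w
    }
    else if (w %in% FW_ADP) pos[i] <- "ADP"
    else if (w %in% FW_CCONJ) pos[i] <- "CCONJ"
    else if (w %in% FW_SCONJ) pos[i] <- "SCONJ"
    else if (w %in% FW_PRON) pos[i] <- "PRON"
    else if (w %in% names(VERB_LEMMA)) {
      pos[i] <- "VERB"; lemma[i] <- VERB_LEMMA[[w]]
    }
    else pos[i] <- "NOUN"
  }
  # noun/verb ambiguity: a "verb" directly followed by a copula/auxiliary
  # is a nominal subject in this grammar ("love is weakness")
  for (i in which(pos == "VERB")) {
    if (i < n && pos[i + 1L] == "AUX") { pos[i] <- "NOUN"; lemma[i] <- surf[i] }
  }
  content <- pos %in% c("NOUN", "PRON", "VERB", "ADJ")
  is_nominal <- pos %in% c("NOUN", "PRON")

  edges <- list()
  add <- function(h, d, rel) edges[[length(edges) + 1L]] <<- list(h, d, rel)
  attached <- logical(n)

  # determiners attach to the next nominal
  for (i in which(pos == "DET")) {
    nxt <- which(is_nominal & seq_len(n) > i)
    if (length(nxt)) { add(nxt[1], i, "det"); attached[i] <- TRUE }
  }
  # adpositions attach to the next nominal (case); that nominal is marked
  # as a prepositional object
  pobj <- logical(n)
  for (i in which(pos == "ADP")) {
    nxt <- which(is_nominal & seq_len(n) > i)
    if (length(nxt)) {
      add(nxt[1], i, "case"); pobj[nxt[1]] <- TRUE; attached[i] <- TRUE
    }
  }

  verb_at <- which(pos %in% c("VERB", "AUX"))
  root <- NA_integer_
  if (length(verb_at)) {
    v <- verb_at[1]
    main_verbs <- which(pos == "VERB")
    if (length(main_verbs)) {
      # clause with a content verb; any preceding AUX become aux arcs
      root <- main_verbs[1]
      for (a in which(pos == "AUX" & seq_len(n) < root)) {
        add(root, a, "aux"); attached[a] <- TRUE
      }
      subj <- which(is_nominal & !pobj & seq_len(n) < root)
      if (length(subj)) {
        add(root, subj[length(subj)], "nsubj")
        attached[subj[length(subj)]] <- TRUE
      }
      obj <- which(is_nominal & !pobj & seq_len(n) > root)
      if (length(obj)) { add(root, obj[1], "obj"); attached[obj[1]] <- TRUE }
    } else {
      # copular clause: predicate after the copula is the root
      pred <- which(content & !pobj & seq_len(n) > v)
      if (length(pred)) {
        root <- pred[1]
        add(root, v, "cop"); attached[v] <- TRUE
        subj <- which(is_nominal & !pobj & seq_len(n) < v)
        if (length(subj)) {
          add(root, subj[length(subj)], "nsubj")
          attached[subj[length(subj)]] <- TRUE
        }
      } else {
        root <- v
      }
    }
  } else {
    first_content <- which(content)
    if (length(first_content)) root <- first_content[1]
  }
  if (is.na(root)) root <- 1L
  attached[root] <- TRUE

  # prepositional objects become obliques of the root
  for (i in which(pobj & seq_len(n) != root)) {
    add(root, i, "obl"); attached[i] <- TRUE
  }
  # negation attaches to the root
  for (i in which(pos == "PART" & lemma == "not")) {
    if (i != root) { add(root, i, "advmod"); attached[i] <- TRUE }
  }
  # conjunctions and leftover tokens hang off the root
  for (i in which(pos == "CCONJ" | pos == "SCONJ")) {
    if (i != root) { add(root, i, "cc"); attached[i] <- TRUE }
  }
  for (i in which(!attached)) add(root, i, "dep")

  edges_df <- if (length(edges)) {
    data.frame(head = vapply(edges, function(e) as.integer(e[[1]]), 1L),
               dep = vapply(edges, function(e) as.integer(e[[2]]), 1L),
               rel = vapply(edges, function(e) e[[3]], ""))
  } else {
    data.frame(head = integer(), dep = integer(), rel = character())
  }
  structure(list(
    tokens = data.frame(index = seq_len(n), surface = surf,
                        lemma = lemma, pos = pos),
    edges = edges_df), class = "depgraph")
}

#' @export
print.depgraph <- function(x, ...) {
  cat("<depgraph> ", nrow(x$tokens), " tokens, ", nrow(x$edges), " arcs\n",
      sep = "")
  if (nrow(x$edges)) {
    lab <- paste0(x$edges$rel, "(", x$tokens$surface[x$edges$head], " -> ",
                  x$tokens$surface[x$edges$dep], ")")
    cat(" ", paste(lab, collapse = ", "), "\n")
  }
  invisible(x)
}
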
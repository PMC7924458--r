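#' @importFrom stats quantile sd median setNames runif pnorm
#' @importFrom utils head read.csv read.delim combn
NULL

EMOTIONS <- c("anger", "anticipation", "disgust", "fear",
              "joy", "sadness", "surprise", "trust")

# Read a 2-column TSV (UTF-8, '#' comments). Returns a data.frame with
# columns v1, v2 (character) plus the originating line numbers.
read_tsv2 <- function(path, what) {
  if (!file.exists(path)) {
    stop("cannot load ", what, ": file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(v1 = character(), v2 = character(), line = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed row in ", what, " file ", path, " at line ",
         lineno[bad[1]], ": expected 2 tab-separated columns", call. = FALSE)
  }
  data.frame(v1 = vapply(parts, `[`, "", 1L),
             v2 = vapply(parts, `[`, "", 2L),
             line = lineno, stringsAsFactors = FALSE)
}

#' Load the psycholinguistic lexicon bundle
#'
#' Reads the four TSV resources the pipeline needs: valence norms
#' (word, score), word-emotion associations (word, emotion; one row per
#' association), synonym pairs and antonym pairs. All words are lowercased.
#' Comment lines starting with `#` are ignored. Duplicate words in the
#' valence file keep the last score, with a warning.
#'
#' @param valence_path,emotion_path,synonym_path,antonym_path TSV file paths.
#' @return an object of class `lexicon_bundle` with elements `valence`
#'   (named numeric), `emotions` (named list of character vectors),
#'   `synonyms` and `antonyms` (2-column character matrices of unordered
#'   pairs), and `stemmer` (the stemming function used downstream).
#' @export
load_lexicons <- function(valence_path, emotion_path, synonym_path,
                          antonym_path) {
  val <- read_tsv2(valence_path, "valence norms")
  scores <- suppressWarnings(as.numeric(val$v2))
  bad <- which(!is.finite(scores))
  if (length(bad)) {
    stop("malformed row in valence file ", valence_path, " at line ",
         val$line[bad[1]], ": non-numeric or non-finite score '",
         val$v2[bad[1]], "'", call. = FALSE)
  }
  words <- tolower(val$v1)
  if (anyDuplicated(words)) {
    warning("duplicate words in valence norms; keeping the last score for: ",
            paste(unique(words[duplicated(words)]), collapse = ", "),
            call. = FALSE)
  }
  valence <- setNames(scores, words)
  valence <- valence[!duplicated(names(valence), fromLast = TRUE)]

  emo <- read_tsv2(emotion_path, "emotion lexicon")
  ew <- tolower(emo$v1); ee <- tolower(emo$v2)
  unk <- which(!ee %in% EMOTIONS)
  if (length(unk)) {
    stop("unknown emotion '", ee[unk[1]], "' in ", emotion_path, " at line ",
         emo$line[unk[1]], "; expected one of: ",
         paste(EMOTIONS, collapse = ", "), call. = FALSE)
  }
  emotions <- lapply(split(ee, ew), function(x) sort(unique(x)))

  load_pairs <- function(path, what) {
    p <- read_tsv2(path, what)
    a <- tolower(p$v1); b <- tolower(p$v2)
    keep <- a != b
    m <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
    unique(m)
  }

  structure(list(valence = valence,
                 emotions = emotions,
                 synonyms = load_pairs(synonym_path, "synonym pairs"),
                 antonyms = load_pairs(antonym_path, "antonym pairs"),
                 stemmer = porter_stem),
            class = "lexicon_bundle")
}

#' @export
print.lexicon_bundle <- function(x, ...) {
  cat("<lexicon_bundle>\n",
      " valence norms : ", length(x$valence), " words\n",
      " emotion lexicon: ", length(x$emotions), " words\n",
      " synonym pairs : ", nrow(x$synonyms), "\n",
      " antonym pairs : ", nrow(x$antonyms), "\n", sep = "")
  invisible(x)
}

#' Aggregate valence norms to stem level
#'
#' Each stem's valence is the arithmetic mean of the scores of the words
#' sharing that stemmed root.
#'
#' @param norms named numeric vector of word valence scores.
#' @param stemmer stemming function (default [porter_stem]).
#' @return named numeric vector: stem -> mean valence.
#' @export
stem_aggregate_valence <- function(norms, stemmer = porter_stem) {
  if (length(norms) == 0L) stop("valence norms are empty", call. = FALSE)
  stems <- stemmer(names(norms))
  means <- vapply(split(unname(norms), stems), mean, numeric(1))
  means[order(names(means))]
}

#' Label stems as positive, neutral or negative by valence quartile
#'
#' Stems above the 75th percentile (q3) of the stem-level valence
#' distribution are labeled positive, stems below the 25th percentile (q1)
#' negative, and everything in the interquartile range (ties included)
#' neutral. Percentiles use linear interpolation between order statistics.
#'
#' @param table named numeric vector: stem -> mean valence
#'   (see [stem_aggregate_valence]).
#' @return an object of class `valence_labels`: list with `labels` (named
#'   character: positive/neutral/negative), `q1`, `q3`.
#' @export
assign_valence_labels <- function(table) {
  if (length(table) < 4L) {
    stop("need at least 4 stems to define valence quartiles", call. = FALSE)
  }
  qs <- quantile(unname(table), probs = c(0.25, 0.75), type = 7, names = FALSE)
  labels <- ifelse(table > qs[2], "positive",
                   ifelse(table < qs[1], "negative", "neutral"))
  structure(list(labels = setNames(labels, names(table)),
                 q1 = qs[1], q3 = qs[2]),
            class = "valence_labels")
}

#' Look up the emotions a word elicits
#'
#' Returns the word-emotion lexicon entry for `word`; if the surface form is
#' absent the stemmed form is tried, because network nodes are stems while
#' emotion lexicons list surface words. Absent words return an empty set.
#'
#' @param lex named list word -> character vector of emotions (the
#'   `emotions` element of a [load_lexicons] bundle).
#' @param word a single word or stem.
#' @param stemmer stemming function for the fallback lookup.
#' @return character vector of emotions (possibly empty).
#' @export
emotions_of <- function(lex, word, stemmer = porter_stem) {
  word <- tolower(word)
  hit <- lex[[word]]
  if (is.null(hit)) hit <- lex[[stemmer(word)]]
  if (is.null(hit)) character(0) else hit
}

# emotion lookup table keyed by stem as well as surface form, used where
# many lookups are needed (profiles, nulls)
stem_emotion_index <- function(lex, stemmer = porter_stem) {
  idx <- lex
  stems <- stemmer(names(lex))
  new <- !stems %in% names(lex) & !duplicated(stems)
  idx[stems[new]] <- lex[new]
  idx
}
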
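#' Clean a short-text document
#'
#' Applies the preprocessing used for tweet-like corpora: URLs are removed,
#' `#` and `@` marker characters are stripped (the hashtag/handle text
#' itself is kept as a token), emoji and other pictographic codepoints are
#' discarded, and whitespace is normalised. The function is idempotent.
#'
#' @param raw character vector of raw document texts.
#' @param strip_mentions if TRUE, remove `@mention` tokens entirely instead
#'   of keeping the handle text (the default keeps it, symmetric with
#'   hashtag handling).
#' @return character vector of cleaned texts.
#' @export
clean_text <- function(raw, strip_mentions = FALSE) {
  x <- raw
  x <- gsub("(https?://|www\\.)\\S+", " ", x, perl = TRUE)
  if (strip_mentions) x <- gsub("@\\S+", " ", x, perl = TRUE)
  x <- gsub("[#@]", "", x, perl = TRUE)
  # emoji / pictographs / symbols outside basic multilingual text
  x <- gsub("[\U0001F000-\U0001FAFF\U00002600-\U000027BF\U0001F1E6-\U0001F1FF\U00002190-\U000021FF\U00002B00-\U00002BFF\UFE0F\U0000200D]",
            " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Admit a document into the corpus
#'
#' Documents with fewer than `min_words` whitespace-separated tokens (after
#' cleaning) are excluded from network construction.
#'
#' @param cleaned character vector of cleaned texts.
#' @param min_words minimum token count (default 3).
#' @return logical vector.
#' @export
admit_document <- function(cleaned, min_words = 3) {
  n_tokens <- lengths(strsplit(trimws(cleaned), "\\s+"))
  n_tokens[!nzchar(trimws(cleaned))] <- 0L
  n_tokens >= min_words
}

#' Split a cleaned document into sentences
#'
#' Naive terminal-punctuation splitter on `.`, `!`, `?`. Abbreviation-aware
#' splitting is delegated to a parser backend when one provides it; the
#' rule-based splitter here will split after abbreviations such as "Dr.".
#'
#' @param cleaned a single cleaned text.
#' @return character vector of non-empty sentences.
#' @export
split_sentences <- function(cleaned) {
  parts <- strsplit(cleaned, "(?<=[.!?])\\s+|(?<=[.!?])$", perl = TRUE)[[1]]
  parts <- gsub("[.!?]+$", "", trimws(parts))
  parts[nzchar(parts)]
}

#' Read a corpus of short documents
#'
#' Accepts plain text (one document per line) or CSV with columns `id` and
#' `text` (header required). Returns cleaned, admitted, sentence-split
#' documents.
#'
#' @param path file path.
#' @param format "txt", "csv", or "auto" (by extension).
#' @param min_words admission threshold, see [admit_document].
#' @param strip_mentions see [clean_text].
#' @return a `corpus` object: list of documents, each with `id`, `raw`,
#'   `cleaned`, `sentences`; attribute `n_discarded` counts documents
#'   dropped by the length filter.
#' @export
read_corpus <- function(path, format = c("auto", "txt", "csv"),
                        min_words = 3, strip_mentions = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  }
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    if (!all(c("id", "text") %in% names(df))) {
      stop("CSV corpus must have 'id' and 'text' columns", call. = FALSE)
    }
    ids <- as.character(df$id); raw <- as.character(df$text)
  } else {
    raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
    raw <- raw[nzchar(trimws(raw))]
    ids <- as.character(seq_along(raw))
  }
  as_corpus(raw, ids = ids, min_words = min_words,
            strip_mentions = strip_mentions)
}

#' Build a corpus object from raw texts in memory
#'
#' @param raw character vector of raw documents.
#' @param ids document identifiers (default positional).
#' @inheritParams read_corpus
#' @return a `corpus` object (see [read_corpus]).
#' @export
as_corpus <- function(raw, ids = as.character(seq_along(raw)),
                      min_words = 3, strip_mentions = FALSE) {
  cleaned <- clean_text(raw, strip_mentions = strip_mentions)
  keep <- admit_document(cleaned, min_words = min_words)
  docs <- Map(function(id, r, cl) {
    list(id = id, raw = r, cleaned = cl, sentences = split_sentences(cl))
  }, ids[keep], raw[keep], cleaned[keep])
  structure(unname(docs), class = "corpus", n_discarded = sum(!keep))
}

#' @export
print.corpus <- function(x, ...) {
  cat("<corpus> ", length(x), " admitted documents (",
      attr(x, "n_discarded"), " discarded by length filter)\n", sep = "")
  invisible(x)
}
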
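#' Porter stemmer
#'
#' Reduces an English word to its stem with Porter's (1980) suffix-stripping
#' algorithm. Network nodes, valence tables and emotion lookups all operate
#' on stems so that inflected forms such as "weak" and "weakness" collapse
#' onto a single concept.
#'
#' The function is deterministic and vectorised; input is lowercased before
#' stemming. Words of two characters or fewer, and tokens containing no
#' alphabetic vowel pattern (e.g. numbers), are returned unchanged apart
#' from lowercasing.
#'
#' @param words character vector of words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("happiness", "happy", "weakness", "winning"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), porter_stem1, character(1), USE.NAMES = FALSE)
}

# consonant/vowel mask: TRUE = consonant. 'y' is a consonant when it starts
# the word or follows a vowel position classified as consonant.
.pm_cons <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# Porter's measure m: number of VC alternations in [C](VC)^m[V]
.pm_m <- function(stem) {
  cons <- .pm_cons(strsplit(stem, "", fixed = TRUE)[[1]])
  if (length(cons) == 0L) return(0L)
  blocks <- rle(cons)$values
  if (blocks[1]) blocks <- blocks[-1]          # optional initial C
  if (length(blocks) && !blocks[length(blocks)]) blocks <- blocks[-length(blocks)]
  length(blocks) %/% 2L + length(blocks) %% 2L # pairs V,C
}

.pm_has_vowel <- function(stem) {
  any(!.pm_cons(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.pm_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L); b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  cons <- .pm_cons(strsplit(stem, "", fixed = TRUE)[[1]])
  cons[n]
}

# *o condition: stem ends cvc where the final c is not w, x or y
.pm_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  cons <- .pm_cons(strsplit(stem, "", fixed = TRUE)[[1]])
  last <- substr(stem, n, n)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(last %in% c("w", "x", "y"))
}

.pm_ends <- function(w, suf) {
  nw <- nchar(w); ns <- nchar(suf)
  nw > ns && substr(w, nw - ns + 1L, nw) == suf
}

.pm_chop <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))

porter_stem1 <- function(w) {
  if (nchar(w) <= 2L || !grepl("[a-z]", w)) return(w)

  # step 1a
  if (.pm_ends(w, "sses")) w <- paste0(.pm_chop(w, "sses"), "ss")
  else if (.pm_ends(w, "ies")) w <- paste0(.pm_chop(w, "ies"), "i")
  else if (.pm_ends(w, "ss")) w <- w
  else if (.pm_ends(w, "s")) w <- .pm_chop(w, "s")

  # step 1b
  step1b_fix <- FALSE
  if (.pm_ends(w, "eed")) {
    if (.pm_m(.pm_chop(w, "eed")) > 0L) w <- .pm_chop(w, "d")
  } else if (.pm_ends(w, "ed") && .pm_has_vowel(.pm_chop(w, "ed"))) {
    w <- .pm_chop(w, "ed"); step1b_fix <- TRUE
  } else if (.pm_ends(w, "ing") && .pm_has_vowel(.pm_chop(w, "ing"))) {
    w <- .pm_chop(w, "ing"); step1b_fix <- TRUE
  }
  if (step1b_fix) {
    if (.pm_ends(w, "at") || .pm_ends(w, "bl") || .pm_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.pm_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.pm_m(w) == 1L && .pm_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (.pm_ends(w, "y") && .pm_has_vowel(.pm_chop(w, "y"))) {
    w <- paste0(.pm_chop(w, "y"), "i")
  }

  # step 2 (m > 0)
  s2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
          izer = "ize", abli = "able", alli = "al", entli = "ent",
          eli = "e", ousli = "ous", ization = "ize", ation = "ate",
          ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
          ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(s2)) {
    if (.pm_ends(w, suf)) {
      stem <- .pm_chop(w, suf)
      if (.pm_m(stem) > 0L) w <- paste0(stem, s2[[suf]])
      break
    }
  }

  # step 3 (m > 0)
  s3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
          ical = "ic", ful = "", ness = "")
  for (suf in names(s3)) {
    if (.pm_ends(w, suf)) {
      stem <- .pm_chop(w, suf)
      if (.pm_m(stem) > 0L) w <- paste0(stem, s3[[suf]])
      break
    }
  }

  # step 4 (m > 1)
  s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
          "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive",
          "ize")
  for (suf in s4) {
    if (.pm_ends(w, suf)) {
      stem <- .pm_chop(w, suf)
      ok <- .pm_m(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (.pm_ends(w, "e")) {
    stem <- .pm_chop(w, "e")
    m <- .pm_m(stem)
    if (m > 1L || (m == 1L && !.pm_cvc(stem))) w <- stem
  }
  # step 5b
  if (.pm_m(w) > 1L && .pm_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}
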
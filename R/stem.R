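# Porter (1980) English stemmer and the fixed stop-word list used throughout
# the package. Both are pinned: golden tokenization fixtures depend on them.

.vowels <- c("a", "e", "i", "o", "u")

# consonant at position i: not a/e/i/o/u, and a "y" only when it is the first
# letter or follows a vowel
.is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% .vowels) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.is_cons(chars, i - 1L))
  }
  TRUE
}

# measure m of a stem: number of VC blocks in [C](VC){m}[V]
.measure <- function(chars) {
  n <- length(chars)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) .is_cons(chars, i), logical(1))
  m <- 0L
  prev <- types[1L]
  for (i in seq_len(n)[-1L]) {
    if (types[i] && !prev) m <- m + 1L
    prev <- types[i]
  }
  m
}

.has_vowel <- function(chars) {
  n <- length(chars)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) .is_cons(chars, i), logical(1)))
}

.ends_double_cons <- function(chars) {
  n <- length(chars)
  n >= 2L && chars[n] == chars[n - 1L] && .is_cons(chars, n)
}

# *o: stem ends cvc where the final c is not w, x or y
.ends_cvc <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(FALSE)
  .is_cons(chars, n - 2L) && !.is_cons(chars, n - 1L) && .is_cons(chars, n) &&
    !(chars[n] %in% c("w", "x", "y"))
}

.ends_with <- function(chars, suffix) {
  s <- strsplit(suffix, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  k <- length(s)
  n >= k && identical(chars[(n - k + 1L):n], s)
}

.chop <- function(chars, k) {
  if (k >= length(chars)) character(0) else chars[seq_len(length(chars) - k)]
}

# apply the longest-matching rule of a step-2/3/4 style table;
# rules: list of c(suffix, replacement); cond takes the stem chars
.apply_table <- function(chars, rules, cond) {
  for (r in rules) {
    if (.ends_with(chars, r[[1L]])) {
      stem <- .chop(chars, nchar(r[[1L]]))
      if (cond(stem)) {
        repl <- if (nzchar(r[[2L]])) strsplit(r[[2L]], "", fixed = TRUE)[[1L]] else character(0)
        return(c(stem, repl))
      }
      return(chars)  # longest suffix matched but condition failed: stop
    }
  }
  chars
}

.step1a <- function(chars) {
  if (.ends_with(chars, "sses")) return(c(.chop(chars, 4L), c("s", "s")))
  if (.ends_with(chars, "ies")) return(c(.chop(chars, 3L), "i"))
  if (.ends_with(chars, "ss")) return(chars)
  if (.ends_with(chars, "s")) return(.chop(chars, 1L))
  chars
}

.step1b <- function(chars) {
  if (.ends_with(chars, "eed")) {
    stem <- .chop(chars, 3L)
    if (.measure(stem) > 0L) return(.chop(chars, 1L))
    return(chars)
  }
  fired <- FALSE
  if (.ends_with(chars, "ed")) {
    stem <- .chop(chars, 2L)
    if (.has_vowel(stem)) { chars <- stem; fired <- TRUE }
  } else if (.ends_with(chars, "ing")) {
    stem <- .chop(chars, 3L)
    if (.has_vowel(stem)) { chars <- stem; fired <- TRUE }
  }
  if (fired) {
    if (.ends_with(chars, "at") || .ends_with(chars, "bl") || .ends_with(chars, "iz")) {
      chars <- c(chars, "e")
    } else if (.ends_double_cons(chars) && !(chars[length(chars)] %in% c("l", "s", "z"))) {
      chars <- .chop(chars, 1L)
    } else if (.measure(chars) == 1L && .ends_cvc(chars)) {
      chars <- c(chars, "e")
    }
  }
  chars
}

.step1c <- function(chars) {
  if (.ends_with(chars, "y") && .has_vowel(.chop(chars, 1L))) {
    chars[length(chars)] <- "i"
  }
  chars
}

.step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

.step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.step4_suffixes <- c(
  "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent", "ion", "ism",
  "ate", "iti", "ous", "ive", "ize", "al", "er", "ic", "ou"
)

.step4 <- function(chars) {
  for (suf in .step4_suffixes) {
    if (.ends_with(chars, suf)) {
      stem <- .chop(chars, nchar(suf))
      ok <- .measure(stem) > 1L
      if (suf == "ion") {
        n <- length(stem)
        ok <- ok && n >= 1L && stem[n] %in% c("s", "t")
      }
      if (ok) return(stem)
      return(chars)
    }
  }
  chars
}

.step5 <- function(chars) {
  if (.ends_with(chars, "e")) {
    stem <- .chop(chars, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) chars <- stem
  }
  if (.ends_double_cons(chars) && chars[length(chars)] == "l" &&
      .measure(.chop(chars, 1L)) > 1L) {
    chars <- .chop(chars, 1L)
  }
  chars
}

.porter_one <- function(word) {
  if (nchar(word) <= 2L) return(word)
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  chars <- .step1a(chars)
  chars <- .step1b(chars)
  chars <- .step1c(chars)
  chars <- .apply_table(chars, .step2_rules, function(s) .measure(s) > 0L)
  chars <- .apply_table(chars, .step3_rules, function(s) .measure(s) > 0L)
  chars <- .step4(chars)
  chars <- .step5(chars)
  paste(chars, collapse = "")
}

#' Stem English words with the Porter algorithm
#'
#' Deterministic implementation of Porter's (1980) suffix-stripping algorithm
#' for English. Words of one or two characters are returned unchanged. Input
#' is expected to be lowercase; the stemmer does not lowercase for you.
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("distributions", "hypergeometric", "genomics"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  # memoise within the call: corpora repeat words heavily
  uw <- unique(words)
  stems <- vapply(uw, .porter_one, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}

#' English stop-word list
#'
#' The fixed stop-word list applied before stemming. Shipping a pinned list
#' keeps tokenization (and every statistic built on it) stable across
#' releases.
#'
#' @return Character vector of lowercase stop words.
#' @export
stop_words <- function() .STOP_WORDS

.STOP_WORDS <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you", "your",
  "yours", "yourself", "yourselves", "he", "him", "his", "himself", "she",
  "her", "hers", "herself", "it", "its", "itself", "they", "them", "their",
  "theirs", "themselves", "what", "which", "who", "whom", "this", "that",
  "these", "those", "am", "is", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing", "would",
  "should", "could", "ought", "a", "an", "the", "and", "but", "if", "or",
  "because", "as", "until", "while", "of", "at", "by", "for", "with", "about",
  "against", "between", "into", "through", "during", "before", "after",
  "above", "below", "to", "from", "up", "down", "in", "out", "on", "off",
  "over", "under", "again", "further", "then", "once", "here", "there",
  "when", "where", "why", "how", "all", "any", "both", "each", "few", "more",
  "most", "other", "some", "such", "no", "nor", "not", "only", "own", "same",
  "so", "than", "too", "very", "can", "cannot", "will", "just", "don",
  "now", "also", "may", "might", "must", "shall", "us", "upon", "among",
  "within", "without", "via", "per", "et", "al"
)
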
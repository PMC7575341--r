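#' Tokenization, stemming and syllable counting
#'
#' Deterministic, dependency-free text primitives shared by every feature
#' family: a lowercasing tokenizer that keeps intra-word apostrophes, a
#' Porter-style suffix-stripping stemmer for TF-IDF n-grams, and a
#' rule-based vowel-group syllable counter with a small exceptions table.
#'
#' @name text-primitives
NULL

#' Tokenize text
#'
#' Lowercases, strips punctuation except intra-word apostrophes, and counts
#' sentences as runs of `.?!` (minimum 1).
#'
#' @param text character vector.
#' @return list with `tokens` (list of token vectors) and `sentences`
#'   (integer vector).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text))
  low <- tolower(text)
  toks <- regmatches(low, gregexpr("[a-z0-9]+(?:'[a-z0-9]+)*", low, perl = TRUE))
  sent <- vapply(gregexpr("[.?!]+", text), function(m) sum(m[1] != -1L & m > 0L),
                 numeric(1))
  sent <- as.integer(pmax(1, sent))
  list(tokens = toks, sentences = sent)
}

## ---- Porter-style stemmer -------------------------------------------------

p_cons <- function(w, i) {
  ch <- substr(w, i, i)
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") return(if (i == 1L) TRUE else !p_cons(w, i - 1L))
  TRUE
}

p_measure <- function(w) {
  n <- nchar(w)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) p_cons(w, i), logical(1))
  # collapse runs, count VC transitions
  runs <- rle(types)$values
  sum(head(runs, -1) == FALSE & tail(runs, -1) == TRUE)
}

p_has_vowel <- function(w) {
  n <- nchar(w)
  n > 0L && any(!vapply(seq_len(n), function(i) p_cons(w, i), logical(1)))
}

p_ends_double_cons <- function(w) {
  n <- nchar(w)
  n >= 2L && substr(w, n, n) == substr(w, n - 1L, n - 1L) && p_cons(w, n)
}

p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  p_cons(w, n - 2L) && !p_cons(w, n - 1L) && p_cons(w, n) &&
    !(substr(w, n, n) %in% c("w", "x", "y"))
}

p_repl <- function(w, suf, rep) paste0(substr(w, 1L, nchar(w) - nchar(suf)), rep)

#' Porter-style stem of a single lowercase word
#'
#' Classic suffix-stripping steps (plural and participle removal, y->i,
#' double-suffix reduction, e-deletion). Words shorter than 3 characters are
#' returned unchanged.
#'
#' @param word single lowercase token (apostrophes removed internally).
#' @return character stem.
#' @export
porter_stem <- function(word) {
  w <- gsub("'", "", word, fixed = TRUE)
  if (nchar(w) < 3L || grepl("[^a-z]", w)) return(w)
  # step 1a
  if (endsWith(w, "sses")) w <- p_repl(w, "sses", "ss")
  else if (endsWith(w, "ies")) w <- p_repl(w, "ies", "i")
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- p_repl(w, "s", "")
  # step 1b
  flag <- FALSE
  if (endsWith(w, "eed")) {
    if (p_measure(substr(w, 1, nchar(w) - 3L)) > 0L) w <- p_repl(w, "eed", "ee")
  } else if (endsWith(w, "ed") && p_has_vowel(substr(w, 1, nchar(w) - 2L))) {
    w <- p_repl(w, "ed", ""); flag <- TRUE
  } else if (endsWith(w, "ing") && p_has_vowel(substr(w, 1, nchar(w) - 3L))) {
    w <- p_repl(w, "ing", ""); flag <- TRUE
  }
  if (flag) {
    if (endsWith(w, "at")) w <- paste0(w, "e")
    else if (endsWith(w, "bl")) w <- paste0(w, "e")
    else if (endsWith(w, "iz")) w <- paste0(w, "e")
    else if (p_ends_double_cons(w) && !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))
      w <- substr(w, 1L, nchar(w) - 1L)
    else if (p_measure(w) == 1L && p_cvc(w)) w <- paste0(w, "e")
  }
  # step 1c
  if (endsWith(w, "y") && p_has_vowel(substr(w, 1, nchar(w) - 1L)))
    w <- p_repl(w, "y", "i")
  # step 2
  s2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
          izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
          ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
          alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
          aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(s2)) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (p_measure(stem) > 0L) w <- paste0(stem, s2[[suf]])
      break
    }
  }
  # step 3
  s3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
          ical = "ic", ful = "", ness = "")
  for (suf in names(s3)) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (p_measure(stem) > 0L) w <- paste0(stem, s3[[suf]])
      break
    }
  }
  # step 4
  s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
          "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize")
  for (suf in s4) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (suf == "ion" && !(endsWith(stem, "s") || endsWith(stem, "t"))) next
      if (p_measure(stem) > 1L) w <- stem
      break
    }
  }
  # step 5a
  if (endsWith(w, "e")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    m <- p_measure(stem)
    if (m > 1L || (m == 1L && !p_cvc(stem))) w <- stem
  }
  # step 5b
  if (p_measure(w) > 1L && p_ends_double_cons(w) && endsWith(w, "l"))
    w <- substr(w, 1L, nchar(w) - 1L)
  w
}

## memoized vectorized stemming over unique tokens
stem_tokens <- function(tokens) {
  u <- unique(tokens)
  stems <- vapply(u, porter_stem, character(1), USE.NAMES = FALSE)
  stems[match(tokens, u)]
}

## ---- syllables ------------------------------------------------------------

syllable_exceptions <- c(
  the = 1, a = 1, i = 1, area = 3, being = 2, quiet = 2, science = 2,
  create = 2, created = 3, really = 2, people = 2, every = 2, everything = 3,
  idea = 3, poem = 2
)

#' Count syllables in words
#'
#' Vowel-group heuristic: count maximal runs of `aeiouy`, subtract a final
#' silent `e` (kept after a consonant+`l`), minimum 1, with a small
#' exceptions table.
#'
#' @param words character vector of lowercase words.
#' @return integer vector of syllable counts.
#' @export
count_syllables <- function(words) {
  w <- gsub("[^a-z]", "", tolower(words))
  out <- integer(length(w))
  groups <- vapply(gregexpr("[aeiouy]+", w), function(m) sum(m[1] != -1L & m > 0L),
                   numeric(1))
  silent_e <- grepl("[^aeiouyl]e$", w) & groups > 1
  ed_silent <- grepl("[^aeiouydt]ed$", w) & groups > 1
  out <- as.integer(pmax(1, groups - silent_e - ed_silent))
  exc <- match(w, names(syllable_exceptions))
  out[!is.na(exc)] <- as.integer(syllable_exceptions[exc[!is.na(exc)]])
  out[nchar(w) == 0L] <- 0L
  out
}
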
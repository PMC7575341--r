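#' Category-lexicon engine
#'
#' An open replacement for proprietary category dictionaries: each lexicon is
#' a named set of lowercase entries that may be literal tokens, stem
#' wildcards (a terminal `*` matches any token with that prefix), or
#' multiword phrases (words joined by `_`). Matching is against a post's
#' token sequence; phrases are matched greedily left-to-right and each
#' consumed token is counted once.
#'
#' @name lexicon-engine
NULL

#' Construct a lexicon
#'
#' @param name lexicon identifier.
#' @param entries character vector of lowercase entries; trailing `*` marks a
#'   stem wildcard, `_` joins the words of a phrase.
#' @return a `mind_lexicon` object with entries split into exact / prefix /
#'   phrase match tables.
#' @export
lexicon <- function(name, entries) {
  stopifnot(is.character(name), length(name) == 1L, is.character(entries))
  entries <- unique(trimws(tolower(entries)))
  entries <- entries[nzchar(entries)]
  bad <- grepl("\\*.", entries)
  if (any(bad)) stop("wildcard '*' must be terminal: ", paste(entries[bad], collapse = ", "))
  is_phrase <- grepl("_", entries, fixed = TRUE)
  is_prefix <- !is_phrase & endsWith(entries, "*")
  structure(list(
    name = name,
    entries = entries,
    exact = entries[!is_phrase & !is_prefix],
    prefixes = sub("\\*$", "", entries[is_prefix]),
    phrases = strsplit(entries[is_phrase], "_", fixed = TRUE)
  ), class = "mind_lexicon")
}

#' @export
print.mind_lexicon <- function(x, ...) {
  cat("<lexicon '", x$name, "': ", length(x$entries), " entries (",
      length(x$exact), " exact, ", length(x$prefixes), " stems, ",
      length(x$phrases), " phrases)>\n", sep = "")
  invisible(x)
}

#' Read lexicons from a TSV of `category<TAB>entry` rows
#'
#' @param path TSV file with a header row; one entry per line.
#' @return named list of `mind_lexicon` objects, in first-appearance order.
#' @export
read_lexicons <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  stopifnot(ncol(tab) >= 2)
  cats <- unique(tab[[1]])
  out <- lapply(cats, function(cc) lexicon(cc, tab[[2]][tab[[1]] == cc]))
  names(out) <- cats
  out
}

## single-column token list (wildcards allowed), e.g. the event lexicon
read_token_list <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lexicon(name, lines[nzchar(trimws(lines))])
}

#' Bundled default lexicons
#'
#' The 62 category lexicons, the 6 custom lexicons (suicidality, economic
#' stress, isolation, substance use, domestic stress, guns), the event token
#' list, and the sentiment valence table shipped with the package. Word lists
#' are editable data files; the engine, not the lists, is the contract.
#'
#' @param which one of "categories", "custom", "event", "valence".
#' @return lexicon list ("categories"/"custom"), a single lexicon ("event"),
#'   or a named numeric valence vector ("valence").
#' @export
bundled_lexicons <- function(which = c("categories", "custom", "event", "valence")) {
  which <- match.arg(which)
  f <- function(x) system.file("extdata", x, package = "mindlang", mustWork = TRUE)
  switch(which,
    categories = read_lexicons(f("category_lexicons.tsv")),
    custom     = read_lexicons(f("custom_lexicons.tsv")),
    event      = read_token_list(f("event_tokens.txt"), "event"),
    valence    = {
      tab <- utils::read.delim(f("valence_lexicon.tsv"), header = TRUE,
                               stringsAsFactors = FALSE, quote = "")
      stats::setNames(as.numeric(tab$valence), tab$word)
    })
}

#' Count lexicon matches in a token sequence
#'
#' Phrases are matched first, greedily left-to-right; tokens consumed by a
#' phrase are not re-counted by exact or stem entries of the same lexicon.
#'
#' @param tokens lowercase token vector.
#' @param lex a `mind_lexicon`.
#' @return integer match count.
#' @export
count_matches <- function(tokens, lex) {
  stopifnot(inherits(lex, "mind_lexicon"))
  n <- length(tokens)
  if (n == 0L) return(0L)
  consumed <- rep(FALSE, n)
  count <- 0L
  for (ph in lex$phrases) {
    L <- length(ph)
    if (L > n) next
    i <- 1L
    while (i <= n - L + 1L) {
      if (!any(consumed[i:(i + L - 1L)]) && all(tokens[i:(i + L - 1L)] == ph)) {
        consumed[i:(i + L - 1L)] <- TRUE
        count <- count + 1L
        i <- i + L
      } else i <- i + 1L
    }
  }
  free <- !consumed
  if (length(lex$exact)) {
    hit <- free & (tokens %in% lex$exact)
    count <- count + sum(hit)
    free <- free & !hit
  }
  if (length(lex$prefixes)) {
    for (pf in lex$prefixes) {
      hit <- free & startsWith(tokens, pf)
      count <- count + sum(hit)
      free <- free & !hit
    }
  }
  count
}

#' Lexicon features for a list of token vectors
#'
#' Per post and lexicon, the matched proportion
#' (match count) / (token count). Empty lexicons yield 0 with a warning.
#'
#' @param token_list list of lowercase token vectors (one per post).
#' @param lexicons named list of `mind_lexicon` objects.
#' @return numeric matrix, posts x lexicons, values in [0,1].
#' @export
lexicon_features <- function(token_list, lexicons) {
  stopifnot(is.list(token_list), length(lexicons) >= 1)
  nm <- vapply(lexicons, function(l) l$name, character(1))
  empty <- vapply(lexicons, function(l) length(l$entries) == 0L, logical(1))
  if (any(empty)) warning("empty lexicons emitted as 0: ", paste(nm[empty], collapse = ", "))
  ntok <- lengths(token_list)
  out <- matrix(0, nrow = length(token_list), ncol = length(lexicons),
                dimnames = list(NULL, nm))
  simple <- vapply(lexicons, function(l) length(l$phrases) == 0L, logical(1))
  ## fast path: no phrases -> vectorized membership over the flattened corpus
  if (any(simple)) {
    all_tok <- unlist(token_list, use.names = FALSE)
    post_id <- rep.int(seq_along(token_list), ntok)
    for (j in which(simple & !empty)) {
      lex <- lexicons[[j]]
      hit <- all_tok %in% lex$exact
      for (pf in lex$prefixes) hit <- hit | startsWith(all_tok, pf)
      if (any(hit)) {
        cnt <- tabulate(post_id[hit], nbins = length(token_list))
        out[, j] <- cnt
      }
    }
  }
  for (j in which(!simple & !empty)) {
    out[, j] <- vapply(token_list, count_matches, integer(1), lex = lexicons[[j]])
  }
  out / pmax(1L, ntok)
}
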
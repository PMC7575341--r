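#' Psycholinguistic feature extraction
#'
#' Converts post text into the fixed 90-feature families — 62 category
#' lexicons, 4 sentiment outputs, 8 surface counts, 1 punctuation measure,
#' 9 readability metrics, 6 custom lexicons — plus V TF-IDF n-grams fitted
#' on a declared reference period. Extraction is a pure function of
#' (text, spec, fitted TF-IDF): repeated calls are identical.
#'
#' @name feature-extraction
NULL

#' Default feature specification
#'
#' @param categories,custom,valence lexicon resources; defaults to the
#'   bundled ones.
#' @param tfidf_v TF-IDF vocabulary size (0 disables; clamped to
#'   [256, 1024] when positive unless `tfidf_v_free`).
#' @param ngram_range integer length-2, n-gram sizes (default 1-2).
#' @param stem use Porter-style stems for TF-IDF n-grams.
#' @param tfidf_v_free allow vocabulary sizes outside [256, 1024] (toy runs).
#' @return a `mind_feature_spec`.
#' @export
feature_spec <- function(categories = bundled_lexicons("categories"),
                         custom = bundled_lexicons("custom"),
                         valence = bundled_lexicons("valence"),
                         tfidf_v = 256, ngram_range = c(1L, 2L),
                         stem = TRUE, tfidf_v_free = FALSE) {
  if (tfidf_v > 0 && !tfidf_v_free) {
    tfidf_v <- min(1024L, max(256L, as.integer(tfidf_v)))
  }
  structure(list(categories = categories, custom = custom, valence = valence,
                 tfidf_v = as.integer(tfidf_v),
                 ngram_range = as.integer(ngram_range), stem = stem),
            class = "mind_feature_spec")
}

#' @export
print.mind_feature_spec <- function(x, ...) {
  cat("<feature spec: ", length(x$categories), " categories + 4 sentiment + ",
      "8 surface + 1 punctuation + 9 readability + ", length(x$custom),
      " custom lexicons; tfidf V=", x$tfidf_v, ">\n", sep = "")
  invisible(x)
}

surface_feature_names <- c("n_tokens", "n_chars", "n_sentences",
                           "avg_token_length", "n_syllables",
                           "avg_syllables_per_token", "n_complex_words",
                           "type_token_ratio")
readability_feature_names <- c("flesch_reading_ease", "flesch_kincaid_grade",
                               "gunning_fog", "smog_index",
                               "automated_readability_index",
                               "coleman_liau_index", "lix", "rix", "forcast")

#' Surface counts, punctuation and readability metrics
#'
#' Word/syllable statistics and nine published readability formulas computed
#' from this package's token, syllable and sentence counts. Complex words
#' have >= 3 syllables; long words (LIX/RIX) have > 6 characters.
#'
#' @param text character vector of post texts.
#' @return numeric matrix with the 8 surface, 1 punctuation and 9
#'   readability columns.
#' @export
surface_and_readability <- function(text) {
  tk <- tokenize(text)
  toks <- tk$tokens
  sents <- tk$sentences
  n_tok <- pmax(1L, lengths(toks))
  uniq_tok <- unique(unlist(toks, use.names = FALSE))
  syl_map <- stats::setNames(count_syllables(uniq_tok), uniq_tok)
  per_post <- function(f) vapply(toks, f, numeric(1))
  n_chars <- per_post(function(t) sum(nchar(gsub("'", "", t))))
  n_syl <- per_post(function(t) sum(syl_map[t]))
  n_complex <- per_post(function(t) sum(syl_map[t] >= 3))
  n_mono <- per_post(function(t) sum(syl_map[t] == 1))
  n_long <- per_post(function(t) sum(nchar(gsub("'", "", t)) > 6))
  n_types <- per_post(function(t) length(unique(t)))
  n_punct <- vapply(gregexpr("[[:punct:]]", text),
                    function(m) sum(m[1] != -1L & m > 0L), numeric(1))
  wps <- n_tok / sents
  spw <- n_syl / n_tok
  out <- cbind(
    n_tokens = as.numeric(lengths(toks)),
    n_chars = n_chars,
    n_sentences = as.numeric(sents),
    avg_token_length = n_chars / n_tok,
    n_syllables = n_syl,
    avg_syllables_per_token = spw,
    n_complex_words = n_complex,
    type_token_ratio = n_types / n_tok,
    punct_ratio = n_punct / n_tok,
    flesch_reading_ease = 206.835 - 1.015 * wps - 84.6 * spw,
    flesch_kincaid_grade = 0.39 * wps + 11.8 * spw - 15.59,
    gunning_fog = 0.4 * (wps + 100 * n_complex / n_tok),
    smog_index = 1.0430 * sqrt(n_complex * 30 / sents) + 3.1291,
    automated_readability_index = 4.71 * n_chars / n_tok + 0.5 * wps - 21.43,
    coleman_liau_index = 0.0588 * (100 * n_chars / n_tok) -
      0.296 * (100 * sents / n_tok) - 15.8,
    lix = wps + 100 * n_long / n_tok,
    rix = n_long / sents,
    forcast = 20 - (n_mono * 150 / n_tok) / 10
  )
  out[!is.finite(out)] <- 0
  out
}

#' Valence-lexicon sentiment
#'
#' Negative / neutral / positive proportions (summing to 1) from a bundled
#' valence lexicon, plus a compound score: the summed token valence S
#' normalized by the saturating S / sqrt(S^2 + 15), in [-1, 1].
#'
#' @param text character vector.
#' @param valence named numeric valence table.
#' @return numeric matrix with columns `sent_negative`, `sent_neutral`,
#'   `sent_positive`, `sent_compound`.
#' @export
sentiment_features <- function(text, valence = bundled_lexicons("valence")) {
  toks <- tokenize(text)$tokens
  out <- t(vapply(toks, function(t) {
    v <- valence[t]
    v[is.na(v)] <- 0
    pos <- sum(v[v > 0] + 1)
    neg <- sum(abs(v[v < 0]) + 1)
    neu <- sum(v == 0)
    tot <- pos + neg + neu
    if (tot == 0) return(c(0, 1, 0, 0))
    s <- sum(v)
    c(neg / tot, neu / tot, pos / tot, s / sqrt(s^2 + 15))
  }, numeric(4)))
  colnames(out) <- c("sent_negative", "sent_neutral", "sent_positive",
                     "sent_compound")
  out
}

## stemmed n-grams of one token vector
make_ngrams <- function(tokens, ngram_range, stem) {
  if (stem) tokens <- stem_tokens(tokens)
  out <- character(0)
  for (n in seq(ngram_range[1], ngram_range[2])) {
    if (length(tokens) < n) next
    if (n == 1L) out <- c(out, tokens)
    else {
      m <- length(tokens) - n + 1L
      grams <- tokens[seq_len(m)]
      for (j in seq_len(n - 1L)) grams <- paste(grams, tokens[seq_len(m) + j])
      out <- c(out, grams)
    }
  }
  out
}

#' Fit a TF-IDF vocabulary
#'
#' Vocabulary = the `v` stemmed n-grams with highest document frequency,
#' ties broken lexicographically; smooth idf = log((1+N)/(1+df)) + 1.
#'
#' @param texts character vector (>= 2 documents).
#' @param spec a `mind_feature_spec`.
#' @param v vocabulary size override (defaults to `spec$tfidf_v`).
#' @return a `mind_tfidf` with `vocab`, `idf`, and the n-gram settings.
#' @export
fit_tfidf <- function(texts, spec = feature_spec(), v = spec$tfidf_v) {
  stopifnot(length(texts) >= 2, v >= 1)
  toks <- tokenize(texts)$tokens
  grams <- lapply(toks, make_ngrams, ngram_range = spec$ngram_range,
                  stem = spec$stem)
  df <- table(unlist(lapply(grams, unique), use.names = FALSE))
  if (length(df) < v) {
    warning("vocabulary shrunk to ", length(df), " available n-grams")
    v <- length(df)
  }
  ord <- order(-as.numeric(df), names(df))
  vocab <- names(df)[ord][seq_len(v)]
  dfv <- as.numeric(df)[ord][seq_len(v)]
  n <- length(texts)
  idf <- log((1 + n) / (1 + dfv)) + 1
  structure(list(vocab = vocab, idf = stats::setNames(idf, vocab),
                 ngram_range = spec$ngram_range, stem = spec$stem,
                 n_docs = n),
            class = "mind_tfidf")
}

#' @export
print.mind_tfidf <- function(x, ...) {
  cat("<tfidf: V=", length(x$vocab), ", n-grams ", x$ngram_range[1], "-",
      x$ngram_range[2], ", fitted on ", x$n_docs, " documents>\n", sep = "")
  invisible(x)
}

## L2-normalized tf-idf values for each text, columns = fitted vocabulary
tfidf_transform <- function(texts, fitted) {
  toks <- tokenize(texts)$tokens
  out <- matrix(0, nrow = length(texts), ncol = length(fitted$vocab),
                dimnames = list(NULL, fitted$vocab))
  for (i in seq_along(texts)) {
    grams <- make_ngrams(toks[[i]], fitted$ngram_range, fitted$stem)
    idx <- match(grams, fitted$vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    tf <- tabulate(idx, nbins = length(fitted$vocab))
    v <- tf * fitted$idf
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) out[i, ] <- v / nrm
  }
  out
}

#' Extract the full feature matrix
#'
#' @param x a `mind_corpus`, or a character vector of texts.
#' @param spec a `mind_feature_spec`.
#' @param tfidf optional fitted `mind_tfidf` (fit it on the pre-event period
#'   to avoid leakage); NULL yields the 90 fixed features only.
#' @param post_ids row identifiers (taken from the corpus if given).
#' @return a `mind_features` object: numeric matrix `values` (posts x
#'   features), `post_ids`, `feature_names` tagged `family:name`, and
#'   `families`.
#' @export
extract_features <- function(x, spec = feature_spec(), tfidf = NULL,
                             post_ids = NULL) {
  if (inherits(x, "mind_corpus")) {
    texts <- x$posts$text
    post_ids <- x$posts$id
  } else {
    texts <- as.character(x)
    if (is.null(post_ids)) post_ids <- as.character(seq_along(texts))
  }
  stopifnot(length(texts) >= 1, all(nzchar(texts)))
  toks <- tokenize(texts)$tokens
  cat_m <- lexicon_features(toks, spec$categories)
  colnames(cat_m) <- paste0("category:", colnames(cat_m))
  sent_m <- sentiment_features(texts, spec$valence)
  colnames(sent_m) <- paste0("sentiment:", colnames(sent_m))
  sr <- surface_and_readability(texts)
  surf_m <- sr[, surface_feature_names, drop = FALSE]
  colnames(surf_m) <- paste0("surface:", colnames(surf_m))
  punct_m <- sr[, "punct_ratio", drop = FALSE]
  colnames(punct_m) <- "punct:punct_ratio"
  read_m <- sr[, readability_feature_names, drop = FALSE]
  colnames(read_m) <- paste0("readability:", colnames(read_m))
  cust_m <- lexicon_features(toks, spec$custom)
  colnames(cust_m) <- paste0("custom:", colnames(cust_m))
  vals <- cbind(cat_m, sent_m, surf_m, punct_m, read_m, cust_m)
  if (!is.null(tfidf)) {
    tf_m <- tfidf_transform(texts, tfidf)
    colnames(tf_m) <- paste0("tfidf:", colnames(tf_m))
    vals <- cbind(vals, tf_m)
  }
  rownames(vals) <- NULL
  fam <- sub(":.*$", "", colnames(vals))
  structure(list(values = vals, post_ids = post_ids,
                 feature_names = colnames(vals), families = fam),
            class = "mind_features")
}

#' @export
print.mind_features <- function(x, ...) {
  cat("<feature matrix: ", nrow(x$values), " posts x ", ncol(x$values),
      " features (", paste(names(table(x$families)), collapse = ", "), ")>\n",
      sep = "")
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Columns are `post_id` plus the `family:name` feature columns.
#'
#' @param x a `mind_features`.
#' @param path CSV path.
#' @export
write_features <- function(x, path) {
  df <- data.frame(post_id = x$post_ids, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  structure(list(values = vals, post_ids = as.character(df$post_id),
                 feature_names = colnames(vals),
                 families = sub(":.*$", "", colnames(vals))),
            class = "mind_features")
}
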
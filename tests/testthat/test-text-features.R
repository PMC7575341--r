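# Tokenizer, stemmer, lexicon engine and the fixed feature families.

test_that("tokenizer keeps intra-word apostrophes and counts sentence runs", {
  tk <- tokenize("Can't stop googling symptoms.")
  expect_identical(tk$tokens[[1]], c("can't", "stop", "googling", "symptoms"))
  expect_equal(tk$sentences, 1L)
  expect_equal(tokenize("Hi. Hi. Hi.")$sentences, 3L)
  expect_equal(length(tokenize("Hi. Hi. Hi.")$tokens[[1]]), 3L)
  expect_equal(tokenize("no terminator here")$sentences, 1L)
  expect_equal(tokenize("what?! really...")$sentences, 2L)
})

test_that("Porter-style stemmer maps inflections onto shared stems", {
  expect_equal(porter_stem("purging"), "purg")
  expect_equal(porter_stem("purged"), "purg")
  expect_equal(porter_stem("restricting"), "restrict")
  expect_equal(porter_stem("restrict"), "restrict")
  expect_equal(porter_stem("calories"), "calori")
  expect_equal(porter_stem("anxiety"), porter_stem("anxieti"))
  # short words untouched
  expect_equal(porter_stem("is"), "is")
})

test_that("lexicon engine: wildcards, phrases, proportions", {
  lex <- lexicon("guns", c("gun*", "rifle", "firearm"))
  expect_equal(count_matches(c("watching", "gun", "deals"), lex), 1L)
  expect_equal(count_matches(c("guns", "gunshot", "rifle"), lex), 3L)
  lex2 <- lexicon("iso", c("restrict*"))
  expect_equal(count_matches("restricting", lex2), 1L)
  ph <- lexicon("econ", c("pay_the_bills", "rent"))
  expect_equal(count_matches(c("pay", "the", "bills", "and", "rent"), ph), 2L)
  # consumed tokens are not double counted
  ph2 <- lexicon("x", c("a_b", "b"))
  expect_equal(count_matches(c("a", "b", "b"), ph2), 2L)
  m <- lexicon_features(list(c(rep("x", 8), "gun", "rifle")), list(lex))
  expect_equal(as.numeric(m), 0.2)
  expect_warning(lexicon_features(list("x"), list(lexicon("empty", character(0)))),
                 "empty")
})

test_that("bundled lexicons have the declared family sizes", {
  expect_length(bundled_lexicons("categories"), 62)
  expect_length(bundled_lexicons("custom"), 6)
  expect_gt(length(bundled_lexicons("event")$entries), 5)
  val <- bundled_lexicons("valence")
  expect_true(any(val > 0) && any(val < 0))
})

test_that("readability metrics equal their closed forms on a fixture", {
  sr <- surface_and_readability("The cat sat on the mat.")
  expect_equal(unname(sr[, "gunning_fog"]), 0.4 * (6 / 1 + 100 * 0 / 6))
  expect_equal(unname(sr[, "flesch_kincaid_grade"]),
               0.39 * 6 + 11.8 * 1 - 15.59)
  expect_equal(unname(sr[, "flesch_reading_ease"]),
               206.835 - 1.015 * 6 - 84.6 * 1)
  expect_equal(unname(sr[, "lix"]), 6 / 1 + 0)
  one <- surface_and_readability("mat")
  expect_equal(unname(one[, "n_tokens"]), 1)
  expect_equal(unname(one[, "n_syllables"]), 1)
  expect_equal(unname(one[, "n_complex_words"]), 0)
})

test_that("sentiment proportions sum to one and compound is saturating", {
  s <- sentiment_features("w0001 w0002 w0003")
  expect_equal(unname(s[1, 1:3]), c(0, 1, 0))
  expect_equal(unname(s[1, 4]), 0)
  s2 <- sentiment_features("wonderful")
  expect_gt(s2[1, "sent_compound"], 0)
  expect_gt(s2[1, "sent_positive"], 0)
  txt <- "this is terrible and hopeless but fine"
  a <- sentiment_features(txt)[1, "sent_compound"]
  b <- sentiment_features(paste(txt, txt))[1, "sent_compound"]
  expect_equal(sign(a), sign(b))
  s3 <- sentiment_features(c("good good bad", "awful awful awful"))
  expect_equal(unname(rowSums(s3[, 1:3])), c(1, 1), tolerance = 1e-9)
})

test_that("TF-IDF fit: top-df vocabulary, stems, deterministic", {
  texts <- c("alpha beta gamma", "alpha beta delta", "alpha epsilon zeta",
             "alpha beta gamma delta")
  sp <- feature_spec(tfidf_v = 3, ngram_range = c(1, 1), stem = FALSE,
                     tfidf_v_free = TRUE)
  ft <- fit_tfidf(texts, sp, v = 3)
  expect_identical(ft$vocab, c("alpha", "beta", "delta"))  # df 4, 3, 2(lex tie)
  expect_true(all(ft$idf > 0))
  expect_equal(unname(ft$idf["alpha"]), log(5 / 5) + 1)
  ft2 <- fit_tfidf(texts, sp, v = 3)
  expect_identical(ft, ft2)
  sp_stem <- feature_spec(tfidf_v = 2, ngram_range = c(1, 1), stem = TRUE,
                          tfidf_v_free = TRUE)
  fts <- fit_tfidf(c("purging daily", "purged daily"), sp_stem, v = 2)
  expect_true("purg" %in% fts$vocab)
  expect_warning(fit_tfidf(c("a b", "a b"), sp, v = 3), "shrunk")
})

test_that("default spec yields 90 features; with V=256 the vector is 346-D", {
  f <- extract_features("I can't sleep and I feel hopeless. Rent is due.",
                        feature_spec(tfidf_v = 0))
  expect_equal(ncol(f$values), 90)
  fam <- table(f$families)
  expect_equal(as.integer(fam[c("category", "sentiment", "surface", "punct",
                                "readability", "custom")]),
               c(62L, 4L, 8L, 1L, 9L, 6L))
  texts <- paste("sample post number", 1:40, "about feeling",
                 rep(c("lonely", "anxious", "fine", "tired"), 10))
  sp <- feature_spec(tfidf_v = 256)
  ft <- suppressWarnings(fit_tfidf(texts, sp))
  f2 <- extract_features(texts, sp, ft)
  expect_equal(ncol(f2$values), 90 + length(ft$vocab))
  expect_true(all(is.finite(f2$values)))
})

test_that("extraction is pure: repeated calls identical; invariants hold", {
  fx <- fx_marker()
  sub <- fx$corpus$posts$text[1:25]
  a <- extract_features(sub, fx$spec, fx$tfidf)
  b <- extract_features(sub, fx$spec, fx$tfidf)
  expect_identical(a, b)
  lexcols <- fx$features$families %in% c("category", "custom")
  expect_true(all(fx$features$values[, lexcols] >= 0 &
                    fx$features$values[, lexcols] <= 1))
  sent <- fx$features$values[, paste0("sentiment:sent_",
                                      c("negative", "neutral", "positive"))]
  expect_equal(unname(rowSums(sent)), rep(1, nrow(sent)), tolerance = 1e-9)
  tfcols <- fx$features$families == "tfidf"
  expect_true(all(fx$features$values[, tfcols] >= 0))
})

test_that("feature matrix round-trips through CSV", {
  f <- extract_features(c("hello there world.", "another post entirely."),
                        feature_spec(tfidf_v = 0))
  path <- tempfile(fileext = ".csv")
  write_features(f, path)
  g <- read_features(path)
  expect_equal(g$values, f$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(g$feature_names, f$feature_names)
})
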
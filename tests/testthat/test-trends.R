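# Binning, OLS trend fitting, change score, semantic-change ranking,
# year-over-year comparison, event tracking.

test_that("binning groups posts into consecutive bins with exact means", {
  fx <- toy_corpus()  # 20 posts on days 1..20, groups alternating by day
  vals <- matrix(ifelse(fx$posts$group == "alpha", 0.5, 1), ncol = 1,
                 dimnames = list(NULL, "custom:x"))
  f <- structure(list(values = vals, post_ids = fx$posts$id,
                      feature_names = "custom:x", families = "custom"),
                 class = "mind_features")
  b <- bin_series(f, fx, bin_days = 2)
  # each 2-day bin holds one alpha and one beta post
  expect_true(all(b$n == 1))
  expect_equal(nrow(b), 2 * 10)  # 2 groups x 10 bins
  expect_equal(unique(b$mean[b$group == "alpha"]), 0.5)
  expect_equal(unique(b$mean[b$group == "beta"]), 1)
  b4 <- bin_series(f, fx, bin_days = 4)
  expect_true(all(b4$n == 2))
  expect_equal(sort(unique(b4$bin)), 0:4)
})

test_that("trend OLS matches the hand-computed example and conventions", {
  mk <- function(means) data.frame(group = "g", feature = "f",
                                   bin = seq_along(means) - 1,
                                   bin_start = as.Date("2020-01-01"),
                                   mean = means, n = 5)
  tr <- fit_trends(mk(c(1, 2, 3, 4)))
  expect_equal(tr$slope, 1)
  expect_equal(tr$r2, 1)
  expect_equal(tr$change, 1)
  flat <- fit_trends(mk(c(5, 5, 5)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$change, 0)
  expect_equal(flat$p, 1)
  expect_true(flat$degenerate)
  hand <- fit_trends(mk(c(0, 2, 1, 3, 2, 4)))
  expect_equal(hand$slope, 11 / 17.5)
  expect_equal(hand$r2, 11^2 / (17.5 * 10))
  expect_equal(hand$change, (11 / 17.5) * 11^2 / (17.5 * 10))
  # |change| <= |slope| always; base-R lm cross-check
  expect_lte(abs(hand$change), abs(hand$slope))
  fit <- lm(c(0, 2, 1, 3, 2, 4) ~ I(0:5))
  expect_equal(hand$slope, unname(coef(fit)[2]))
  expect_equal(hand$p, summary(fit)$coefficients[2, 4])
})

test_that("planted drift slope is recovered with correct sign, <=30% error", {
  fx <- fx_drift()
  b <- bin_series(fx$features, fx$analysis, bin_days = 2)
  tr <- fit_trends(b)
  r <- tr[tr$group == "grp01" & tr$feature == "custom:isolation", ]
  slope_day <- r$slope / 2  # bins are 2 days wide
  planted <- fx$gt$drifts$slope[1]
  expect_gt(slope_day, 0)
  expect_lt(abs(slope_day - planted) / planted, 0.3)
  expect_true(r$significant)
})

test_that("semantic-change ranking: formula, valence spec, tie-breaks", {
  spec <- default_valence_spec()
  expect_length(spec$negative, 13)
  expect_length(spec$positive, 3)
  tr <- data.frame(
    group = c("a", "a", "b"),
    feature = c("category:negative_emotion", "category:positive_emotion",
                "category:negative_emotion"),
    change = c(0.2, 0.1, 0), significant = c(TRUE, TRUE, TRUE))
  rk <- rank_semantic_change(tr, spec)
  expect_equal(rk$score[rk$group == "a"], 0.2 - 0.1)
  expect_equal(rk$score[rk$group == "b"], 0)
  expect_equal(rk$group[1], "a")
  # non-significant rows contribute nothing
  tr$significant <- FALSE
  rk0 <- rank_semantic_change(tr, spec)
  expect_true(all(rk0$score == 0))
  expect_equal(rk0$group, sort(rk0$group))  # ties broken by name
  expect_error(rank_semantic_change(tr, list(negative = character(0),
                                             positive = character(0))))
})

test_that("year-over-year |change| comparison behaves directionally", {
  tr_a <- data.frame(group = "g", feature = paste0("f", 1:12),
                     change = seq(0.01, 0.12, by = 0.01), significant = TRUE)
  same <- compare_year_change(tr_a, tr_a)
  expect_gt(same$p, 0.9)
  tr_b <- tr_a
  tr_b$change <- tr_b$change * 3
  shifted <- compare_year_change(tr_a, tr_b)
  expect_lt(shifted$p, 0.01)
  # planted-drift year vs its own baseline year
  fx <- fx_drift()
  base <- corpus_subset(fx$corpus, period = "baseline_year")
  fb <- extract_features(base, feature_spec(tfidf_v = 0))
  trb <- suppressWarnings(fit_trends(bin_series(fb, base, bin_days = 2)))
  tra <- suppressWarnings(fit_trends(bin_series(fx$features, fx$analysis,
                                                bin_days = 2)))
  yy <- compare_year_change(trb, tra)
  expect_lt(yy$p, 0.05)
})

test_that("event-token tracking: proportions, ramp correlation", {
  fx <- fx_drift()
  ev <- track_event_tokens(fx$corpus, bin_days = 2)
  expect_true(all(ev$series$proportion >= 0 & ev$series$proportion <= 1))
  # correlate realized series with the planted expected-rate curve
  gt_rate <- fx$gt$event_rate
  daily <- aggregate(rate ~ date, gt_rate, mean)
  evt <- track_event_tokens(fx$corpus, bin_days = 2, measure = "tokens")
  m <- merge(evt$mean_series,
             data.frame(bin = as.integer(floor(as.numeric(
               daily$date - evt$window[1]) / 2)), rate = daily$rate),
             by = "bin")
  r <- spearman_rho(m$proportion, m$rate)
  expect_gte(r$estimate, 0.9)
  # a lexicon matching nothing gives all-zero proportions
  none <- track_event_tokens(fx$corpus, lexicon("none", "qqqzzzz"), bin_days = 2)
  expect_true(all(none$series$proportion == 0))
})

test_that("external case series alignment produces a correlation", {
  fx <- fx_drift()
  days <- seq(as.Date("2020-01-01"), as.Date("2020-04-20"), by = "day")
  cases <- data.frame(date = days,
                      count = cumsum(exp(0.05 * seq_along(days))))
  ev <- track_event_tokens(fx$corpus, case_series = cases, bin_days = 2)
  expect_s3_class(ev$correlation, "mind_test")
  expect_gt(ev$correlation$estimate, 0.5)
})
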
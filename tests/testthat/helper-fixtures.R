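# Shared synthetic fixtures, built once per test run and memoized.
# All corpora are generated in code; no stored data.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

group_names <- function(n) sprintf("grp%02d", seq_len(n))

## marker-only corpus: 6 groups, the classification workhorse
fx_marker <- function() fixture("marker", function() {
  cfg <- synthetic_config(n_groups = 6, posts_per_group_per_period = 150,
                          seed = 7)
  sim <- generate_corpus(cfg)
  spec <- feature_spec(tfidf_v = 512)
  per <- as.character(post_periods(sim$corpus))
  tfidf <- fit_tfidf(sim$corpus$posts$text[per == "pre_event"], spec)
  feats <- extract_features(sim$corpus, spec, tfidf)
  list(config = cfg, corpus = sim$corpus, gt = sim$ground_truth,
       spec = spec, tfidf = tfidf, features = feats, periods = per)
})

## three latent themes; th1 0.10 -> 0.30, th2 0.20 -> 0.40 (ratio 2.0)
fx_theme <- function() fixture("theme", function() {
  ng <- 10
  themes <- list(
    list(name = "sleepissues", vocab = sprintf("thslp%02d", 1:12)),
    list(name = "medication", vocab = sprintf("thmed%02d", 1:12)),
    list(name = "workstress", vocab = sprintf("thwrk%02d", 1:12)))
  pre <- matrix(rep(c(0.10, 0.20, 0.70), each = ng), ng, 3)
  mid <- matrix(rep(c(0.30, 0.40, 0.30), each = ng), ng, 3)
  cfg <- synthetic_config(
    n_groups = ng, posts_per_group_per_period = 100,
    theme_specs = list(
      themes = themes,
      prevalence = list(baseline_year = pre, pre_event = pre, mid_event = mid)),
    seed = 11)
  sim <- generate_corpus(cfg)
  spec <- feature_spec(tfidf_v = 256)
  per <- as.character(post_periods(sim$corpus))
  tfidf <- fit_tfidf(sim$corpus$posts$text[per == "pre_event"], spec)
  feats <- extract_features(sim$corpus, spec, tfidf)
  list(config = cfg, corpus = sim$corpus, gt = sim$ground_truth,
       themes = themes, spec = spec, tfidf = tfidf, features = feats,
       periods = per)
})

## planted lexicon drift plus an event ramp
fx_drift <- function() fixture("drift", function() {
  cfg <- synthetic_config(
    n_groups = 6, posts_per_group_per_period = 150,
    drift_specs = data.frame(group = "grp01", lexicon = "isolation",
                             base_rate = 0.02, slope = 5e-4),
    event_spec = list(onset = as.Date("2020-03-01"), steepness = 0.1,
                      ceiling = 0.12),
    seed = 42)
  sim <- generate_corpus(cfg)
  ana <- corpus_subset(sim$corpus, period = c("pre_event", "mid_event"))
  feats <- extract_features(ana, feature_spec(tfidf_v = 0))
  list(config = cfg, corpus = sim$corpus, analysis = ana, gt = sim$ground_truth,
       features = feats)
})

## planted convergence: reference emits the event vocabulary throughout,
## every other group ramps toward it
fx_converge <- function() fixture("converge", function() {
  ng <- 6
  onsets <- c(stats::setNames(as.Date("2019-06-01"), "grp01"),
              stats::setNames(rep(as.Date("2020-03-01"), ng - 1),
                              group_names(ng)[-1]))
  cfg <- synthetic_config(
    n_groups = ng, posts_per_group_per_period = 250,
    event_spec = list(onset = onsets, steepness = 0.03, ceiling = 0.35),
    seed = 21)
  sim <- generate_corpus(cfg)
  spec <- feature_spec(tfidf_v = 512)
  per <- as.character(post_periods(sim$corpus))
  tfidf <- fit_tfidf(sim$corpus$posts$text[per == "pre_event"], spec)
  feats <- extract_features(sim$corpus, spec, tfidf)
  list(config = cfg, corpus = sim$corpus, spec = spec, tfidf = tfidf,
       features = feats, reference = "grp01")
})

## stationary corpus with no planted effects
fx_null <- function() fixture("null", function() {
  cfg <- synthetic_config(n_groups = 4, posts_per_group_per_period = 200,
                          seed = 5)
  sim <- generate_corpus(cfg)
  spec <- feature_spec(tfidf_v = 0)
  feats <- extract_features(sim$corpus, spec)
  list(config = cfg, corpus = sim$corpus, features = feats,
       periods = as.character(post_periods(sim$corpus)))
})

## corpus whose posts are drawn almost entirely from two disjoint
## vocabularies — the cleanest topic-recovery scenario
fx_two_topics <- function() fixture("two_topics", function() {
  themes <- list(list(name = "ta", vocab = sprintf("tka%02d", 1:15)),
                 list(name = "tb", vocab = sprintf("tkb%02d", 1:15)))
  prev <- matrix(0.5, 4, 2)
  cfg <- synthetic_config(
    n_groups = 4, posts_per_group_per_period = 80, post_length_mean = 60,
    marker_rate = 0, theme_token_rate = 0.85,
    theme_specs = list(themes = themes,
                       prevalence = list(baseline_year = prev,
                                         pre_event = prev, mid_event = prev)),
    seed = 19)
  sim <- generate_corpus(cfg)
  spec <- feature_spec(tfidf_v = 256, ngram_range = c(1, 1), stem = FALSE)
  per <- as.character(post_periods(sim$corpus))
  tfidf <- fit_tfidf(sim$corpus$posts$text[per == "pre_event"], spec)
  list(config = cfg, corpus = sim$corpus, gt = sim$ground_truth,
       themes = themes, tfidf = tfidf, periods = per)
})

## tiny hand-built corpus for plumbing tests
toy_corpus <- function() {
  days <- seq(as.Date("2020-01-01"), as.Date("2020-01-20"), by = "day")
  posts <- data.frame(
    id = sprintf("t%02d", 1:20),
    author = sprintf("auth%02d", rep(1:10, each = 2)),
    group = rep(c("alpha", "beta"), 10),
    created_utc = days,
    text = paste("some plain text number", 1:20, "with words."),
    stringsAsFactors = FALSE)
  corpus(posts, periods = list(window = range(days)))
}

## subset a mind_features by row index
features_subset <- function(feats, idx) {
  structure(list(values = feats$values[idx, , drop = FALSE],
                 post_ids = feats$post_ids[idx],
                 feature_names = feats$feature_names,
                 families = feats$families),
            class = "mind_features")
}
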
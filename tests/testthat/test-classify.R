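# Binary tasks, model kinds, weighted F1, feature importance, classifier bank.

test_that("task building: dedup, balance, determinism, no author leakage", {
  fx <- fx_marker()
  t1 <- suppressWarnings(build_binary_task(fx$corpus, "grp01", seed = 4))
  t2 <- suppressWarnings(build_binary_task(fx$corpus, "grp01", seed = 4))
  expect_identical(t1$train_ids, t2$train_ids)
  expect_identical(t1$test_ids, t2$test_ids)
  # one post per author across the whole task
  all_ids <- c(t1$train_ids, t1$test_ids)
  authors <- fx$corpus$posts$author[match(all_ids, fx$corpus$posts$id)]
  expect_false(anyDuplicated(authors) > 0)
  # train and test share no author (implied by dedup, assert directly)
  tr_a <- fx$corpus$posts$author[match(t1$train_ids, fx$corpus$posts$id)]
  te_a <- fx$corpus$posts$author[match(t1$test_ids, fx$corpus$posts$id)]
  expect_length(intersect(tr_a, te_a), 0)
  sh_a <- fx$corpus$posts$author[match(t1$shift_ids, fx$corpus$posts$id)]
  expect_length(intersect(tr_a, sh_a), 0)
  # balanced classes
  expect_equal(sum(t1$train_labels == 1), sum(t1$train_labels == 0))
})

test_that("author dedup caps eligible posts at the author count", {
  fx <- toy_corpus()
  expect_error(build_binary_task(fx, "alpha"), "control")
  days <- seq(as.Date("2020-01-01"), by = "day", length.out = 72)
  posts <- data.frame(
    id = sprintf("p%03d", 1:72),
    author = sprintf("auth%02d", rep(1:36, each = 2)),  # 2 posts per author
    group = rep(c("a", "b", "c"), each = 24),
    created_utc = days,
    text = paste("post body number", 1:72),
    stringsAsFactors = FALSE)
  cp <- corpus(posts, periods = list(window = range(days)))
  tk <- suppressWarnings(build_binary_task(cp, "a", n_per_class = 100,
                                           period = "window",
                                           shift_period = NULL, seed = 1))
  pos_ids <- c(tk$train_ids, tk$test_ids)
  pos_auth <- unique(posts$author[match(pos_ids, posts$id)])
  expect_lte(sum(grepl("^auth(0[1-9]|1[0-2])$", pos_auth)), 12)
  expect_lte(tk$n_per_class, 12)  # 12 authors in the target group
})

test_that("weighted F1 matches hand arithmetic and rejects degenerates", {
  expect_equal(weighted_f1(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  # balanced test, all predicted positive: 0.5 * 2/3 + 0.5 * 0
  expect_equal(weighted_f1(c(1, 1, 0, 0), c(1, 1, 1, 1)), 1 / 3)
  expect_error(weighted_f1(c(1, 1), c(1, 0)), "single-class")
})

test_that("linearly separable toy task trains to F1 = 1; L1 sparsity grows", {
  set.seed(1)
  n <- 60
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c(0L, 1L), each = n / 2)
  x[y == 1, 1] <- x[y == 1, 1] + 6
  ids <- as.character(seq_len(n))
  f <- structure(list(values = x, post_ids = ids,
                      feature_names = colnames(x),
                      families = rep("tfidf", 20)), class = "mind_features")
  task <- list(target = "toy", train_ids = ids, train_labels = y,
               test_ids = ids, test_labels = y, shift_ids = character(0),
               shift_labels = integer(0), n_per_class = n / 2, seed = 1)
  class(task) <- "mind_binary_task"
  m <- train_classifier(task, f, reg = 0.001)
  expect_equal(weighted_f1(y, predict(m, f)), 1)
  lo <- train_classifier(task, f, reg = 0.001)
  hi <- train_classifier(task, f, reg = 0.2)
  expect_lt(sum(hi$coefficients != 0), sum(lo$coefficients != 0))
  # degenerate single-class training errors
  bad <- task; bad$train_labels <- rep(1L, n)
  expect_error(train_classifier(bad, f), "single-class")
})

test_that("all five model kinds fit and expose importances appropriately", {
  set.seed(2)
  n <- 80
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c(0L, 1L), each = n / 2)
  x[y == 1, 3] <- x[y == 1, 3] + 4
  ids <- as.character(seq_len(n))
  f <- structure(list(values = x, post_ids = ids, feature_names = colnames(x),
                      families = rep("tfidf", 10)), class = "mind_features")
  task <- list(target = "toy", train_ids = ids, train_labels = y,
               test_ids = ids, test_labels = y, shift_ids = character(0),
               shift_labels = integer(0), n_per_class = n / 2, seed = 1)
  class(task) <- "mind_binary_task"
  for (kind in c("sgd_l1", "sgd_elastic_net", "linear_svm")) {
    m <- train_classifier(task, f, model_kind = kind, reg = 0.01)
    expect_gte(weighted_f1(y, predict(m, f)), 0.95)
    rk <- rank_model_features(m, top_n = 3)
    expect_equal(rk$mode, "signed")
    expect_equal(rk$positive$feature[1], "f3")
  }
  for (kind in c("extra_trees", "gradient_boosting")) {
    m <- train_classifier(task, f, model_kind = kind, seed = 3)
    expect_gte(weighted_f1(y, predict(m, f)), 0.9)
    rk <- rank_model_features(m, top_n = 3)
    expect_equal(rk$mode, "unsigned")
    expect_equal(rk$positive$feature[1], "f3")
  }
})

test_that("planted markers give high held-out F1 and top-5 importance", {
  fx <- fx_marker()
  task <- suppressWarnings(build_binary_task(fx$corpus, "grp03", seed = 2))
  m <- train_classifier(task, fx$features, seed = 2)
  ev <- evaluate_classifier(m, task, fx$features)
  expect_gte(ev$weighted_f1[ev$test_set == "held_out"], 0.9)
  # marker rate unchanged mid-period: shift F1 within 0.05 of held-out
  expect_lt(abs(ev$weighted_f1[ev$test_set == "shift"] -
                  ev$weighted_f1[ev$test_set == "held_out"]), 0.05)
  rk <- rank_model_features(m)
  top5 <- sub("^tfidf:", "", head(rk$positive$feature, 5))
  expect_true(any(top5 %in% fx$gt$marker_tokens[["grp03"]]))
})

test_that("classifier bank returns per-model detection proportions", {
  fx <- fx_marker()
  models <- lapply(c("grp01", "grp02"), function(g) {
    task <- suppressWarnings(build_binary_task(fx$corpus, g, seed = 5))
    train_classifier(task, fx$features, seed = 5)
  })
  names(models) <- c("grp01", "grp02")
  ids <- fx$corpus$posts$id[fx$corpus$posts$group == "grp01"][1:50]
  props <- apply_classifiers_to_group(models, fx$features, ids)
  expect_gte(props[["grp01"]], 0.8)
  expect_lt(props[["grp02"]], 0.5)
  one <- apply_classifiers_to_group(models, fx$features,
                                    fx$corpus$posts$id[1])
  expect_true(all(one %in% c(0, 1)))
  expect_error(apply_classifiers_to_group(models, fx$features, character(0)))
})
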
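# Spectral clustering, characteristic features, enrichment, matching,
# agreement metrics, diversity.

test_that("well-separated planted blobs are recovered exactly", {
  set.seed(1)
  n <- 90
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  truth <- rep(1:3, each = n / 3)
  x[truth == 2, 1:3] <- x[truth == 2, 1:3] + 10
  x[truth == 3, 4:6] <- x[truth == 3, 4:6] + 10
  f <- structure(list(values = x, post_ids = as.character(1:n),
                      feature_names = colnames(x),
                      families = rep("tfidf", 8)), class = "mind_features")
  cm <- suppressWarnings(fit_cluster_model(f, groups = rep("g", n),
                                           n_per_group = n, n_components = 5,
                                           k = 3, nn = 10, seed = 2))
  ag <- label_agreement(cm$assignments, truth)
  expect_equal(unname(ag["adjusted_rand"]), 1)
  # determinism and invariance to post order
  cm2 <- suppressWarnings(fit_cluster_model(f, groups = rep("g", n),
                                            n_per_group = n, n_components = 5,
                                            k = 3, nn = 10, seed = 2))
  expect_identical(cm$assignments, cm2$assignments)
  expect_error(fit_cluster_model(f, rep("g", n), n_per_group = n, k = n + 1),
               "k exceeds")
})

test_that("planted themes are recovered with adjusted Rand >= 0.8", {
  fx <- fx_theme()
  pre_i <- which(fx$periods == "pre_event")
  fpre <- features_subset(fx$features, pre_i)
  cm <- suppressWarnings(fit_cluster_model(
    fpre, fx$corpus$posts$group[pre_i], n_per_group = 100,
    n_components = 30, k = 3, nn = 10, seed = 5, period = "pre"))
  truth <- fx$gt$theme_assignment$theme[
    match(cm$sample_ids, fx$gt$theme_assignment$post_id)]
  ag <- label_agreement(cm$assignments, truth)
  expect_gte(ag["adjusted_rand"], 0.8)
  # theme-vocabulary TF-IDF features are the top characteristic features
  cm <- characteristic_features(cm, fpre)
  theme_tokens <- unlist(lapply(fx$themes, `[[`, "vocab"))
  for (ci in 1:3) {
    expect_gt(nrow(cm$characteristic[[ci]]), 0)
    expect_true(sub("^tfidf:", "", cm$characteristic[[ci]]$feature[1]) %in%
                  theme_tokens)
  }
  .fixture_env$theme_cluster_pre <- cm  # reused by the matching test
})

test_that("characteristic p-values agree with the rank-sum oracle on a toy", {
  set.seed(3)
  x <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[1:10, 1] <- x[1:10, 1] + 2
  f <- structure(list(values = x, post_ids = as.character(1:20),
                      feature_names = colnames(x),
                      families = rep("tfidf", 3)), class = "mind_features")
  cm <- suppressWarnings(fit_cluster_model(f, rep("g", 20), n_per_group = 20,
                                           n_components = 2, k = 2, nn = 5,
                                           seed = 1))
  cm <- characteristic_features(cm, f, alpha = 1)
  inc <- cm$assignments == 1
  for (j in 1:3) {
    ref <- mann_whitney_u(x[inc, j], x[!inc, j], exact_max = 0)  # approx path
    got <- cm$characteristic[[1]]
    row <- got[got$feature == colnames(x)[j], ]
    if (nrow(row) == 1) expect_equal(row$p, ref$p, tolerance = 1e-10)
  }
  # constant feature is never characteristic
  x2 <- cbind(x, const = 1)
  f2 <- structure(list(values = x2, post_ids = as.character(1:20),
                       feature_names = colnames(x2),
                       families = rep("tfidf", 4)), class = "mind_features")
  cm2 <- suppressWarnings(fit_cluster_model(f2, rep("g", 20), n_per_group = 20,
                                            n_components = 2, k = 2, nn = 5,
                                            seed = 1))
  cm2 <- characteristic_features(cm2, f2, alpha = 1)
  expect_false(any(vapply(cm2$characteristic,
                          function(df) "const" %in% df$feature, logical(1))))
})

test_that("enrichment: exact toy p, null composition, planted concentration", {
  # uniform themes across groups: no Bonferroni-significant pair
  fx <- fx_theme()
  pre <- .fixture_env$theme_cluster_pre
  enr0 <- cluster_enrichment(pre)
  expect_equal(sum(enr0$significant), 0)
  expect_true(all(enr0$p >= 0 & enr0$p <= 1))
  # overlap counts per cluster sum to cluster size
  agg <- aggregate(overlap ~ cluster, enr0, sum)
  expect_equal(agg$overlap, tabulate(pre$assignments, pre$k))
  # planted concentration: one group dominated by one theme
  ng <- 4
  prev <- matrix(c(0.9, 0.1, rep(c(0.3, 0.7), ng - 1)), ng, 2, byrow = TRUE)
  cfg <- synthetic_config(
    n_groups = ng, posts_per_group_per_period = 80,
    theme_specs = list(
      themes = list(list(name = "ta", vocab = sprintf("tka%02d", 1:10)),
                    list(name = "tb", vocab = sprintf("tkb%02d", 1:10))),
      prevalence = list(baseline_year = prev, pre_event = prev,
                        mid_event = prev)),
    seed = 17)
  sim <- generate_corpus(cfg)
  per <- as.character(post_periods(sim$corpus))
  spc <- feature_spec(tfidf_v = 256)
  tf <- fit_tfidf(sim$corpus$posts$text[per == "pre_event"], spc)
  fe <- extract_features(sim$corpus, spc, tf)
  pre_i <- which(per == "pre_event")
  cm <- suppressWarnings(fit_cluster_model(
    features_subset(fe, pre_i), sim$corpus$posts$group[pre_i],
    n_per_group = 80, n_components = 20, k = 2, nn = 10, seed = 3))
  enr <- cluster_enrichment(cm)
  hit <- enr[enr$group == "grp01" & enr$significant, ]
  expect_gte(nrow(hit), 1)
})

test_that("cluster matching recovers identity and planted size shifts", {
  fx <- fx_theme()
  pre <- .fixture_env$theme_cluster_pre
  # identical models match identically with Jaccard 1 and ratio 1
  self <- match_clusters(pre, pre, top_m = 25, tau = 0.2)
  expect_equal(nrow(self$pairs), pre$k)
  expect_true(all(self$pairs$jaccard == 1))
  expect_true(all(self$pairs$size_ratio == 1))
  # mid-period model: th1 0.10 -> 0.30 (x3), th2 0.20 -> 0.40 (x2)
  mid_i <- which(fx$periods == "mid_event")
  fmid <- features_subset(fx$features, mid_i)
  mid <- suppressWarnings(fit_cluster_model(
    fmid, fx$corpus$posts$group[mid_i], n_per_group = 100,
    n_components = 30, k = 3, nn = 10, seed = 6, period = "mid"))
  mid <- characteristic_features(mid, fmid)
  mt <- match_clusters(pre, mid, top_m = 25, tau = 0.2)
  expect_equal(nrow(mt$pairs), 3)
  # identify the matched pair for each theme by its top token family
  theme_of <- function(model, ci) {
    tok <- sub("^tfidf:", "", model$characteristic[[ci]]$feature[1])
    substr(tok, 1, 5)
  }
  pre_theme <- vapply(seq_len(pre$k), function(ci) theme_of(pre, ci), "")
  ratios <- setNames(mt$pairs$size_ratio, pre_theme[mt$pairs$pre_cluster])
  expect_gt(ratios[["thslp"]], 2.2)              # planted x3
  expect_true(ratios[["thmed"]] >= 1.6 && ratios[["thmed"]] <= 2.4)  # x2
  expect_lt(ratios[["thwrk"]], 0.7)              # shrinking theme
  .fixture_env$theme_cluster_mid <- mid
})

test_that("label agreement metrics: perfect, random, and hand-computed toy", {
  g <- rep(c("a", "b", "c"), each = 20)
  ag <- label_agreement(g, g)
  expect_equal(unname(ag), rep(1, 4))
  set.seed(8)
  rnd <- label_agreement(sample(1:3, 600, replace = TRUE),
                         sample(letters[1:3], 600, replace = TRUE))
  expect_lt(abs(rnd["adjusted_rand"]), 0.05)
  # 6-point toy: clusters {a,a,b}, {b,c,c}
  cl <- c(1, 1, 1, 2, 2, 2)
  gr <- c("a", "a", "b", "b", "c", "c")
  ag <- label_agreement(cl, gr)
  hc <- log(3)                                   # H(classes), uniform thirds
  hck <- -2 * ((2 / 6) * log((2 / 6) / (1 / 2)) +  # H(C|K) from the 2/6,1/6 cells
                 (1 / 6) * log((1 / 6) / (1 / 2)))
  expect_equal(unname(ag["homogeneity"]), 1 - hck / hc)
  hkc <- -2 * (1 / 6) * log((1 / 6) / (1 / 3))   # only class b is split
  expect_equal(unname(ag["completeness"]), 1 - hkc / log(2))
  # single cluster: homogeneity 0 when classes vary
  one <- label_agreement(rep(1, 6), gr)
  expect_equal(unname(one["homogeneity"]), 0)
})

test_that("Shannon diversity: single group 0, uniform ln(k), concavity", {
  fx <- fx_theme()
  pre <- .fixture_env$theme_cluster_pre
  H <- cluster_diversity(pre)
  expect_true(all(H >= 0))
  expect_true(all(H <= log(length(unique(pre$sample_groups))) + 1e-9))
  toy <- pre
  toy$k <- 2
  toy$assignments <- setNames(rep(1:2, length.out = length(pre$assignments)),
                              names(pre$assignments))
  toy$sample_groups <- rep("only", length(pre$sample_groups))
  expect_equal(cluster_diversity(toy), c(0, 0))
  toy$sample_groups <- rep(sprintf("g%02d", 1:15),
                           length.out = length(pre$sample_groups))
  H15 <- cluster_diversity(toy)
  expect_equal(H15[1], log(15), tolerance = 0.01)
})
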
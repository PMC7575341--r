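# Directed Hausdorff, supervised 2D embedding, trajectories, bands,
# event correlation.

test_that("directed Hausdorff: examples, asymmetry, brute-force sweep", {
  expect_equal(directed_hausdorff(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  a <- rbind(c(0, 0), c(1, 0)); b <- rbind(c(0, 0))
  expect_equal(directed_hausdorff(a, b), 1)
  expect_equal(directed_hausdorff(b, a), 0)
  expect_equal(directed_hausdorff(a, a), 0)
  brute <- function(p, q) {
    max(apply(p, 1, function(pp) {
      min(apply(q, 1, function(qq) sqrt(sum((pp - qq)^2))))
    }))
  }
  set.seed(1)
  for (i in 1:60) {
    p <- matrix(rnorm(2 * sample(1:50, 1)), ncol = 2)
    q <- matrix(rnorm(2 * sample(1:50, 1)), ncol = 2)
    expect_equal(directed_hausdorff(p, q), brute(p, q), tolerance = 1e-9)
  }
  # monotone under adding points to the source set
  set.seed(2)
  a <- matrix(rnorm(20), ncol = 2); b <- matrix(rnorm(20), ncol = 2)
  extra <- matrix(rnorm(8, sd = 3), ncol = 2)
  expect_gte(directed_hausdorff(rbind(a, extra), b), directed_hausdorff(a, b))
  expect_error(directed_hausdorff(a[0, , drop = FALSE], b))
})

test_that("supervised embedding separates planted groups; silhouette grid", {
  set.seed(3)
  n <- 120
  x <- matrix(rnorm(n * 10), n, 10)
  lab <- rep(c("a", "b", "c"), each = n / 3)
  x[lab == "b", 1:5] <- x[lab == "b", 1:5] + 6
  x[lab == "c", 6:10] <- x[lab == "c", 6:10] + 6
  emb <- embed_2d(x, lab, n_neighbors = 15)
  expect_equal(dim(emb), c(n, 2))
  sil <- cluster::silhouette(as.integer(factor(lab)), dist(emb))
  expect_gte(mean(sil[, "sil_width"]), 0.5)
  # deterministic
  expect_identical(emb, embed_2d(x, lab, n_neighbors = 15))
  # grid of one returns it; larger grid returns the argmax
  one <- select_embedding_params(x, lab,
                                 grid = data.frame(n_neighbors = 15,
                                                   min_dist = 0,
                                                   metric = "euclidean"))
  expect_equal(one$best$n_neighbors, 15)
  grid <- data.frame(n_neighbors = c(10, 25), min_dist = c(0, 0.1),
                     metric = c("euclidean", "cosine"),
                     stringsAsFactors = FALSE)
  sel <- select_embedding_params(x, lab, grid)
  expect_equal(sel$best$silhouette, max(sel$scores$silhouette, na.rm = TRUE))
})

test_that("baseline band percentiles and flagging", {
  base <- structure(list(
    distances = data.frame(window_start = as.Date("2019-01-01") + 0:19,
                           group = "g", reference = "r",
                           median_distance = 1:20,
                           boot_low = 1, boot_high = 20),
    reference_groups = "r", window_days = 15, n_boot = 5,
    window = as.Date(c("2019-01-01", "2019-10-01"))),
    class = "mind_convergence")
  band <- baseline_band(base)
  expect_equal(band$low, 1.95)   # linear-interpolation 5th percentile
  expect_equal(band$high, 19.05)
  inside <- mean(base$distances$median_distance >= band$low &
                   base$distances$median_distance <= band$high)
  expect_equal(inside, 0.9)
  flagged <- flag_outside_band(base, band)
  expect_equal(sum(flagged$outside_band), 2)
  # degenerate constant baseline: zero-width band flags any other value
  const <- base
  const$distances$median_distance <- rep(2, 20)
  cb <- baseline_band(const)
  expect_equal(cb$low, cb$high)
  probe <- base
  probe$distances$median_distance <- c(rep(2, 19), 3)
  expect_equal(sum(flag_outside_band(probe, cb)$outside_band), 1)
  # short baselines widen to min/max with a warning
  short <- base
  short$distances <- short$distances[1:3, ]
  expect_warning(bs <- baseline_band(short), "widening")
  expect_equal(c(bs$low, bs$high), c(1, 3))
})

test_that("planted convergence: distances to reference fall with the ramp", {
  fx <- fx_converge()
  traj <- suppressWarnings(distance_trajectory(
    fx$features, fx$corpus, fx$reference, window_days = 15, n_per_group = 50,
    n_boot = 12, n_neighbors = 120, sup_weight = 3, seed = 3))
  d <- traj$distances
  expect_true(all(d$median_distance >= 0))
  expect_true(all(d$median_distance >= d$boot_low &
                    d$median_distance <= d$boot_high))
  # reference to itself is zero
  expect_true(all(d$median_distance[d$group == fx$reference] == 0))
  evw <- event_by_window(fx$corpus, traj)
  corr <- correlate_with_event(traj, evw)
  expect_lte(corr$rho[corr$reference == fx$reference], -0.8)
  expect_true(corr$significant[corr$reference == fx$reference])
  .fixture_env$converge_traj <- traj
})

test_that("stationary corpus shows no significant event correlation", {
  fx <- fx_null()
  ana <- corpus_subset(fx$corpus, period = c("pre_event", "mid_event"))
  keep <- match(ana$posts$id, fx$features$post_ids)
  fa <- features_subset(fx$features, keep)
  # n_per_group matches what every baseline window can also supply, so the
  # analysis and baseline Hausdorff statistics share one sampling law
  traj <- suppressWarnings(distance_trajectory(
    fa, ana, "grp01", window_days = 10, n_per_group = 12, n_boot = 14,
    n_neighbors = 15, seed = 9))
  evw <- event_by_window(fx$corpus, traj)
  corr <- correlate_with_event(traj, evw)
  expect_false(any(corr$significant, na.rm = TRUE))
  # null trajectories mostly stay inside the baseline band; with an
  # 11-window baseline the empirical 5th-95th band carries estimation
  # error on top of its nominal 10% exceedance, hence the 30% ceiling
  base <- corpus_subset(fx$corpus, period = "baseline_year")
  fb <- features_subset(fx$features, match(base$posts$id, fx$features$post_ids))
  base_traj <- suppressWarnings(distance_trajectory(
    fb, base, "grp01", window_days = 10, n_per_group = 12, n_boot = 14,
    n_neighbors = 15, window = range(base$posts$created_utc), seed = 10))
  band <- suppressWarnings(baseline_band(base_traj))
  flagged <- flag_outside_band(traj, band)
  off <- flagged[flagged$group != flagged$reference, ]
  expect_lte(mean(off$outside_band), 0.3)
})

test_that("full bootstrap trajectory is deterministic under seed", {
  fx <- fx_converge()
  t1 <- .fixture_env$converge_traj
  t2 <- suppressWarnings(distance_trajectory(
    fx$features, fx$corpus, fx$reference, window_days = 15, n_per_group = 50,
    n_boot = 12, n_neighbors = 120, sup_weight = 3, seed = 3))
  expect_identical(t1$distances, t2$distances)
})
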
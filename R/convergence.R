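#' Linguistic convergence between groups over time
#'
#' For each 15-day window, balanced bootstrap subsamples of each group's
#' feature vectors are projected to 2D with a supervised neighbor-graph
#' embedding, and the directed Hausdorff distance from each group's point
#' cloud to a reference group's cloud is recorded (median over bootstraps).
#' Because each window's embedding has its own arbitrary scale, every
#' window's directed-distance matrix is normalized by its median
#' off-diagonal entry before cross-window comparison. A stationary
#' baseline-year run supplies the 5th-95th percentile null band, and the
#' per-reference distance trajectory is correlated (Spearman, BH over
#' references) with the event-token posting trajectory.
#'
#' @name convergence
NULL

#' Directed (asymmetric) Hausdorff distance
#'
#' h(A -> B) = max over a in A of the Euclidean distance to the closest
#' point of B.
#'
#' @param a,b numeric matrices (points x dims), same dimensionality.
#' @return non-negative scalar.
#' @export
directed_hausdorff <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) > 0, nrow(b) > 0, ncol(a) == ncol(b))
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
  sqrt(max(0, max(apply(d2, 1, min))))
}

#' Supervised neighbor-graph embedding to 2D
#'
#' Labeled nonlinear projection in the Isomap family: pairwise distances
#' (euclidean or cosine) are computed, between-class distances are inflated
#' by `sup_weight` (the supervision), a k-nearest-neighbor graph is built
#' with edge lengths floored at `min_dist`, geodesic (graph shortest-path)
#' distances are taken over the graph, and classical MDS projects them to
#' 2D. Deterministic; disconnected graphs are bridged through the nearest
#' cross-component pair.
#'
#' @param x feature matrix (rows = posts).
#' @param labels group label per row.
#' @param n_neighbors neighborhood size (clamped to n-1).
#' @param min_dist floor on graph edge lengths.
#' @param metric "euclidean" or "cosine".
#' @param sup_weight multiplicative inflation of between-class distances.
#' @return n x 2 coordinate matrix (unit RMS, deterministic sign).
#' @export
embed_2d <- function(x, labels, n_neighbors = 15, min_dist = 0.0,
                     metric = c("euclidean", "cosine"), sup_weight = 1) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 4, length(labels) == n)
  d <- if (metric == "cosine") {
    nx <- x / pmax(sqrt(rowSums(x^2)), 1e-12)
    dd <- 1 - nx %*% t(nx)
    dd[dd < 0] <- 0
    dd
  } else {
    as.matrix(stats::dist(x))
  }
  same <- outer(labels, labels, "==")
  d <- d * ifelse(same, 1, 1 + sup_weight)
  diag(d) <- 0
  k <- max(2L, min(n_neighbors, n - 1L))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    A[i, nb] <- pmax(d[i, nb], min_dist, 1e-12)
  }
  A <- pmax(A, t(A))  # union symmetrization
  # bridge disconnected components through their nearest cross pair
  adj <- (A > 0) * 1
  comp <- components_of(adj)
  while (max(comp) > 1L) {
    in1 <- which(comp == 1L); rest <- which(comp != 1L)
    dd <- d[in1, rest, drop = FALSE]
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    a <- in1[ij[1]]; b <- rest[ij[2]]
    A[a, b] <- A[b, a] <- max(d[a, b], min_dist, 1e-12)
    adj[a, b] <- adj[b, a] <- 1
    comp <- components_of(adj)
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  geo <- igraph::distances(g)
  emb <- stats::cmdscale(geo, k = 2)
  if (ncol(emb) < 2) emb <- cbind(emb, 0)
  rms <- sqrt(mean(emb^2))
  if (rms > 0) emb <- emb / rms
  # deterministic sign convention
  for (j in 1:2) if (emb[which.max(abs(emb[, j])), j] < 0) emb[, j] <- -emb[, j]
  emb
}

#' Select embedding hyperparameters by silhouette score
#'
#' Embeds under every grid point and scores the labeled 2D embedding with
#' the mean silhouette width; returns the argmax (ties by grid order). The
#' recorded large-corpus defaults are n_neighbors = 200, min_dist = 0,
#' cosine metric.
#'
#' @param x feature matrix.
#' @param labels group labels.
#' @param grid data.frame with columns n_neighbors, min_dist, metric.
#' @return list with `best` (one grid row + silhouette) and `scores`.
#' @export
select_embedding_params <- function(x, labels,
                                    grid = data.frame(
                                      n_neighbors = c(200, 100, 15),
                                      min_dist = c(0, 0, 0.1),
                                      metric = c("cosine", "cosine", "euclidean"),
                                      stringsAsFactors = FALSE)) {
  stopifnot(nrow(grid) >= 1, length(unique(labels)) >= 2)
  scores <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    emb <- tryCatch(
      embed_2d(x, labels, n_neighbors = grid$n_neighbors[i],
               min_dist = grid$min_dist[i], metric = grid$metric[i]),
      error = function(e) {
        warning("grid point ", i, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(emb)) next
    sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(emb))
    scores[i] <- mean(sil[, "sil_width"])
  }
  if (all(is.na(scores))) stop("every grid point failed")
  best <- which.max(scores)
  list(best = cbind(grid[best, , drop = FALSE], silhouette = scores[best]),
       scores = cbind(grid, silhouette = scores))
}

## directed, normalized distance matrix between group clouds in one embedding
pairwise_directed <- function(emb, labels) {
  glev <- sort(unique(labels))
  m <- matrix(0, length(glev), length(glev), dimnames = list(glev, glev))
  for (i in seq_along(glev)) for (j in seq_along(glev)) {
    if (i == j) next
    m[i, j] <- directed_hausdorff(emb[labels == glev[i], , drop = FALSE],
                                  emb[labels == glev[j], , drop = FALSE])
  }
  off <- m[row(m) != col(m)]
  md <- stats::median(off)
  if (md > 0) m <- m / md
  m
}

#' Bootstrap distance trajectory between groups and reference groups
#'
#' Splits the corpus span into consecutive `window_days` windows; per window
#' and bootstrap draws a balanced subsample (without replacement), fits the
#' supervised 2D embedding on the window's subsample with true labels, and
#' records the normalized directed Hausdorff distance from every group to
#' every reference group. The per-(pair, window) statistic is the median
#' over bootstraps.
#'
#' @param features a `mind_features`.
#' @param corp the matching `mind_corpus`.
#' @param reference_groups groups used as distance references.
#' @param window_days window width (default 15).
#' @param n_per_group balanced subsample size per group per window.
#' @param n_boot bootstrap repetitions (default 50).
#' @param n_components principal components retained per bootstrap sample
#'   before embedding (default 30, as in the clustering stage); features are
#'   standardized first so no family's scale dominates, and the projection
#'   sheds the isotropic noise that high-dimensional point distances
#'   otherwise concentrate on.
#' @param n_neighbors,min_dist,metric,sup_weight embedding configuration.
#' @param window optional c(start, end) Dates (default: non-baseline span).
#' @param min_posts windows where any group has fewer posts are dropped
#'   for that pair with a warning.
#' @param seed RNG seed; the full pipeline is deterministic under it.
#' @return a `mind_convergence`: data.frame `distances` (window_start,
#'   group, reference, median_distance, boot_low, boot_high) plus window
#'   metadata.
#' @export
distance_trajectory <- function(features, corp, reference_groups,
                                window_days = 15, n_per_group = 1300,
                                n_boot = 50, n_components = 30,
                                n_neighbors = 15, min_dist = 0,
                                metric = "euclidean", sup_weight = 4,
                                window = NULL, min_posts = 5, seed = 1L) {
  stopifnot(inherits(corp, "mind_corpus"),
            all(reference_groups %in% corp$groups))
  idx <- match(features$post_ids, corp$posts$id)
  dates <- corp$posts$created_utc[idx]
  groups <- corp$posts$group[idx]
  if (is.null(window)) {
    per <- post_periods(corp)[idx]
    keep <- !is.na(per) & per != "baseline_year"
    if (!any(keep)) keep <- !is.na(per)
    window <- range(dates[keep])
  }
  # standardize once across the trajectory's posts: mixed feature families
  # have wildly different scales (character counts vs proportions), and the
  # embedding metric must not be dominated by the largest-scale family
  vals <- features$values
  sds <- apply(vals, 2, stats::sd)
  ok_col <- is.finite(sds) & sds > 0
  vals <- scale(vals[, ok_col, drop = FALSE])
  # only full-width windows: a truncated trailing window has a smaller post
  # pool and hence a different Hausdorff sampling law
  starts <- seq(window[1], window[2], by = window_days)
  starts <- starts[starts + window_days - 1 <= window[2]]
  rows <- list()
  set.seed(seed)
  glev <- sort(unique(groups))
  n_windows_used <- 0L
  for (ws in starts) {
    ws <- as.Date(ws, origin = "1970-01-01")
    we <- min(ws + window_days - 1, window[2])
    sel <- which(dates >= ws & dates <= we)
    counts <- table(factor(groups[sel], levels = glev))
    if (any(counts < min_posts)) {
      warning("window ", format(ws), ": group(s) below ", min_posts,
              " posts; window dropped")
      next
    }
    n_windows_used <- n_windows_used + 1L
    take <- min(n_per_group, min(counts))
    boots <- array(NA_real_, dim = c(length(glev), length(reference_groups),
                                     n_boot),
                   dimnames = list(glev, reference_groups, NULL))
    for (b in seq_len(n_boot)) {
      sub <- unlist(lapply(glev, function(g) {
        gi <- sel[groups[sel] == g]
        gi[sample.int(length(gi), take)]
      }))
      x <- vals[sub, , drop = FALSE]
      nc <- min(n_components, ncol(x), nrow(x) - 1L)
      x <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = nc)$x
      emb <- embed_2d(x, groups[sub],
                      n_neighbors = n_neighbors, min_dist = min_dist,
                      metric = metric, sup_weight = sup_weight)
      m <- pairwise_directed(emb, groups[sub])
      for (rg in reference_groups) boots[, rg, b] <- m[, rg]
    }
    for (g in glev) for (rg in reference_groups) {
      v <- boots[g, rg, ]
      rows[[length(rows) + 1L]] <- data.frame(
        window_start = ws, group = g, reference = rg,
        median_distance = stats::median(v),
        boot_low = min(v), boot_high = max(v), stringsAsFactors = FALSE)
    }
  }
  if (n_windows_used < 3) stop("fewer than 3 usable windows")
  out <- do.call(rbind, rows)
  structure(list(distances = out, window_days = window_days,
                 reference_groups = reference_groups, n_boot = n_boot,
                 window = window, seed = seed),
            class = "mind_convergence")
}

#' @export
print.mind_convergence <- function(x, ...) {
  cat("<convergence series: ", length(unique(x$distances$window_start)),
      " windows x ", length(unique(x$distances$group)), " groups -> ",
      length(x$reference_groups), " reference(s), ", x$n_boot,
      " bootstraps>\n", sep = "")
  invisible(x)
}

#' Baseline percentile band per (group, reference) pair
#'
#' Empirical 5th / 95th percentiles of the baseline-year distances,
#' linear-interpolation percentiles; fewer than 5 baseline windows widens
#' the band to min/max with a warning.
#'
#' @param baseline a `mind_convergence` from the stationary baseline year.
#' @param probs percentile pair.
#' @return data.frame (group, reference, low, high).
#' @export
baseline_band <- function(baseline, probs = c(0.05, 0.95)) {
  d <- baseline$distances
  sp <- split(d, list(d$group, d$reference), drop = TRUE)
  rows <- lapply(sp, function(s) {
    if (nrow(s) < 5) {
      warning("fewer than 5 baseline windows for ", s$group[1], "->",
              s$reference[1], "; widening band to min/max")
      lo <- min(s$median_distance); hi <- max(s$median_distance)
    } else {
      qq <- stats::quantile(s$median_distance, probs, type = 7)
      lo <- qq[1]; hi <- qq[2]
    }
    data.frame(group = s$group[1], reference = s$reference[1],
               low = as.numeric(lo), high = as.numeric(hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag analysis distances outside the baseline band
#'
#' @param series analysis-year `mind_convergence`.
#' @param band output of [baseline_band()].
#' @return the series' distances with an `outside_band` flag.
#' @export
flag_outside_band <- function(series, band) {
  d <- merge(series$distances, band, by = c("group", "reference"))
  d$outside_band <- d$median_distance < d$low | d$median_distance > d$high
  d[order(d$reference, d$group, d$window_start), ]
}

#' Correlate distance trajectories with event posting
#'
#' Per reference group, the across-group median distance per window is
#' correlated (Spearman) with the event-token posting proportion per
#' window; BH over reference groups. Constant trajectories are flagged
#' degenerate and excluded from the BH family.
#'
#' @param series a `mind_convergence`.
#' @param event_series data.frame (window_start, proportion): per-window
#'   mean event posting; see [event_by_window()].
#' @param alpha BH level.
#' @return data.frame (reference, rho, p, q, significant, degenerate).
#' @export
correlate_with_event <- function(series, event_series, alpha = 0.05) {
  d <- series$distances
  rows <- lapply(series$reference_groups, function(rg) {
    dd <- d[d$reference == rg & d$group != rg, ]
    med <- stats::aggregate(median_distance ~ window_start, dd, stats::median)
    m <- merge(med, event_series, by = "window_start")
    if (nrow(m) < 3 || stats::sd(m$median_distance) == 0 ||
        stats::sd(m$proportion) == 0) {
      return(data.frame(reference = rg, rho = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    ts <- spearman_rho(m$median_distance, m$proportion)
    data.frame(reference = rg, rho = ts$estimate, p = ts$p,
               degenerate = ts$degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  res$significant <- FALSE
  fam <- !res$degenerate
  if (any(fam)) {
    adj <- bh_adjust(res$p[fam], alpha)
    res$q[fam] <- adj$q
    res$significant[fam] <- adj$reject
  }
  res
}

#' Mean event-token posting per trajectory window
#'
#' @param corp a `mind_corpus`.
#' @param series a `mind_convergence` (defines the windows).
#' @param event_lexicon event lexicon.
#' @return data.frame (window_start, proportion).
#' @export
event_by_window <- function(corp, series,
                            event_lexicon = bundled_lexicons("event"),
                            measure = "tokens") {
  ev <- track_event_tokens(corp, event_lexicon, bin_days = series$window_days,
                           window = series$window, measure = measure)
  ms <- ev$mean_series
  data.frame(window_start = series$window[1] + ms$bin * series$window_days,
             proportion = ms$proportion)
}

#' Write convergence outputs
#'
#' @param flagged output of [flag_outside_band()] (or a series' distances).
#' @param corr output of [correlate_with_event()].
#' @param dir output directory.
#' @export
write_convergence_outputs <- function(flagged, corr = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(flagged, file.path(dir, "convergence.csv"),
                   row.names = FALSE)
  if (!is.null(corr)) {
    utils::write.csv(corr, file.path(dir, "convergence_correlation.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
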
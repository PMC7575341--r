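#' Spectral clustering of balanced post samples
#'
#' The clustering pipeline is fixed and fully specified: standardize the
#' sampled feature rows, project to `n_components` principal components,
#' build a symmetric (union) k-nearest-neighbor connectivity affinity,
#' form the normalized graph Laplacian, take the `k` smallest eigenvectors,
#' and run seeded k-means on the embedding rows. Cluster-characteristic
#' features come from rank-sum tests with Bonferroni correction; cluster vs
#' group structure is tested with upper-tail hypergeometric enrichment.
#'
#' @name spectral-clustering
NULL

knn_affinity <- function(emb, nn) {
  n <- nrow(emb)
  nn <- min(nn, n - 1L)
  d <- as.matrix(stats::dist(emb))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    nb <- setdiff(ord, i)[seq_len(nn)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))  # union symmetrization
  diag(A) <- 0
  A
}

## connect components with minimal bridging edges (nearest cross pair)
connect_components <- function(A, emb) {
  g <- components_of(A)
  while (max(g) > 1L) {
    warning("affinity graph disconnected; adding bridging edge")
    d <- as.matrix(stats::dist(emb))
    in1 <- which(g == 1L); rest <- which(g != 1L)
    dd <- d[in1, rest, drop = FALSE]
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    a <- in1[ij[1]]; b <- rest[ij[2]]
    A[a, b] <- A[b, a] <- 1
    g <- components_of(A)
  }
  A
}

components_of <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Fit a spectral cluster model
#'
#' @param features a `mind_features`.
#' @param groups group label per feature row.
#' @param n_per_group balanced sample size per group (default 1500; shrunk
#'   uniformly with a warning when a group is smaller).
#' @param n_components PCA components (default 30).
#' @param k number of clusters (default 20).
#' @param nn nearest neighbors of the affinity graph (default 10).
#' @param seed RNG seed (sampling and k-means).
#' @param period free-text period tag stored on the model.
#' @return a `mind_cluster_model` with `assignments` (named by post id),
#'   sample indices, and the fitted projection.
#' @export
fit_cluster_model <- function(features, groups, n_per_group = 1500,
                              n_components = 30, k = 20, nn = 10,
                              seed = 1L, period = "") {
  stopifnot(inherits(features, "mind_features"),
            length(groups) == nrow(features$values))
  set.seed(seed)
  glev <- sort(unique(groups))
  n_take <- min(n_per_group, min(table(groups)))
  if (n_take < n_per_group) {
    warning("n_per_group shrunk uniformly to ", n_take)
  }
  sel <- unlist(lapply(glev, function(g) {
    idx <- which(groups == g)
    idx[sample.int(length(idx), n_take)]
  }))
  sel <- sort(sel)
  if (k > length(sel)) stop("k exceeds sample size")
  x <- features$values[sel, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  keep_f <- sds > 0
  xs <- scale(x[, keep_f, drop = FALSE])
  nc <- min(n_components, ncol(xs), nrow(xs) - 1L)
  pca <- stats::prcomp(xs, center = FALSE, scale. = FALSE, rank. = nc)
  emb <- pca$x
  A <- knn_affinity(emb, nn)
  A <- connect_components(A, emb)
  deg <- rowSums(A)
  dinv <- 1 / sqrt(pmax(deg, 1e-12))
  L <- diag(nrow(A)) - (dinv * A) %*% diag(dinv)
  L <- (L + t(L)) / 2
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, ncol(ev$vectors) - seq_len(k) + 1L, drop = FALSE]
  km <- stats::kmeans(U, centers = k, nstart = 10, iter.max = 100)
  assignments <- stats::setNames(km$cluster, features$post_ids[sel])
  structure(list(
    period = period, sample_idx = sel,
    sample_ids = features$post_ids[sel], sample_groups = groups[sel],
    projection = list(center = attr(xs, "scaled:center"),
                      scale = attr(xs, "scaled:scale"),
                      keep = keep_f, rotation = pca$rotation),
    k = k, nn = nn, n_components = nc, n_per_group = n_take,
    assignments = assignments, seed = seed,
    characteristic = NULL, annotation = stats::setNames(rep("", k), seq_len(k))
  ), class = "mind_cluster_model")
}

#' @export
print.mind_cluster_model <- function(x, ...) {
  cat("<cluster model", if (nzchar(x$period)) paste0(" [", x$period, "]"),
      ": ", length(x$assignments), " posts, k=", x$k, ", sizes ",
      paste(tabulate(x$assignments, x$k), collapse = "/"), ">\n", sep = "")
  invisible(x)
}

#' Cluster-characteristic features
#'
#' Per (cluster, feature): rank-sum test of in-cluster vs out-of-cluster
#' values, Bonferroni-corrected over the full clusters x features family.
#' Significant features are returned sorted by |rank-biserial| effect size.
#' Uses the same midrank / tie-corrected normal approximation as
#' [mann_whitney_u()], vectorized over clusters.
#'
#' @param model a `mind_cluster_model`.
#' @param features the `mind_features` the model was fitted on.
#' @param alpha Bonferroni level.
#' @return the model, with `characteristic`: per cluster a data.frame
#'   (feature, direction, effect, p, p_adj).
#' @export
characteristic_features <- function(model, features, alpha = 0.05) {
  idx <- match(model$sample_ids, features$post_ids)
  x <- features$values[idx, , drop = FALSE]
  cl <- model$assignments
  n <- nrow(x)
  m_tests <- 0L
  res <- vector("list", model$k)
  ranks <- apply(x, 2, rank, ties.method = "average")
  tie_term <- apply(x, 2, function(col) {
    tt <- table(col)
    sum(tt^3 - tt) / (n * (n - 1))
  })
  const <- apply(x, 2, function(col) length(unique(col)) == 1L)
  m_tests <- model$k * sum(!const)
  for (ci in seq_len(model$k)) {
    inc <- cl == ci
    n1 <- sum(inc); n2 <- n - n1
    if (n1 == 0L || n2 == 0L) {
      res[[ci]] <- data.frame(feature = character(0), direction = character(0),
                              effect = numeric(0), p = numeric(0),
                              p_adj = numeric(0))
      next
    }
    r1 <- colSums(ranks[inc, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(pmax(sigma2, 1e-12))
    p <- 2 * stats::pnorm(-abs(z))
    p[const] <- 1
    p_adj <- bonferroni_adjust(p, m_tests)
    rb <- 2 * u / (n1 * n2) - 1  # rank-biserial, >0 means higher in cluster
    keep <- !const & p_adj <= alpha
    df <- data.frame(feature = colnames(x)[keep],
                     direction = ifelse(rb[keep] > 0, "up", "down"),
                     effect = rb[keep], p = p[keep], p_adj = p_adj[keep],
                     stringsAsFactors = FALSE)
    df <- df[order(-abs(df$effect), df$feature), ]
    rownames(df) <- NULL
    res[[ci]] <- df
  }
  model$characteristic <- res
  model
}

#' Cluster-group enrichment table
#'
#' Upper-tail hypergeometric test per (cluster, group): population = the
#' clustered sample, successes = cluster size, draws = group size, observed
#' = overlap; Bonferroni over clusters x groups.
#'
#' @param model a `mind_cluster_model`.
#' @param alpha Bonferroni level.
#' @return data.frame (cluster, group, overlap, cluster_size, group_size,
#'   p, p_adj, significant).
#' @export
cluster_enrichment <- function(model, alpha = 0.05) {
  cl <- model$assignments
  gr <- model$sample_groups
  N <- length(cl)
  glev <- sort(unique(gr))
  m <- model$k * length(glev)
  rows <- list()
  for (ci in seq_len(model$k)) {
    K <- sum(cl == ci)
    for (g in glev) {
      ng <- sum(gr == g)
      k_obs <- sum(cl == ci & gr == g)
      p <- hypergeometric_tail(N, K, ng, k_obs)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = ci, group = g, overlap = k_obs, cluster_size = K,
        group_size = ng, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p, m)
  out$significant <- out$p_adj <= alpha
  out
}

#' Match clusters across two periods
#'
#' Greedy one-to-one matching by descending Jaccard similarity of the
#' top-`top_m` characteristic-feature name sets; pairs below `tau` stay
#' unmatched. The size ratio mid/pre is reported per matched pair.
#'
#' @param pre_model,mid_model fitted models with characteristic features.
#' @param top_m number of top characteristic features compared.
#' @param tau minimum Jaccard for a match.
#' @return a `mind_cluster_matching`: `pairs` data.frame (pre_cluster,
#'   mid_cluster, jaccard, size_pre, size_mid, size_ratio), plus
#'   `unmatched_pre` and `unmatched_mid` (emergent clusters).
#' @export
match_clusters <- function(pre_model, mid_model, top_m = 25, tau = 0.2) {
  tops <- function(model) {
    lapply(model$characteristic, function(df) {
      utils::head(df$feature, top_m)
    })
  }
  if (is.null(pre_model$characteristic) || is.null(mid_model$characteristic)) {
    stop("compute characteristic_features() on both models first")
  }
  a <- tops(pre_model); b <- tops(mid_model)
  if (all(lengths(a) == 0) || all(lengths(b) == 0)) {
    stop("no significant characteristic features to match on")
  }
  jac <- matrix(0, length(a), length(b))
  for (i in seq_along(a)) for (j in seq_along(b)) {
    u <- length(union(a[[i]], b[[j]]))
    jac[i, j] <- if (u == 0) 0 else length(intersect(a[[i]], b[[j]])) / u
  }
  size_pre <- tabulate(pre_model$assignments, pre_model$k)
  size_mid <- tabulate(mid_model$assignments, mid_model$k)
  pairs <- list()
  J <- jac
  repeat {
    best <- which(J == max(J), arr.ind = TRUE)[1, , drop = TRUE]
    if (J[best[1], best[2]] < tau || max(J) <= 0) break
    i <- best[1]; j <- best[2]
    pairs[[length(pairs) + 1L]] <- data.frame(
      pre_cluster = i, mid_cluster = j, jaccard = jac[i, j],
      size_pre = size_pre[i], size_mid = size_mid[j],
      size_ratio = size_mid[j] / max(1, size_pre[i]))
    J[i, ] <- -1; J[, j] <- -1
    if (all(J < tau)) break
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pre_cluster = integer(0), mid_cluster = integer(0),
               jaccard = numeric(0), size_pre = integer(0),
               size_mid = integer(0), size_ratio = numeric(0))
  structure(list(
    pairs = pairs,
    unmatched_pre = setdiff(seq_len(pre_model$k), pairs$pre_cluster),
    unmatched_mid = setdiff(seq_len(mid_model$k), pairs$mid_cluster),
    top_m = top_m, tau = tau
  ), class = "mind_cluster_matching")
}

#' @export
print.mind_cluster_matching <- function(x, ...) {
  cat("<cluster matching: ", nrow(x$pairs), " matched pairs, ",
      length(x$unmatched_pre), " unmatched pre, ",
      length(x$unmatched_mid), " emergent mid>\n", sep = "")
  invisible(x)
}

entropy_of <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Agreement between a clustering and the group labels
#'
#' Homogeneity, completeness and V-measure from the conditional entropies of
#' the contingency table, and the adjusted Rand index.
#'
#' @param assignments cluster labels.
#' @param groups reference labels of the same length.
#' @return named numeric vector (homogeneity, completeness, v_measure,
#'   adjusted_rand).
#' @export
label_agreement <- function(assignments, groups) {
  stopifnot(length(assignments) == length(groups))
  tab <- table(groups, assignments)
  n <- sum(tab)
  pc <- rowSums(tab) / n   # classes
  pk <- colSums(tab) / n   # clusters
  hc <- entropy_of(pc)
  hk <- entropy_of(pk)
  p_joint <- tab / n
  h_c_given_k <- -sum(p_joint[p_joint > 0] *
                        log(p_joint[p_joint > 0] /
                              rep(pk, each = nrow(tab))[p_joint > 0]))
  h_k_given_c <- -sum(p_joint[p_joint > 0] *
                        log((p_joint / rep(pc, times = ncol(tab)))[p_joint > 0]))
  homogeneity <- if (hc == 0) 1 else 1 - h_c_given_k / hc
  completeness <- if (hk == 0) 1 else 1 - h_k_given_c / hk
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  ari <- mclust::adjustedRandIndex(assignments, groups)
  c(homogeneity = homogeneity, completeness = completeness,
    v_measure = v, adjusted_rand = ari)
}

#' Shannon diversity of each cluster's group composition
#'
#' H = -sum p_g log p_g over the cluster's group proportions.
#'
#' @param model a `mind_cluster_model`.
#' @return numeric vector, one H per cluster.
#' @export
cluster_diversity <- function(model) {
  vapply(seq_len(model$k), function(ci) {
    g <- model$sample_groups[model$assignments == ci]
    if (length(g) == 0) return(0)
    entropy_of(table(g) / length(g))
  }, numeric(1))
}

#' Write clustering outputs
#'
#' @param model fitted model with characteristic features.
#' @param enrich enrichment table.
#' @param matching optional `mind_cluster_matching`.
#' @param dir output directory.
#' @export
write_cluster_outputs <- function(model, enrich, matching = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(post_id = names(model$assignments),
                              cluster = as.integer(model$assignments)),
                   file.path(dir, "clusters.csv"), row.names = FALSE)
  cf <- do.call(rbind, lapply(seq_along(model$characteristic), function(ci) {
    df <- model$characteristic[[ci]]
    if (nrow(df) == 0) return(NULL)
    cbind(cluster = ci, df)
  }))
  if (is.null(cf)) cf <- data.frame(cluster = integer(0), feature = character(0))
  utils::write.csv(cf, file.path(dir, "cluster_features.csv"), row.names = FALSE)
  utils::write.csv(enrich, file.path(dir, "enrichment.csv"), row.names = FALSE)
  if (!is.null(matching)) {
    utils::write.csv(matching$pairs, file.path(dir, "cluster_matching.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
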
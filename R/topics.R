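#' Dirichlet-prior topic modeling
#'
#' Fits a latent Dirichlet allocation model per period on balanced samples
#' with a collapsed Gibbs sampler (compiled, seeded, deterministic), infers
#' per-post topic distributions for any period under the pre-period model,
#' and tests pre-vs-mid prevalence shifts per topic with a signed-rank test
#' across groups, BH-corrected over topics. Documents are represented on
#' the TF-IDF module's fitted stemmed n-gram vocabulary; the default
#' weighting is integer counts, with a `tfidf` mode that feeds rounded
#' TF-IDF weights to the estimator instead.
#'
#' @name topic-modeling
NULL

## doc-term count lists on the fitted vocabulary; returns flattened tokens
docs_to_tokens <- function(texts, tfidf, weighting = "counts") {
  toks <- tokenize(texts)$tokens
  vocab <- tfidf$vocab
  per_doc <- lapply(toks, function(t) {
    grams <- make_ngrams(t, tfidf$ngram_range, tfidf$stem)
    idx <- match(grams, vocab)
    idx <- idx[!is.na(idx)]
    if (weighting == "tfidf" && length(idx)) {
      tf <- tabulate(idx, nbins = length(vocab))
      w <- tf * tfidf$idf
      cnt <- round(w / max(w) * 20)
      rep(seq_along(cnt), cnt)
    } else idx
  })
  per_doc
}

#' Fit a topic model
#'
#' @param texts document texts of the (balanced) training sample.
#' @param tfidf fitted `mind_tfidf` providing the vocabulary.
#' @param K number of topics (default 10).
#' @param weighting `"counts"` (default) or `"tfidf"`.
#' @param alpha,beta Dirichlet hyperparameters.
#' @param n_iter,burnin Gibbs sweeps and burn-in.
#' @param seed integer seed; identical data + seed reproduce the model.
#' @param period free-text period tag.
#' @return a `mind_topic_model` with `phi` (K x V topic-term rows summing to
#'   1) and training `theta`.
#' @export
fit_topic_model <- function(texts, tfidf, K = 10, weighting = c("counts", "tfidf"),
                            alpha = 0.1, beta = 0.01, n_iter = 300,
                            burnin = 150, seed = 1L, period = "") {
  weighting <- match.arg(weighting)
  V <- length(tfidf$vocab)
  if (K > V) stop("K exceeds vocabulary size")
  per_doc <- docs_to_tokens(texts, tfidf, weighting)
  keep <- lengths(per_doc) > 0
  if (!all(keep)) message(sum(!keep), " empty document(s) dropped from fit")
  per_doc <- per_doc[keep]
  tokens <- unlist(per_doc, use.names = FALSE) - 1L
  doc_ptr <- c(0L, cumsum(lengths(per_doc)))
  res <- .lda_gibbs(as.integer(tokens), as.integer(doc_ptr), V, as.integer(K),
                    alpha, beta, as.integer(n_iter), as.integer(burnin),
                    as.integer(seed))
  phi <- res$phi
  colnames(phi) <- tfidf$vocab
  structure(list(period = period, K = K, phi = phi, theta = res$theta,
                 tfidf = tfidf, weighting = weighting, alpha = alpha,
                 beta = beta, n_iter = n_iter, burnin = burnin, seed = seed,
                 kept = keep),
            class = "mind_topic_model")
}

#' @export
print.mind_topic_model <- function(x, ...) {
  cat("<topic model", if (nzchar(x$period)) paste0(" [", x$period, "]"),
      ": K=", x$K, ", V=", ncol(x$phi), ", ", nrow(x$theta),
      " training docs (", x$weighting, ")>\n", sep = "")
  invisible(x)
}

#' Infer per-post topic distributions under a fitted model
#'
#' Deterministic fixed-point (EM) fold-in with the topic-term table held
#' fixed. Posts with zero in-vocabulary tokens are flagged (NA rows).
#'
#' @param model a `mind_topic_model`.
#' @param texts documents to score.
#' @param n_iter fixed-point iterations.
#' @return matrix posts x K, rows on the simplex (NA rows where no token is
#'   in vocabulary).
#' @export
infer_topics <- function(model, texts, n_iter = 60) {
  per_doc <- docs_to_tokens(texts, model$tfidf, model$weighting)
  K <- model$K
  phi <- model$phi
  out <- matrix(NA_real_, length(texts), K)
  for (i in seq_along(per_doc)) {
    ids <- per_doc[[i]]
    if (length(ids) == 0L) next
    cnt <- tabulate(ids, nbins = ncol(phi))
    w <- which(cnt > 0)
    cw <- cnt[w]
    pw <- phi[, w, drop = FALSE]  # K x |w|
    theta <- rep(1 / K, K)
    for (it in seq_len(n_iter)) {
      resp <- theta * pw            # K x |w|
      cs <- colSums(resp)
      cs[cs == 0] <- 1e-300
      theta_new <- (resp %*% (cw / cs)) + model$alpha
      theta <- as.numeric(theta_new / sum(theta_new))
    }
    out[i, ] <- theta
  }
  out
}

#' Top terms of a topic
#'
#' @param model a `mind_topic_model`.
#' @param topic topic index.
#' @param n number of terms (ties broken by name; n > V returns all).
#' @return character vector of terms, highest weight first.
#' @export
top_terms <- function(model, topic, n = 10) {
  stopifnot(topic >= 1, topic <= model$K)
  if (n <= 0) return(character(0))
  w <- model$phi[topic, ]
  ord <- order(-w, names(w))
  names(w)[ord][seq_len(min(n, length(w)))]
}

#' Topic stability across seeds
#'
#' Refits the model under several seeds and reports the mean best-match
#' cosine similarity between aligned topic-term rows, a stability check for
#' the chosen K.
#'
#' @param texts,tfidf,K,weighting as in [fit_topic_model()].
#' @param seeds integer vector (>= 2 seeds).
#' @param ... passed to [fit_topic_model()].
#' @return list with `mean_cosine` and the pairwise table.
#' @export
topic_stability <- function(texts, tfidf, K = 10, weighting = "counts",
                            seeds = 1:3, ...) {
  stopifnot(length(seeds) >= 2)
  fits <- lapply(seeds, function(s) {
    fit_topic_model(texts, tfidf, K = K, weighting = weighting, seed = s, ...)
  })
  pairs <- utils::combn(length(fits), 2)
  vals <- apply(pairs, 2, function(ij) {
    mean(best_match_cosine(fits[[ij[1]]]$phi, fits[[ij[2]]]$phi))
  })
  list(mean_cosine = mean(vals),
       pairwise = data.frame(i = seeds[pairs[1, ]], j = seeds[pairs[2, ]],
                             cosine = vals))
}

#' Greedy best-match cosine between two topic-term tables
#'
#' @param phi_a,phi_b K x V matrices (rows L2-comparable).
#' @return per-topic cosine of the greedy one-to-one alignment.
#' @export
best_match_cosine <- function(phi_a, phi_b) {
  an <- phi_a / sqrt(rowSums(phi_a^2))
  bn <- phi_b / sqrt(rowSums(phi_b^2))
  S <- an %*% t(bn)
  out <- numeric(0)
  while (nrow(S) > 0 && ncol(S) > 0) {
    ij <- which(S == max(S), arr.ind = TRUE)[1, ]
    out <- c(out, S[ij[1], ij[2]])
    S <- S[-ij[1], -ij[2], drop = FALSE]
  }
  out
}

#' Test pre-vs-mid topic prevalence shifts across groups
#'
#' Both periods are inferred under the same (pre-period) model. Per topic,
#' the paired per-group mean prevalences are compared with a two-sided
#' signed-rank test across groups; BH over the K topics.
#'
#' @param model the pre-period `mind_topic_model`.
#' @param pre_texts,pre_groups,mid_texts,mid_groups documents and group
#'   labels for the two periods.
#' @param alpha BH level.
#' @return a `mind_topic_shift`: data.frame per topic (topic, mean_pre,
#'   mean_mid, direction, p, q, significant) plus the per-group prevalence
#'   table.
#' @export
compare_topic_prevalence <- function(model, pre_texts, pre_groups,
                                     mid_texts, mid_groups, alpha = 0.05) {
  th_pre <- infer_topics(model, pre_texts)
  th_mid <- infer_topics(model, mid_texts)
  group_means <- function(th, g) {
    ok <- !is.na(th[, 1])
    ag <- stats::aggregate(th[ok, , drop = FALSE], list(group = g[ok]), mean)
    ag
  }
  mp <- group_means(th_pre, pre_groups)
  mm <- group_means(th_mid, mid_groups)
  shared <- intersect(mp$group, mm$group)
  dropped <- setdiff(union(mp$group, mm$group), shared)
  if (length(dropped)) {
    warning("groups present in only one period dropped: ",
            paste(dropped, collapse = ", "))
  }
  mp <- mp[match(shared, mp$group), ]
  mm <- mm[match(shared, mm$group), ]
  K <- model$K
  rows <- lapply(seq_len(K), function(t) {
    pre_v <- mp[[t + 1]]
    mid_v <- mm[[t + 1]]
    ts <- wilcoxon_signed_rank(mid_v - pre_v)
    data.frame(topic = t, mean_pre = mean(pre_v), mean_mid = mean(mid_v),
               direction = ifelse(mean(mid_v) >= mean(pre_v), "up", "down"),
               p = ts$p, degenerate = ts$degenerate)
  })
  res <- do.call(rbind, rows)
  adj <- bh_adjust(res$p, alpha)
  res$q <- adj$q
  res$significant <- adj$reject
  prev <- rbind(cbind(period = "pre", mp), cbind(period = "mid", mm))
  structure(list(shifts = res, prevalence = prev, groups = shared),
            class = "mind_topic_shift")
}

#' @export
print.mind_topic_shift <- function(x, ...) {
  cat("<topic shift test over", length(x$groups), "groups>\n")
  print(x$shifts[, c("topic", "mean_pre", "mean_mid", "direction", "q",
                     "significant")])
  invisible(x)
}

#' Write topic-model outputs
#'
#' @param model fitted model.
#' @param shift optional `mind_topic_shift`.
#' @param dir output directory.
#' @param n_terms terms per topic in `topics_terms.csv`.
#' @export
write_topic_outputs <- function(model, shift = NULL, dir, n_terms = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tt <- do.call(rbind, lapply(seq_len(model$K), function(t) {
    terms <- top_terms(model, t, n_terms)
    data.frame(topic = t, rank = seq_along(terms), term = terms,
               weight = model$phi[t, terms], stringsAsFactors = FALSE)
  }))
  utils::write.csv(tt, file.path(dir, "topics_terms.csv"), row.names = FALSE)
  if (!is.null(shift)) {
    utils::write.csv(shift$prevalence, file.path(dir, "topic_prevalence.csv"),
                     row.names = FALSE)
    utils::write.csv(shift$shifts, file.path(dir, "topic_shift.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
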
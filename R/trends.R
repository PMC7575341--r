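#' Trend analysis of time-binned features
#'
#' Bins each (group, feature) series into fixed-width date bins (default 2
#' days), fits ordinary least squares of the bin mean on the bin index, and
#' scores each trend with `change = slope * R^2` — the rate of change
#' weighed by the goodness of fit. Significance is controlled with the
#' Benjamini-Hochberg procedure, jointly over the whole group-by-feature
#' family by default.
#'
#' @name trend-analysis
NULL

#' Bin per-post feature values into date bins
#'
#' @param features a `mind_features` aligned with `corp`.
#' @param corp a `mind_corpus` (dates taken from `created_utc`).
#' @param bin_days bin width in days.
#' @param window optional c(start, end) Dates; defaults to the span of the
#'   non-baseline periods present.
#' @return data.frame with group, feature, bin (0-based index), bin_start,
#'   mean, n; empty bins are absent (recorded implicitly by gaps).
#' @export
bin_series <- function(features, corp, bin_days = 2, window = NULL) {
  stopifnot(inherits(features, "mind_features"), inherits(corp, "mind_corpus"))
  idx <- match(features$post_ids, corp$posts$id)
  stopifnot(!anyNA(idx))
  dates <- corp$posts$created_utc[idx]
  groups <- corp$posts$group[idx]
  if (is.null(window)) window <- range(dates)
  keep <- dates >= window[1] & dates <= window[2]
  dates <- dates[keep]; groups <- groups[keep]
  vals <- features$values[keep, , drop = FALSE]
  bin <- as.integer(floor(as.numeric(dates - window[1]) / bin_days))
  key <- paste(groups, bin, sep = "\r")
  out <- list()
  for (f in seq_len(ncol(vals))) {
    mu <- tapply(vals[, f], key, mean)
    nn <- tapply(vals[, f], key, length)
    kk <- strsplit(names(mu), "\r", fixed = TRUE)
    g <- vapply(kk, `[[`, character(1), 1)
    b <- as.integer(vapply(kk, `[[`, character(1), 2))
    out[[f]] <- data.frame(group = g, feature = features$feature_names[f],
                           bin = b, bin_start = window[1] + b * bin_days,
                           mean = as.numeric(mu), n = as.integer(nn),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$feature, res$bin), ]
  rownames(res) <- NULL
  attr(res, "bin_days") <- bin_days
  attr(res, "window") <- window
  res
}

ols_trend <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (syy < 1e-300 || sxx == 0) {
    return(list(slope = 0, intercept = my, r2 = 0, p = 1, degenerate = TRUE))
  }
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  rss <- syy - slope * sxy
  if (n <= 2 || rss <= 0) {
    p <- if (r2 >= 1 - 1e-12 && n > 2) 0 else 1
    return(list(slope = slope, intercept = my - slope * mx, r2 = min(1, r2),
                p = p, degenerate = n <= 2))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  tt <- slope / se
  list(slope = slope, intercept = my - slope * mx, r2 = r2,
       p = 2 * stats::pt(-abs(tt), df = n - 2), degenerate = FALSE)
}

#' Fit per-(group, feature) trends with joint BH correction
#'
#' OLS of bin mean on bin index; p from the two-sided slope t-test;
#' `change = slope * R^2`. Series with fewer than `min_bins` non-empty bins
#' are excluded with a warning; zero-variance series get slope 0, R^2 0,
#' p 1 and a degenerate flag.
#'
#' @param binned output of [bin_series()].
#' @param alpha BH level.
#' @param family `"joint"` (BH over all group x feature pairs, default) or
#'   `"per_group"`.
#' @param min_bins minimum non-empty bins per series.
#' @param weighted weight bins by post count (default FALSE, plain OLS).
#' @return a `mind_trends` data.frame: group, feature, slope, intercept, r2,
#'   p, q, change, significant, degenerate, n_bins.
#' @export
fit_trends <- function(binned, alpha = 0.05, family = c("joint", "per_group"),
                       min_bins = 3, weighted = FALSE) {
  family <- match.arg(family)
  sp <- split(binned, list(binned$group, binned$feature), drop = TRUE)
  short <- vapply(sp, nrow, integer(1)) < min_bins
  if (any(short)) {
    warning(sum(short), " series with < ", min_bins, " non-empty bins excluded")
    sp <- sp[!short]
  }
  rows <- lapply(sp, function(s) {
    if (weighted) {
      # weighted OLS via expansion of the normal equations
      w <- s$n / sum(s$n)
      mx <- sum(w * s$bin); my <- sum(w * s$mean)
      sxx <- sum(w * (s$bin - mx)^2); syy <- sum(w * (s$mean - my)^2)
      sxy <- sum(w * (s$bin - mx) * (s$mean - my))
      ft <- if (syy < 1e-300 || sxx == 0) {
        list(slope = 0, intercept = my, r2 = 0, p = 1, degenerate = TRUE)
      } else {
        sl <- sxy / sxx
        r2 <- sxy^2 / (sxx * syy)
        o <- ols_trend(s$bin, s$mean)  # unweighted p as a pragmatic fallback
        list(slope = sl, intercept = my - sl * mx, r2 = r2, p = o$p,
             degenerate = FALSE)
      }
    } else {
      ft <- ols_trend(s$bin, s$mean)
    }
    data.frame(group = s$group[1], feature = s$feature[1],
               slope = ft$slope, intercept = ft$intercept, r2 = ft$r2,
               p = ft$p, change = ft$slope * ft$r2,
               degenerate = ft$degenerate, n_bins = nrow(s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (family == "joint") {
    adj <- bh_adjust(res$p, alpha)
    res$q <- adj$q
    res$significant <- adj$reject
  } else {
    res$q <- NA_real_
    res$significant <- FALSE
    for (g in unique(res$group)) {
      sel <- res$group == g
      adj <- bh_adjust(res$p[sel], alpha)
      res$q[sel] <- adj$q
      res$significant[sel] <- adj$reject
    }
  }
  attr(res, "alpha") <- alpha
  attr(res, "bin_days") <- attr(binned, "bin_days")
  class(res) <- c("mind_trends", "data.frame")
  res
}

#' Default valence specification for the semantic-change ranking
#'
#' 13 negatively valenced features weighted +1 (negative sentiment, the six
#' custom lexicons, and the anger, anxiety, death, negations,
#' negative-emotion and sadness categories) and 3 positive features weighted
#' -1 (compound sentiment, positive sentiment, positive emotion).
#'
#' @return list with `negative` and `positive` feature-name vectors.
#' @export
default_valence_spec <- function() {
  list(
    negative = c("sentiment:sent_negative",
                 "custom:suicidality", "custom:economic_stress",
                 "custom:isolation", "custom:substance_use",
                 "custom:domestic_stress", "custom:guns",
                 "category:anger", "category:anxiety", "category:death",
                 "category:negations", "category:negative_emotion",
                 "category:sadness"),
    positive = c("sentiment:sent_compound", "sentiment:sent_positive",
                 "category:positive_emotion")
  )
}

#' Rank groups by negative semantic change
#'
#' Per group, the sum of significant change scores over the negative-valence
#' features minus the sum over the positive-valence features (positive
#' features inversely weighed). Only BH-significant trends contribute.
#'
#' @param trends a `mind_trends`.
#' @param valence_spec list with `negative` / `positive` feature names.
#' @return data.frame (group, score, n_contributing, rank), sorted
#'   descending by score, ties broken by group name.
#' @export
rank_semantic_change <- function(trends, valence_spec = default_valence_spec()) {
  stopifnot(length(valence_spec$negative) + length(valence_spec$positive) > 0)
  groups <- sort(unique(trends$group))
  sig <- trends[trends$significant, , drop = FALSE]
  score <- vapply(groups, function(g) {
    s <- sig[sig$group == g, , drop = FALSE]
    sum(s$change[s$feature %in% valence_spec$negative]) -
      sum(s$change[s$feature %in% valence_spec$positive])
  }, numeric(1))
  ncontrib <- vapply(groups, function(g) {
    s <- sig[sig$group == g, , drop = FALSE]
    sum(s$feature %in% c(valence_spec$negative, valence_spec$positive))
  }, numeric(1))
  out <- data.frame(group = groups, score = score,
                    n_contributing = as.integer(ncontrib),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$group), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Compare the amount of absolute change between two years
#'
#' Mann-Whitney U on the two collections of |change| values over the same
#' (group, feature) grid.
#'
#' @param trends_a,trends_b `mind_trends` tables for the two years.
#' @param significant_only pool only BH-significant trends (default FALSE:
#'   pool all).
#' @return a `mind_test`.
#' @export
compare_year_change <- function(trends_a, trends_b, significant_only = FALSE) {
  stopifnot(nrow(trends_a) > 0, nrow(trends_b) > 0)
  a <- if (significant_only) trends_a[trends_a$significant, ] else trends_a
  b <- if (significant_only) trends_b[trends_b$significant, ] else trends_b
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty trend set")
  mann_whitney_u(abs(a$change), abs(b$change))
}

#' Track event-token posting over time
#'
#' Per (group, bin): the proportion of posts containing at least one
#' event-lexicon token. If an external case series (date, cumulative count)
#' is supplied, the Spearman correlation between the across-group mean
#' proportion and the case series is reported (aligned by date
#' intersection).
#'
#' @param corp a `mind_corpus`.
#' @param event_lexicon a `mind_lexicon` (default: bundled event tokens).
#' @param case_series optional data.frame (date, count).
#' @param bin_days bin width.
#' @param window c(start, end) Dates; default the analysis-year periods.
#' @param measure `"posts"` (default): proportion of posts containing at
#'   least one event token; `"tokens"`: mean per-post event-token share,
#'   which does not saturate when event language becomes ubiquitous.
#' @return a `mind_event_series`: `series` data.frame (group, bin,
#'   bin_start, proportion, n), `mean_series`, and optional `correlation`.
#' @export
track_event_tokens <- function(corp, event_lexicon = bundled_lexicons("event"),
                               case_series = NULL, bin_days = 2,
                               window = NULL, measure = c("posts", "tokens")) {
  measure <- match.arg(measure)
  stopifnot(inherits(event_lexicon, "mind_lexicon"),
            length(event_lexicon$entries) > 0)
  if (is.null(window)) {
    per <- post_periods(corp)
    keep <- !is.na(per) & per != "baseline_year"
    if (!any(keep)) keep <- !is.na(per)
    window <- range(corp$posts$created_utc[keep])
  }
  sel <- corp$posts$created_utc >= window[1] & corp$posts$created_utc <= window[2]
  posts <- corp$posts[sel, , drop = FALSE]
  toks <- tokenize(posts$text)$tokens
  hit <- if (measure == "posts") {
    vapply(toks, function(t) count_matches(t, event_lexicon) > 0, numeric(1))
  } else {
    vapply(toks, function(t) count_matches(t, event_lexicon) /
             max(1L, length(t)), numeric(1))
  }
  bin <- as.integer(floor(as.numeric(posts$created_utc - window[1]) / bin_days))
  key <- paste(posts$group, bin, sep = "\r")
  prop <- tapply(hit, key, mean)
  nn <- tapply(hit, key, length)
  kk <- strsplit(names(prop), "\r", fixed = TRUE)
  g <- vapply(kk, `[[`, character(1), 1)
  b <- as.integer(vapply(kk, `[[`, character(1), 2))
  series <- data.frame(group = g, bin = b, bin_start = window[1] + b * bin_days,
                       proportion = as.numeric(prop), n = as.integer(nn),
                       stringsAsFactors = FALSE)
  series <- series[order(series$group, series$bin), ]
  mean_series <- stats::aggregate(proportion ~ bin + bin_start, series, mean)
  mean_series <- mean_series[order(mean_series$bin), ]
  correlation <- NULL
  if (!is.null(case_series)) {
    cs <- data.frame(date = as.Date(case_series[[1]]),
                     count = as.numeric(case_series[[2]]))
    cs$bin <- as.integer(floor(as.numeric(cs$date - window[1]) / bin_days))
    cs_bin <- stats::aggregate(count ~ bin, cs, function(z) z[length(z)])
    m <- merge(mean_series, cs_bin, by = "bin")
    if (nrow(m) < 3) {
      warning("fewer than 3 shared time points with the case series")
    } else {
      correlation <- spearman_rho(m$proportion, m$count)
    }
  }
  structure(list(series = series, mean_series = mean_series,
                 correlation = correlation, window = window,
                 bin_days = bin_days),
            class = "mind_event_series")
}

#' @export
print.mind_event_series <- function(x, ...) {
  cat("<event-token series: ", length(unique(x$series$group)), " groups, ",
      length(unique(x$series$bin)), " bins>\n", sep = "")
  if (!is.null(x$correlation)) print(x$correlation)
  invisible(x)
}

#' Write trend outputs
#'
#' @param trends a `mind_trends`.
#' @param ranking output of [rank_semantic_change()].
#' @param dir output directory.
#' @export
write_trend_outputs <- function(trends, ranking, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trends[, c("group", "feature", "slope", "r2", "p", "q",
                              "change", "significant")],
                   file.path(dir, "trends.csv"), row.names = FALSE)
  utils::write.csv(ranking[, c("group", "score", "rank")],
                   file.path(dir, "semantic_change.csv"), row.names = FALSE)
  invisible(dir)
}
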
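#' Synthetic post corpora with planted, recoverable effects
#'
#' Generates reproducible multi-group corpora with the statistical structure
#' the analysis stages assume: group-specific marker vocabularies,
#' multi-post authors, a baseline year plus an analysis year, a logistic
#' event-vocabulary ramp, linear drifts in lexicon-feature prevalence, and
#' latent discussion themes whose per-group prevalence can shift between the
#' pre-event and mid-event periods. Token emission is i.i.d. within a post
#' given (group, theme, date) — the simplest model that the downstream
#' bag-of-words stages assume. Alongside the corpus a ground-truth record of
#' every planted parameter is returned for recovery tests.
#'
#' @name synthetic-corpus
NULL

#' Synthetic corpus configuration
#'
#' Defaults are the package's standard study conditions: 16 groups, 400
#' posts per group per period, geometric author multiplicity (mean 1.6),
#' negative-binomial post length (mean 120 tokens), marker rate 0.05, and an
#' analysis window of January 1 - April 20 with a baseline window one year
#' earlier.
#'
#' @param n_groups number of groups.
#' @param posts_per_group_per_period posts per group in each declared period.
#' @param posts_per_author mean of the geometric posts-per-author law.
#' @param post_length_mean,post_length_disp negative-binomial token count
#'   (mean, dispersion `size`); lengths are clamped to >= 5 tokens.
#' @param shared_vocab_size size of the shared emission vocabulary (generic
#'   tokens plus a seeded sample of bundled-lexicon words, Zipf-weighted).
#' @param marker_tokens_per_group,marker_rate group marker vocabulary size
#'   and per-token emission probability.
#' @param theme_specs optional list of theme specs, each
#'   `list(name=, vocab = character)`, plus a `prevalence` element: a named
#'   list (one entry per period) of groups x themes probability matrices with
#'   rows summing to 1. NULL disables themes.
#' @param theme_token_rate per-token probability of emitting from the post's
#'   theme vocabulary.
#' @param drift_specs optional data.frame with columns `group`, `lexicon`,
#'   `base_rate`, `slope` (proportion units per day, applied over the
#'   analysis year only); lexicon names refer to bundled custom/category
#'   lexicons whose literal entries are emitted.
#' @param event_spec optional `list(onset=, steepness=, vocab=, ceiling=)`:
#'   logistic ramp midpoint (Date within the analysis year), steepness per
#'   day, event vocabulary (default: bundled event tokens), and per-group
#'   ceiling emission rate (single number or named by group).
#' @param sentence_period tokens per inserted sentence terminator.
#' @param analysis_start,analysis_end analysis-year window (the baseline
#'   window is the same span one year earlier).
#' @param event_onset_split if TRUE (default) the analysis year is split
#'   into `pre_event` / `mid_event` at the event onset date (or at
#'   `analysis_split` when there is no event).
#' @param analysis_split fallback pre/mid split date.
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   corpus.
#' @return a `mind_synth_config`.
#' @export
synthetic_config <- function(n_groups = 16,
                             posts_per_group_per_period = 400,
                             posts_per_author = 1.6,
                             post_length_mean = 120,
                             post_length_disp = 10,
                             shared_vocab_size = 400,
                             marker_tokens_per_group = 8,
                             marker_rate = 0.05,
                             theme_specs = NULL,
                             theme_token_rate = 0.2,
                             drift_specs = NULL,
                             event_spec = NULL,
                             sentence_period = 12,
                             analysis_start = as.Date("2020-01-01"),
                             analysis_end = as.Date("2020-04-20"),
                             event_onset_split = TRUE,
                             analysis_split = as.Date("2020-03-01"),
                             seed = 1L) {
  stopifnot(n_groups >= 2, posts_per_group_per_period >= 1,
            posts_per_author >= 1, post_length_mean >= 5,
            marker_rate >= 0, marker_rate <= 1,
            theme_token_rate >= 0, theme_token_rate <= 1)
  groups <- sprintf("grp%02d", seq_len(n_groups))
  if (!is.null(event_spec)) {
    if (is.null(event_spec$vocab)) {
      event_spec$vocab <- bundled_lexicons("event")$exact
    }
    if (is.null(event_spec$steepness)) event_spec$steepness <- 0.15
    if (is.null(event_spec$onset)) event_spec$onset <- analysis_split
    # onset may be a single date or a named per-group vector of dates
    event_spec$onset <- stats::setNames(as.Date(event_spec$onset),
                                        names(event_spec$onset))
    ceil <- event_spec$ceiling %||% 0.05
    if (is.null(names(ceil))) ceil <- stats::setNames(rep(ceil[1], n_groups), groups)
    stopifnot(all(ceil >= 0 & ceil <= 1))
    event_spec$ceiling <- ceil
  }
  if (!is.null(drift_specs)) {
    drift_specs <- as.data.frame(drift_specs, stringsAsFactors = FALSE)
    stopifnot(all(c("group", "lexicon", "base_rate", "slope") %in% names(drift_specs)),
              all(drift_specs$group %in% groups),
              all(drift_specs$base_rate >= 0 & drift_specs$base_rate <= 1))
  }
  if (!is.null(theme_specs)) {
    stopifnot(is.list(theme_specs$themes), is.list(theme_specs$prevalence))
    th_names <- vapply(theme_specs$themes, `[[`, character(1), "name")
    vocabs <- lapply(theme_specs$themes, `[[`, "vocab")
    if (anyDuplicated(unlist(vocabs))) stop("theme vocabularies collide")
    for (per in names(theme_specs$prevalence)) {
      pm <- theme_specs$prevalence[[per]]
      stopifnot(is.matrix(pm), ncol(pm) == length(th_names))
      if (any(abs(rowSums(pm) - 1) > 1e-8)) {
        stop("theme prevalence rows must sum to 1 (period ", per, ")")
      }
    }
  }
  structure(list(
    n_groups = n_groups, groups = groups,
    posts_per_group_per_period = posts_per_group_per_period,
    posts_per_author = posts_per_author,
    post_length_mean = post_length_mean, post_length_disp = post_length_disp,
    shared_vocab_size = shared_vocab_size,
    marker_tokens_per_group = marker_tokens_per_group,
    marker_rate = marker_rate,
    theme_specs = theme_specs, theme_token_rate = theme_token_rate,
    drift_specs = drift_specs, event_spec = event_spec,
    sentence_period = sentence_period,
    analysis_start = analysis_start, analysis_end = analysis_end,
    event_onset_split = event_onset_split, analysis_split = analysis_split,
    seed = as.integer(seed)
  ), class = "mind_synth_config")
}

#' @export
print.mind_synth_config <- function(x, ...) {
  cat("<synthetic config: ", x$n_groups, " groups x ",
      x$posts_per_group_per_period, " posts/period, seed ", x$seed, ">\n",
      sep = "")
  invisible(x)
}

## shared emission vocabulary: lexicon words + generic filler, Zipf weights
build_shared_vocab <- function(config) {
  lex_words <- unique(c(
    unlist(lapply(bundled_lexicons("categories"), `[[`, "exact")),
    unlist(lapply(bundled_lexicons("custom"), `[[`, "exact")),
    names(bundled_lexicons("valence"))
  ))
  n_lex <- min(length(lex_words), floor(config$shared_vocab_size * 0.6))
  words <- c(sample(lex_words, n_lex),
             sprintf("w%04d", seq_len(config$shared_vocab_size - n_lex)))
  words <- sample(words)  # shuffle so lexicon words span the frequency range
  # Zipf-Mandelbrot: rank-1 share ~5%, matching natural-text head words
  wts <- 1 / (seq_along(words) + 2.7)^1.05
  list(words = words, weights = wts / sum(wts))
}

marker_vocab <- function(groups, k) {
  stats::setNames(lapply(seq_along(groups), function(g) {
    sprintf("mk%02dx%02d", g, seq_len(k))
  }), groups)
}

## per-token emission rates for one (group, period, date) cell
drift_rate <- function(config, group, day_index) {
  ds <- config$drift_specs
  if (is.null(ds)) return(NULL)
  ds <- ds[ds$group == group, , drop = FALSE]
  if (nrow(ds) == 0L) return(NULL)
  r <- pmin(0.5, pmax(0, ds$base_rate + ds$slope * day_index))
  stats::setNames(r, ds$lexicon)
}

event_rate_at <- function(config, group, dates) {
  ev <- config$event_spec
  if (is.null(ev)) return(rep(0, length(dates)))
  onset <- if (!is.null(names(ev$onset)) && group %in% names(ev$onset)) {
    ev$onset[[group]]
  } else ev$onset[[1]]
  day <- as.numeric(dates - onset)
  ev$ceiling[[group]] * stats::plogis(ev$steepness * day)
}

## resolve a drift lexicon name to its emitted word list
drift_words <- function(lexicon_name) {
  all_lex <- c(bundled_lexicons("custom"), bundled_lexicons("categories"))
  if (!lexicon_name %in% names(all_lex)) {
    stop("unknown drift lexicon: ", lexicon_name)
  }
  w <- all_lex[[lexicon_name]]$exact
  if (length(w) == 0L) stop("drift lexicon has no literal entries: ", lexicon_name)
  w
}

#' Generate a synthetic corpus and its ground truth
#'
#' @param config a `mind_synth_config`.
#' @return list with `corpus` (a `mind_corpus`) and `ground_truth` (a
#'   `mind_ground_truth` recording marker tokens, drifts, per-post theme
#'   assignments, theme prevalences and expected event-token rates).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "mind_synth_config"))
  set.seed(config$seed)
  shared <- build_shared_vocab(config)
  markers <- marker_vocab(config$groups, config$marker_tokens_per_group)

  base_start <- config$analysis_start - 365
  base_end <- config$analysis_end - 365
  split <- if (!is.null(config$event_spec) && config$event_onset_split) {
    # per-group onsets: split at the median onset inside the analysis window
    on <- config$event_spec$onset
    on <- on[on >= config$analysis_start & on <= config$analysis_end]
    if (length(on)) as.Date(stats::median(on)) else config$analysis_split
  } else config$analysis_split
  periods <- list(
    baseline_year = c(base_start, base_end),
    pre_event = c(config$analysis_start, split - 1),
    mid_event = c(split, config$analysis_end)
  )

  theme_names <- if (!is.null(config$theme_specs)) {
    vapply(config$theme_specs$themes, `[[`, character(1), "name")
  } else character(0)
  theme_vocabs <- if (length(theme_names)) {
    stats::setNames(lapply(config$theme_specs$themes, `[[`, "vocab"), theme_names)
  } else list()

  dw_cache <- list()
  rows <- list(); truth_theme <- list(); k <- 0L
  for (per in names(periods)) {
    pr <- periods[[per]]
    days <- seq(pr[1], pr[2], by = "day")
    in_analysis <- per != "baseline_year"
    for (g in config$groups) {
      n <- config$posts_per_group_per_period
      ## authors: geometric multiplicity, truncated at the post quota
      counts <- integer(0)
      while (sum(counts) < n) {
        counts <- c(counts, 1L + stats::rgeom(n, 1 / config$posts_per_author))
      }
      counts <- counts[cumsum(counts) - counts < n]
      counts[length(counts)] <- n - sum(counts[-length(counts)])
      author_of <- rep(seq_along(counts), counts)
      dates <- sort(sample(days, n, replace = TRUE))
      lens <- pmax(5L, stats::rnbinom(n, mu = config$post_length_mean,
                                      size = config$post_length_disp))
      theme_of <- rep(NA_character_, n)
      if (length(theme_names) && !is.null(config$theme_specs$prevalence[[per]])) {
        pm <- config$theme_specs$prevalence[[per]]
        pv <- pm[match(g, config$groups), ]
        theme_of <- sample(theme_names, n, replace = TRUE, prob = pv)
      }
      p_event <- event_rate_at(config, g, dates)
      day_idx <- as.numeric(dates - config$analysis_start)
      for (i in seq_len(n)) {
        k <- k + 1L
        dr <- if (in_analysis) drift_rate(config, g, day_idx[i]) else NULL
        p_dr <- if (is.null(dr)) numeric(0) else dr
        p_mk <- config$marker_rate
        p_th <- if (!is.na(theme_of[i])) config$theme_token_rate else 0
        p_ev <- if (in_analysis) p_event[i] else 0
        p_base <- 1 - p_mk - p_th - p_ev - sum(p_dr)
        if (p_base <= 0) stop("emission rates exceed 1 for group ", g)
        src_p <- c(base = p_base, marker = p_mk, theme = p_th, event = p_ev, p_dr)
        src <- sample.int(length(src_p), lens[i], replace = TRUE, prob = src_p)
        toks <- character(lens[i])
        nb <- sum(src == 1L)
        if (nb) toks[src == 1L] <- sample(shared$words, nb, replace = TRUE,
                                          prob = shared$weights)
        nm <- sum(src == 2L)
        if (nm) toks[src == 2L] <- sample(markers[[g]], nm, replace = TRUE)
        nt <- sum(src == 3L)
        if (nt) toks[src == 3L] <- sample(theme_vocabs[[theme_of[i]]], nt,
                                          replace = TRUE)
        ne <- sum(src == 4L)
        if (ne) toks[src == 4L] <- sample(config$event_spec$vocab, ne,
                                          replace = TRUE)
        if (length(p_dr)) {
          for (j in seq_along(p_dr)) {
            lx <- names(p_dr)[j]
            if (is.null(dw_cache[[lx]])) dw_cache[[lx]] <- drift_words(lx)
            sel <- src == 4L + j
            if (any(sel)) toks[sel] <- sample(dw_cache[[lx]], sum(sel),
                                              replace = TRUE)
          }
        }
        txt <- render_text(toks, config$sentence_period)
        rows[[k]] <- data.frame(
          id = sprintf("p%07d", k),
          author = sprintf("a_%s_%s_%04d", g, per, author_of[i]),
          group = g, created_utc = dates[i], text = txt,
          stringsAsFactors = FALSE)
        truth_theme[[k]] <- theme_of[i]
      }
    }
  }
  posts <- do.call(rbind, rows)
  cp <- corpus(posts, periods, config$groups)

  event_tab <- NULL
  if (!is.null(config$event_spec)) {
    days <- seq(config$analysis_start, config$analysis_end, by = "day")
    event_tab <- do.call(rbind, lapply(config$groups, function(g) {
      data.frame(group = g, date = days,
                 rate = event_rate_at(config, g, days),
                 stringsAsFactors = FALSE)
    }))
  }
  gt <- structure(list(
    marker_tokens = markers,
    drifts = config$drift_specs,
    theme_assignment = data.frame(post_id = posts$id,
                                  theme = unlist(truth_theme),
                                  stringsAsFactors = FALSE),
    theme_prevalences = config$theme_specs$prevalence,
    theme_vocabs = theme_vocabs,
    event_rate = event_tab,
    config = config
  ), class = "mind_ground_truth")
  list(corpus = cp, ground_truth = gt)
}

render_text <- function(tokens, sentence_period) {
  n <- length(tokens)
  cut <- seq_len(n) %% sentence_period == 0L
  cut[n] <- TRUE
  paste0(paste0(tokens, ifelse(cut, ".", ""), collapse = " "))
}

#' Generate a stationary baseline-year corpus
#'
#' Requires a config with no drifts and no event; returns only the
#' baseline-year slice, used to calibrate null bands and year-over-year
#' comparisons.
#'
#' @param config a `mind_synth_config` without `drift_specs` / `event_spec`.
#' @return a `mind_corpus` covering the baseline-year period.
#' @export
generate_baseline_year <- function(config) {
  stopifnot(inherits(config, "mind_synth_config"))
  if (!is.null(config$drift_specs) || !is.null(config$event_spec)) {
    stop("baseline corpus must be null: remove drift_specs and event_spec")
  }
  out <- generate_corpus(config)
  corpus_subset(out$corpus, period = "baseline_year")
}

#' Tabulate the planted effects of a ground truth
#'
#' @param gt a `mind_ground_truth`.
#' @return data.frame with one row per planted effect (`kind`, `group`,
#'   `name`, `value`), suitable for test assertions and reports.
#' @export
summarize_ground_truth <- function(gt) {
  stopifnot(inherits(gt, "mind_ground_truth"))
  rows <- list()
  for (g in names(gt$marker_tokens)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "marker", group = g, name = "marker_tokens",
      value = paste(gt$marker_tokens[[g]], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!is.null(gt$drifts)) {
    for (i in seq_len(nrow(gt$drifts))) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "drift", group = gt$drifts$group[i], name = gt$drifts$lexicon[i],
        value = as.character(gt$drifts$slope[i]), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(gt$theme_prevalences)) {
    for (per in names(gt$theme_prevalences)) {
      pm <- gt$theme_prevalences[[per]]
      for (g in seq_len(nrow(pm))) {
        for (t in seq_len(ncol(pm))) {
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "theme", group = gt$config$groups[g],
            name = paste0(per, ":", colnames(pm)[t] %||% t),
            value = as.character(pm[g, t]), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!is.null(gt$event_rate)) {
    agg <- stats::aggregate(rate ~ group, gt$event_rate, max)
    for (i in seq_len(nrow(agg))) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "event_ceiling_realized", group = agg$group[i], name = "max_rate",
        value = as.character(signif(agg$rate[i], 6)), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(0), group = character(0),
                      name = character(0), value = character(0)))
  }
  do.call(rbind, rows)
}

#' Serialize / load a ground-truth summary
#'
#' @param gt a `mind_ground_truth`.
#' @param path output file (TSV).
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.table(summarize_ground_truth(gt), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth_summary <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                    colClasses = "character")
}
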
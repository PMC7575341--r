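#' Full-pipeline orchestration
#'
#' One configuration drives every stage in dependency order:
#' simulate -> features -> trends / classify / cluster / topics / converge.
#' A single global seed is fanned out to per-stage child seeds by a stable
#' string hash, so toggling one stage never shifts another stage's
#' randomness. Stage outputs are CSV files in the output directory plus a
#' JSON run manifest (config hash, seed, stage timings).
#'
#' @name pipeline
NULL

## stable string hash -> 31-bit integer, endian/platform independent
stable_hash <- function(s) {
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stable_hash(stage)) %% 2147483647)
}

#' Build a run configuration
#'
#' @param synth a `mind_synth_config` (or NULL with `corpus_path`).
#' @param corpus_path JSON-lines corpus to load instead of simulating.
#' @param stages character vector of stages to run, a subset of
#'   c("trends", "classify", "cluster", "topics", "converge").
#' @param tfidf_v TF-IDF vocabulary size for the feature stage.
#' @param seed global seed.
#' @param outdir output directory.
#' @param params named list of per-stage parameter overrides; unknown stage
#'   names are rejected.
#' @return a `mind_run_config`.
#' @export
run_config <- function(synth = synthetic_config(),
                       corpus_path = NULL,
                       stages = c("trends", "classify", "cluster", "topics",
                                  "converge"),
                       tfidf_v = 256, seed = 1L, outdir = "mindlang_out",
                       params = list()) {
  known <- c("trends", "classify", "cluster", "topics", "converge")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (!all(names(params) %in% c(known, "features", "simulate"))) {
    stop("unknown params section(s): ",
         paste(setdiff(names(params), c(known, "features", "simulate")),
               collapse = ", "))
  }
  structure(list(synth = synth, corpus_path = corpus_path, stages = stages,
                 tfidf_v = tfidf_v, seed = as.integer(seed), outdir = outdir,
                 params = params),
            class = "mind_run_config")
}

config_hash <- function(config) {
  stable_hash(paste(utils::capture.output(utils::str(config, digits.d = 12)),
                    collapse = "\n"))
}

pget <- function(config, stage, name, default) {
  v <- config$params[[stage]][[name]]
  if (is.null(v)) default else v
}

#' Run the full pipeline
#'
#' @param config a `mind_run_config`.
#' @param quiet suppress progress messages.
#' @return a `mind_report_bundle`: paths of every written output, the run
#'   manifest, and the in-memory stage objects.
#' @export
run_full <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "mind_run_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message("[mindlang] ", ...)
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, stage) {
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), start,
                                                   units = "secs")), 3)
  }

  ## simulate / load
  st <- tic()
  if (!is.null(config$corpus_path)) {
    log_msg("loading corpus from ", config$corpus_path)
    corp <- load_corpus(config$corpus_path)
    gt <- NULL
  } else {
    synth <- config$synth
    synth$seed <- child_seed(config$seed, "simulate")
    log_msg("simulating corpus (", synth$n_groups, " groups)")
    sim <- generate_corpus(synth)
    corp <- sim$corpus
    gt <- sim$ground_truth
    write_corpus(corp, file.path(config$outdir, "corpus.jsonl"))
    write_ground_truth(gt, file.path(config$outdir, "ground_truth.tsv"))
  }
  toc(st, "simulate")

  ## features: TF-IDF fitted on the pre-event period only (no leakage)
  st <- tic()
  spec <- feature_spec(tfidf_v = config$tfidf_v,
                       tfidf_v_free = pget(config, "features", "tfidf_v_free",
                                           FALSE))
  per <- as.character(post_periods(corp))
  pre_texts <- corp$posts$text[per == "pre_event"]
  if (length(pre_texts) < 2) pre_texts <- corp$posts$text
  tfidf <- fit_tfidf(pre_texts, spec)
  log_msg("extracting features for ", nrow(corp$posts), " posts")
  feats <- extract_features(corp, spec, tfidf)
  write_features(feats, file.path(config$outdir, "features.csv"))
  toc(st, "features")

  objects <- list(corpus = corp, ground_truth = gt, features = feats,
                  tfidf = tfidf)

  analysis_groups <- corp$groups
  pidx <- match(feats$post_ids, corp$posts$id)

  if ("trends" %in% config$stages) {
    st <- tic()
    log_msg("trend analysis")
    ana <- corpus_subset(corp, period = c("pre_event", "mid_event"))
    fa <- extract_features(ana, spec, NULL)
    binned <- bin_series(fa, ana, bin_days = pget(config, "trends", "bin_days", 2))
    trends <- fit_trends(binned, alpha = pget(config, "trends", "alpha", 0.05))
    ranking <- rank_semantic_change(trends)
    write_trend_outputs(trends, ranking, config$outdir)
    ev <- track_event_tokens(corp,
                             bin_days = pget(config, "trends", "bin_days", 2))
    utils::write.csv(ev$series, file.path(config$outdir, "event_tokens.csv"),
                     row.names = FALSE)
    objects$trends <- trends
    objects$semantic_change <- ranking
    objects$event_series <- ev
    toc(st, "trends")
  }

  if ("classify" %in% config$stages) {
    st <- tic()
    log_msg("classification")
    n_cls <- pget(config, "classify", "n_per_class", 2700)
    targets <- pget(config, "classify", "targets", analysis_groups)
    excl <- pget(config, "classify", "exclude_from_control", character(0))
    reports <- list(); imps <- list(); models <- list()
    for (g in targets) {
      seed_g <- child_seed(config$seed, paste0("classify:", g))
      task <- suppressWarnings(build_binary_task(
        corp, g, n_per_class = n_cls, exclude_from_control = excl,
        seed = seed_g))
      model <- train_classifier(task, feats,
                                model_kind = pget(config, "classify", "model_kind",
                                                  "sgd_l1"),
                                seed = seed_g)
      evr <- evaluate_classifier(model, task, feats)
      reports[[g]] <- cbind(group = g, model = model$model_kind, evr)
      rk <- rank_model_features(model)
      if (nrow(rk$positive)) {
        imps[[g]] <- rbind(cbind(group = g, sign = "positive", rk$positive),
                           cbind(group = g, sign = "negative", rk$negative))
      }
      models[[g]] <- model
    }
    utils::write.csv(do.call(rbind, reports),
                     file.path(config$outdir, "classification_report.csv"),
                     row.names = FALSE)
    imp_df <- if (length(imps)) do.call(rbind, imps) else
      data.frame(group = character(0))
    utils::write.csv(imp_df,
                     file.path(config$outdir, "feature_importance.csv"),
                     row.names = FALSE)
    objects$classifiers <- models
    toc(st, "classify")
  }

  if ("cluster" %in% config$stages) {
    st <- tic()
    log_msg("spectral clustering")
    k <- pget(config, "cluster", "k", 20)
    npg <- pget(config, "cluster", "n_per_group", 1500)
    ncomp <- pget(config, "cluster", "n_components", 30)
    pre_sel <- which(per[pidx] %in% c("baseline_year", "pre_event"))
    fpre <- list(values = feats$values[pre_sel, , drop = FALSE],
                 post_ids = feats$post_ids[pre_sel],
                 feature_names = feats$feature_names,
                 families = feats$families)
    class(fpre) <- "mind_features"
    gpre <- corp$posts$group[pidx][pre_sel]
    cm <- suppressWarnings(fit_cluster_model(
      fpre, gpre, n_per_group = npg, n_components = ncomp, k = k,
      nn = pget(config, "cluster", "nn", 10),
      seed = child_seed(config$seed, "cluster"), period = "pre"))
    cm <- characteristic_features(cm, fpre)
    enr <- cluster_enrichment(cm)
    write_cluster_outputs(cm, enr, NULL, config$outdir)
    utils::write.csv(
      data.frame(cluster = seq_len(cm$k), shannon = cluster_diversity(cm)),
      file.path(config$outdir, "cluster_diversity.csv"), row.names = FALSE)
    objects$cluster_model <- cm
    objects$enrichment <- enr
    toc(st, "cluster")
  }

  if ("topics" %in% config$stages) {
    st <- tic()
    log_msg("topic modeling")
    K <- pget(config, "topics", "K", 10)
    pre_i <- which(per == "pre_event" | per == "baseline_year")
    mid_i <- which(per == "mid_event")
    tm <- fit_topic_model(corp$posts$text[pre_i], tfidf, K = K,
                          weighting = pget(config, "topics", "weighting",
                                           "counts"),
                          seed = child_seed(config$seed, "topics"),
                          period = "pre")
    shift <- NULL
    if (length(mid_i) > 0) {
      shift <- suppressWarnings(compare_topic_prevalence(
        tm, corp$posts$text[pre_i], corp$posts$group[pre_i],
        corp$posts$text[mid_i], corp$posts$group[mid_i]))
    }
    write_topic_outputs(tm, shift, config$outdir)
    objects$topic_model <- tm
    objects$topic_shift <- shift
    toc(st, "topics")
  }

  if ("converge" %in% config$stages) {
    st <- tic()
    log_msg("convergence tracking")
    refs <- pget(config, "converge", "reference_groups", analysis_groups[1])
    traj <- suppressWarnings(distance_trajectory(
      feats, corp, refs,
      window_days = pget(config, "converge", "window_days", 15),
      n_per_group = pget(config, "converge", "n_per_group", 1300),
      n_boot = pget(config, "converge", "n_boot", 50),
      n_neighbors = pget(config, "converge", "n_neighbors", 15),
      seed = child_seed(config$seed, "converge")))
    evw <- event_by_window(corp, traj)
    corr <- correlate_with_event(traj, evw)
    base_corp <- corpus_subset(corp, period = "baseline_year")
    flagged <- traj$distances
    if (nrow(base_corp$posts) > 0) {
      bidx <- which(per[pidx] == "baseline_year")
      fbase <- list(values = feats$values[bidx, , drop = FALSE],
                    post_ids = feats$post_ids[bidx],
                    feature_names = feats$feature_names,
                    families = feats$families)
      class(fbase) <- "mind_features"
      base_traj <- tryCatch(suppressWarnings(distance_trajectory(
        fbase, base_corp, refs,
        window_days = pget(config, "converge", "window_days", 15),
        n_per_group = pget(config, "converge", "n_per_group", 1300),
        n_boot = pget(config, "converge", "n_boot", 50),
        n_neighbors = pget(config, "converge", "n_neighbors", 15),
        window = range(base_corp$posts$created_utc),
        seed = child_seed(config$seed, "converge_baseline"))),
        error = function(e) NULL)
      if (!is.null(base_traj)) {
        band <- suppressWarnings(baseline_band(base_traj))
        flagged <- flag_outside_band(traj, band)
        objects$baseline_band <- band
      }
    }
    write_convergence_outputs(flagged, corr, config$outdir)
    objects$convergence <- traj
    objects$convergence_correlation <- corr
    toc(st, "converge")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mindlang")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = config$stages,
    timings_sec = timings,
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle <- structure(list(outdir = config$outdir, manifest = manifest,
                           files = list.files(config$outdir),
                           objects = objects),
                      class = "mind_report_bundle")
  bundle
}

#' @export
print.mind_report_bundle <- function(x, ...) {
  cat("<report bundle in '", x$outdir, "': ", length(x$files), " files, ",
      x$manifest$total_sec, " s>\n", sep = "")
  invisible(x)
}
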
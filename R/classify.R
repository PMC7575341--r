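#' Per-group binary classification against a balanced control
#'
#' Each target group is classified against a control pool in which the
#' remaining groups are first equalized, with one post per author, an 80-20
#' train-test split, and optional later-period (data-set shift) and transfer
#' test sets. Linear models expose signed coefficients for the ranked
#' feature-importance tables; performance is weighted F1.
#'
#' @name classification
NULL

## one post per author, deterministic under the current RNG state
dedup_authors <- function(posts) {
  sh <- posts[sample.int(nrow(posts)), , drop = FALSE]
  sh[!duplicated(sh$author), , drop = FALSE]
}

#' Build a binary classification task
#'
#' @param corp a `mind_corpus`.
#' @param target target group label.
#' @param n_per_class posts per class (default 2700); shrunk with a warning
#'   when fewer eligible posts exist.
#' @param exclude_from_control groups never used as controls (broad groups).
#' @param train_frac training fraction of the 80-20 split.
#' @param period period(s) for the main task (default `pre_event` plus
#'   `baseline_year`); the shift set draws from `shift_period`.
#' @param shift_period later period for the data-set-shift test set.
#' @param seed RNG seed; identical seeds give identical splits.
#' @return a `mind_binary_task` with train/test post ids and labels.
#' @export
build_binary_task <- function(corp, target, n_per_class = 2700,
                              exclude_from_control = character(0),
                              train_frac = 0.8,
                              period = c("baseline_year", "pre_event"),
                              shift_period = "mid_event", seed = 1L) {
  stopifnot(inherits(corp, "mind_corpus"), target %in% corp$groups)
  ctrl_groups <- setdiff(corp$groups, c(target, exclude_from_control))
  if (length(ctrl_groups) < 2) stop("need >= 2 control groups")
  set.seed(seed)
  per <- as.character(post_periods(corp))
  main <- corp$posts[per %in% period, , drop = FALSE]
  pos <- dedup_authors(main[main$group == target, , drop = FALSE])
  if (nrow(pos) < 10) stop("target has fewer than 10 eligible authors")
  ## control pool: equalize groups first, then sample
  ctrl <- dedup_authors(main[main$group %in% ctrl_groups, , drop = FALSE])
  min_g <- min(table(factor(ctrl$group, levels = ctrl_groups)))
  pool <- do.call(rbind, lapply(ctrl_groups, function(g) {
    cg <- ctrl[ctrl$group == g, , drop = FALSE]
    cg[sample.int(nrow(cg), min_g), , drop = FALSE]
  }))
  n <- min(n_per_class, nrow(pos), nrow(pool))
  if (n < n_per_class) {
    warning("n_per_class shrunk to ", n, " (eligible posts limited)")
  }
  pos <- pos[sample.int(nrow(pos), n), , drop = FALSE]
  neg <- pool[sample.int(nrow(pool), n), , drop = FALSE]
  lab <- c(rep(1L, n), rep(0L, n))
  all_posts <- rbind(pos, neg)
  tr <- c(sample.int(n, round(train_frac * n)),
          n + sample.int(n, round(train_frac * n)))
  shift_ids <- character(0); shift_lab <- integer(0)
  if (!is.null(shift_period) && shift_period %in% names(corp$periods)) {
    sh <- corp$posts[per %in% shift_period, , drop = FALSE]
    sh <- sh[!sh$author %in% all_posts$author[tr], , drop = FALSE]
    sh <- dedup_authors(sh)
    sp <- sh[sh$group == target, , drop = FALSE]
    sn <- sh[sh$group %in% ctrl_groups, , drop = FALSE]
    m <- min(nrow(sp), nrow(sn))
    if (m >= 5) {
      sp <- sp[sample.int(nrow(sp), m), , drop = FALSE]
      sn <- sn[sample.int(nrow(sn), m), , drop = FALSE]
      shift_ids <- c(sp$id, sn$id)
      shift_lab <- c(rep(1L, m), rep(0L, m))
    }
  }
  structure(list(
    target = target,
    train_ids = all_posts$id[tr], train_labels = lab[tr],
    test_ids = all_posts$id[-tr], test_labels = lab[-tr],
    shift_ids = shift_ids, shift_labels = shift_lab,
    n_per_class = n, control_groups = ctrl_groups, seed = seed
  ), class = "mind_binary_task")
}

#' @export
print.mind_binary_task <- function(x, ...) {
  cat("<binary task '", x$target, "': ", length(x$train_ids), " train / ",
      length(x$test_ids), " test posts (n=", x$n_per_class, "/class); ",
      length(x$shift_ids), " shift posts>\n", sep = "")
  invisible(x)
}

task_matrix <- function(features, ids) {
  idx <- match(ids, features$post_ids)
  stopifnot(!anyNA(idx))
  features$values[idx, , drop = FALSE]
}

#' Train a classifier on a binary task
#'
#' Continuous features are standardized on the training data only. Model
#' kinds: `sgd_l1` (L1-regularized logistic regression, the default),
#' `sgd_elastic_net`, `linear_svm`, `extra_trees`, `gradient_boosting`.
#' Linear kinds expose one signed coefficient per feature.
#'
#' @param task a `mind_binary_task`.
#' @param features a `mind_features` covering the task's post ids.
#' @param model_kind one of the five kinds above.
#' @param reg regularization strength (lambda for the penalized linear
#'   models, cost^-1 analog for the SVM).
#' @param seed RNG seed for the stochastic kinds.
#' @return a `mind_classifier`.
#' @export
train_classifier <- function(task, features,
                             model_kind = c("sgd_l1", "sgd_elastic_net",
                                            "linear_svm", "extra_trees",
                                            "gradient_boosting"),
                             reg = 0.01, seed = 1L) {
  model_kind <- match.arg(model_kind)
  x <- task_matrix(features, task$train_ids)
  y <- task$train_labels
  if (length(unique(y)) < 2) stop("degenerate single-class training data")
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  xs <- scale(x, center = mu, scale = sd_)
  set.seed(seed)
  fit <- switch(model_kind,
    sgd_l1 = glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                            lambda = reg, standardize = FALSE),
    sgd_elastic_net = glmnet::glmnet(xs, y, family = "binomial", alpha = 0.5,
                                     lambda = reg, standardize = FALSE),
    linear_svm = e1071::svm(xs, factor(y), kernel = "linear",
                            cost = 1 / max(reg, 1e-6), scale = FALSE),
    extra_trees = ranger::ranger(
      y = factor(y), x = as.data.frame(xs), num.trees = 200,
      splitrule = "extratrees", importance = "impurity", seed = seed),
    gradient_boosting = xgboost::xgb.train(
      params = list(max_depth = 3, eta = 0.3, objective = "binary:logistic",
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(xs, label = y, nthread = 1),
      nrounds = 60, verbose = 0)
  )
  coefs <- switch(model_kind,
    sgd_l1 = ,
    sgd_elastic_net = {
      b <- as.numeric(stats::coef(fit))[-1]
      stats::setNames(b, colnames(xs))
    },
    linear_svm = {
      # decision f(x) = w.x - rho is positive for the first level ("0"),
      # so the class-1 direction is -w
      b <- -as.numeric(t(fit$coefs) %*% fit$SV)
      stats::setNames(b, colnames(xs))
    },
    NULL)
  structure(list(model_kind = model_kind, fit = fit, center = mu, scale = sd_,
                 coefficients = coefs, feature_names = colnames(x),
                 target = task$target, seed = seed),
            class = "mind_classifier")
}

#' @export
print.mind_classifier <- function(x, ...) {
  cat("<", x$model_kind, " classifier for '", x$target, "' (",
      length(x$feature_names), " features", sep = "")
  if (!is.null(x$coefficients)) {
    cat(", ", sum(x$coefficients != 0), " nonzero coefficients", sep = "")
  }
  cat(")>\n")
  invisible(x)
}

#' Predict binary labels
#'
#' @param object a `mind_classifier`.
#' @param newdata feature matrix (raw scale) or `mind_features`.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.mind_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "mind_features")) newdata$values else newdata
  xs <- scale(x[, object$feature_names, drop = FALSE],
              center = object$center, scale = object$scale)
  switch(object$model_kind,
    sgd_l1 = ,
    sgd_elastic_net = as.integer(
      stats::predict(object$fit, xs, type = "response") > 0.5),
    linear_svm = as.integer(as.character(stats::predict(object$fit, xs))),
    extra_trees = as.integer(as.character(
      stats::predict(object$fit, data = as.data.frame(xs))$predictions)),
    gradient_boosting = as.integer(
      stats::predict(object$fit,
                     xgboost::xgb.DMatrix(xs, nthread = 1)) > 0.5)
  )
}

#' Weighted F1 score
#'
#' Per-class F1 averaged with class-support weights.
#'
#' @param truth,pred 0/1 integer vectors.
#' @return weighted F1 in [0, 1].
#' @export
weighted_f1 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  if (length(unique(truth)) < 2) stop("single-class test set")
  f1_of <- function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  classes <- sort(unique(truth))
  w <- vapply(classes, function(cl) mean(truth == cl), numeric(1))
  sum(w * vapply(classes, f1_of, numeric(1)))
}

#' Evaluate a classifier on the task's test regimes
#'
#' @param model a `mind_classifier`.
#' @param task the `mind_binary_task` it was trained on.
#' @param features a `mind_features` covering all ids.
#' @return data.frame (test_set, weighted_f1, n).
#' @export
evaluate_classifier <- function(model, task, features) {
  sets <- list(held_out = list(task$test_ids, task$test_labels))
  if (length(task$shift_ids) > 0) {
    sets$shift <- list(task$shift_ids, task$shift_labels)
  }
  rows <- lapply(names(sets), function(nm) {
    ids <- sets[[nm]][[1]]; lab <- sets[[nm]][[2]]
    pred <- predict(model, task_matrix(features, ids))
    data.frame(test_set = nm, weighted_f1 = weighted_f1(lab, pred),
               n = length(ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ranked signed feature importance of a linear model
#'
#' Top `top_n` features by |coefficient| within each sign, ties broken by
#' feature name. Tree-ensemble models return unsigned importances with a
#' mode flag.
#'
#' @param model a `mind_classifier`.
#' @param top_n list length per sign.
#' @return list with `positive` and `negative` data.frames (feature,
#'   coefficient, rank) and `mode` ("signed" or "unsigned").
#' @export
rank_model_features <- function(model, top_n = 10) {
  if (is.null(model$coefficients)) {
    imp <- switch(model$model_kind,
      extra_trees = model$fit$variable.importance,
      gradient_boosting = {
        it <- xgboost::xgb.importance(model = model$fit)
        stats::setNames(it$Gain, it$Feature)
      },
      stop("no importances for kind ", model$model_kind))
    imp <- sort(imp, decreasing = TRUE)
    return(list(mode = "unsigned",
                positive = data.frame(feature = names(imp)[seq_len(min(top_n, length(imp)))],
                                      coefficient = as.numeric(imp)[seq_len(min(top_n, length(imp)))],
                                      rank = seq_len(min(top_n, length(imp))),
                                      stringsAsFactors = FALSE),
                negative = data.frame(feature = character(0),
                                      coefficient = numeric(0),
                                      rank = integer(0))))
  }
  b <- model$coefficients
  pick <- function(v) {
    if (length(v) == 0) {
      return(data.frame(feature = character(0), coefficient = numeric(0),
                        rank = integer(0)))
    }
    o <- order(-abs(v), names(v))
    k <- min(top_n, length(v))
    data.frame(feature = names(v)[o][seq_len(k)],
               coefficient = as.numeric(v)[o][seq_len(k)],
               rank = seq_len(k), stringsAsFactors = FALSE)
  }
  list(mode = "signed",
       positive = pick(b[b > 0]),
       negative = pick(b[b < 0]))
}

#' Apply a bank of binary classifiers to a post set
#'
#' For each classifier, the fraction of the posts it predicts positive
#' (independent binary models: proportions need not sum to 1).
#'
#' @param models named list of `mind_classifier` objects.
#' @param features a `mind_features`.
#' @param ids post ids to score (default: all rows of `features`).
#' @return named numeric vector of detection proportions.
#' @export
apply_classifiers_to_group <- function(models, features, ids = features$post_ids) {
  stopifnot(length(ids) > 0)
  x <- task_matrix(features, ids)
  vapply(models, function(m) mean(predict(m, x) == 1L), numeric(1))
}
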
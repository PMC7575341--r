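#' Post corpora
#'
#' A corpus is a table of timestamped, author- and group-labeled free-text
#' posts together with a registry of group labels and a set of named,
#' non-overlapping analysis periods (`baseline_year`, `pre_event`,
#' `mid_event`). The on-disk interchange format is JSON lines: one post per
#' line with fields `id`, `author`, `group`, `created_utc` (ISO-8601 date)
#' and `text`, UTF-8.
#'
#' @name corpus
NULL

#' Construct a corpus
#'
#' @param posts data.frame with columns `id`, `author`, `group`,
#'   `created_utc` (Date or ISO-8601 string), `text`.
#' @param periods named list of length-2 Date vectors (start, end),
#'   inclusive, non-overlapping.
#' @param groups group registry; defaults to the groups present.
#' @return a `mind_corpus`.
#' @export
corpus <- function(posts, periods, groups = sort(unique(posts$group))) {
  need <- c("id", "author", "group", "created_utc", "text")
  stopifnot(is.data.frame(posts), all(need %in% names(posts)))
  posts <- posts[, need]
  posts$created_utc <- as.Date(posts$created_utc)
  if (anyNA(posts$created_utc)) stop("unparseable created_utc dates")
  if (any(!nzchar(posts$text))) stop("empty post text")
  if (anyDuplicated(posts$id)) stop("duplicate post ids")
  if (!all(posts$group %in% groups)) stop("unregistered group label")
  periods <- lapply(periods, as.Date)
  stopifnot(length(names(periods)) == length(periods))
  ord <- order(vapply(periods, function(p) as.numeric(p[1]), numeric(1)))
  pp <- periods[ord]
  for (i in seq_along(pp)) {
    if (pp[[i]][2] < pp[[i]][1]) stop("period end before start: ", names(pp)[i])
    if (i > 1 && pp[[i]][1] <= pp[[i - 1]][2]) stop("overlapping periods")
  }
  structure(list(posts = posts, groups = groups, periods = periods),
            class = "mind_corpus")
}

#' Period label of every post
#'
#' @param x a `mind_corpus`.
#' @return factor with one level per declared period plus `NA` for posts
#'   outside all periods.
#' @export
post_periods <- function(x) {
  stopifnot(inherits(x, "mind_corpus"))
  d <- x$posts$created_utc
  lab <- rep(NA_character_, length(d))
  for (nm in names(x$periods)) {
    p <- x$periods[[nm]]
    lab[d >= p[1] & d <= p[2]] <- nm
  }
  factor(lab, levels = names(x$periods))
}

#' Subset a corpus by period and/or groups
#'
#' @param x a `mind_corpus`.
#' @param period period name, or NULL for all.
#' @param groups group labels, or NULL for all.
#' @return a `mind_corpus` with the same period declarations.
#' @export
corpus_subset <- function(x, period = NULL, groups = NULL) {
  keep <- rep(TRUE, nrow(x$posts))
  if (!is.null(period)) keep <- keep & (as.character(post_periods(x)) %in% period)
  if (!is.null(groups)) keep <- keep & (x$posts$group %in% groups)
  corpus(x$posts[keep, , drop = FALSE], x$periods, x$groups)
}

#' @export
print.mind_corpus <- function(x, ...) {
  cat("<corpus: ", nrow(x$posts), " posts, ", length(x$groups), " groups, ",
      length(x$periods), " periods (",
      paste(names(x$periods), collapse = ", "), ")>\n", sep = "")
  invisible(x)
}

#' @export
summary.mind_corpus <- function(object, ...) {
  tab <- table(group = object$posts$group, period = post_periods(object))
  print(object)
  print(tab)
  invisible(tab)
}

#' Write a corpus as JSON lines
#'
#' @param x a `mind_corpus`.
#' @param path output file; a sidecar `<path>.periods.json` stores the
#'   period declarations.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "mind_corpus"))
  df <- x$posts
  df$created_utc <- format(df$created_utc)
  lines <- vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  meta <- list(groups = x$groups,
               periods = lapply(x$periods, function(p) format(p)))
  jsonlite::write_json(meta, paste0(path, ".periods.json"), auto_unbox = FALSE)
  invisible(path)
}

#' Load a corpus from JSON lines
#'
#' Malformed lines (unparseable JSON or missing fields) are counted and
#' reported; more than `max_malformed_frac` of them is an error. Posts dated
#' outside every declared period are kept but produce a warning.
#'
#' @param path JSON-lines file written by [write_corpus()] (or compatible).
#' @param periods named list of period date windows; defaults to the sidecar
#'   file if present.
#' @param max_malformed_frac tolerated fraction of malformed lines.
#' @return a `mind_corpus`.
#' @export
load_corpus <- function(path, periods = NULL, max_malformed_frac = 0.01) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  need <- c("id", "author", "group", "created_utc", "text")
  rows <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || !all(need %in% names(rec)) ||
        !nzchar(as.character(rec$text %||% ""))) {
      bad <- bad + 1L
    } else {
      rows[[i]] <- rec[need]
    }
  }
  if (bad > 0) message(bad, " malformed line(s) skipped")
  if (bad > max_malformed_frac * length(lines)) {
    stop("too many malformed lines: ", bad, " of ", length(lines))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  posts <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = as.character(r$id), author = as.character(r$author),
               group = as.character(r$group),
               created_utc = as.character(r$created_utc),
               text = as.character(r$text), stringsAsFactors = FALSE)
  }))
  if (is.null(periods)) {
    side <- paste0(path, ".periods.json")
    if (file.exists(side)) {
      meta <- jsonlite::read_json(side, simplifyVector = TRUE)
      periods <- lapply(meta$periods, as.Date)
    } else {
      rng <- range(as.Date(posts$created_utc))
      periods <- list(all = rng)
    }
  }
  out <- corpus(posts, periods)
  if (anyNA(post_periods(out))) {
    warning(sum(is.na(post_periods(out))),
            " post(s) dated outside every declared period")
  }
  out
}
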
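#' Statistical primitives for the surveillance pipeline
#'
#' Self-contained implementations of the rank and enrichment tests used by the
#' trend, clustering and topic stages. Small samples use exact enumeration;
#' larger samples fall back to standard approximations at documented
#' thresholds. Degenerate inputs are always flagged, never returned as NaN.
#'
#' @name stats-core
NULL

new_test_result <- function(statistic, p, method, n, degenerate = FALSE,
                            estimate = NULL, note = NULL) {
  stopifnot(is.finite(p), p >= 0, p <= 1 + 1e-12)
  out <- list(statistic = statistic, p = min(p, 1), method = method, n = n,
              degenerate = degenerate, estimate = estimate, note = note)
  class(out) <- "mind_test"
  out
}

#' @export
print.mind_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic), "  p =", format.pval(x$p), "\n")
  if (!is.null(x$estimate)) cat("  estimate =", format(x$estimate), "\n")
  if (x$degenerate) cat("  [degenerate:", x$note %||% "flat input", "]\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR control: order the m p-values, find the largest rank i
#' with p_(i) <= alpha * i / m, and reject all hypotheses at or below it.
#' Returned q-values are the usual monotone cumulative minima so that
#' `reject == (q <= alpha)`.
#'
#' @param p numeric vector of p-values in [0,1].
#' @param alpha target false-discovery rate (default 0.05).
#' @return list with `q` (adjusted values, same order as input) and `reject`
#'   (logical vector).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  m <- length(p)
  if (m == 0L) return(list(q = numeric(0), reject = logical(0)))
  ok <- !is.na(p)
  q <- rep(NA_real_, m)
  if (any(ok)) {
    pv <- p[ok]
    mm <- length(pv)
    o <- order(pv)
    ro <- order(o)
    # step-up: running minimum taken from the largest rank downwards
    qv <- rev(cummin(rev(pv[o] * mm / seq_len(mm))))
    q[ok] <- pmin(1, qv)[ro]
  }
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Bonferroni adjustment
#'
#' @param p numeric vector of p-values.
#' @param m family size; defaults to `length(p)`.
#' @return adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)), m >= 1)
  pmin(1, m * p)
}

## midranks of a numeric vector
midrank <- function(x) rank(x, ties.method = "average")

#' Mann-Whitney U / Wilcoxon rank-sum test
#'
#' Two-sided test on two independent samples with midrank tie handling. For
#' combined n <= `exact_max` the null distribution is obtained by exact
#' enumeration over all group labelings of the pooled sample; above that a
#' normal approximation with tie correction (and 0.5 continuity correction)
#' is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max largest combined sample size for exact enumeration.
#' @return a `mind_test` with the U statistic of sample `a`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(new_test_result(n1 * n2 / 2, 1, "Mann-Whitney U", c(n1, n2),
                           degenerate = TRUE, note = "all values identical"))
  }
  r <- midrank(pooled)
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= u_a + eps), mean(u_all >= u_a - eps))
    p <- min(1, p)
    method <- "Mann-Whitney U (exact)"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Mann-Whitney U (normal approx)"
  }
  new_test_result(u_a, p, method, c(n1, n2))
}

#' @rdname mann_whitney_u
#' @export
wilcoxon_rank_sum <- mann_whitney_u

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (standard practice). For n <= `exact_max`
#' nonzero differences the two-sided p-value is exact, obtained by
#' enumerating all 2^n sign patterns of the midranks of |d|; above that a
#' normal approximation with tie correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest n for exact enumeration.
#' @return a `mind_test` with statistic W+ (sum of positive-sign ranks).
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 15L) {
  stopifnot(length(d) >= 1)
  d <- d[is.finite(d)]
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(new_test_result(0, 1, "Wilcoxon signed-rank", 0,
                           degenerate = TRUE, note = "all differences zero"))
  }
  n <- length(d)
  r <- midrank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    # enumerate sign patterns via subset sums of the rank vector
    w_all <- 0
    for (ri in r) w_all <- c(w_all, w_all + ri)  # 2^n subset sums
    eps <- 1e-9
    p <- 2 * min(mean(w_all <= w_pos + eps), mean(w_all >= w_pos - eps))
    p <- min(1, p)
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank (normal approx)"
  }
  new_test_result(w_pos, p, method, n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. For n <= `exact_max` the two-sided
#' p-value is exact by enumerating all permutations of one rank vector;
#' otherwise the t approximation t = rho * sqrt((n-2)/(1-rho^2)) is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_max largest n for the exact permutation p-value.
#' @return a `mind_test` with `estimate` rho.
#' @export
spearman_rho <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(new_test_result(NA_real_, 1, "Spearman rho", n,
                           degenerate = TRUE, note = "zero variance"))
  }
  rx <- midrank(x); ry <- midrank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permute_all(n)
    rhos <- apply(perms, 1, function(pp) stats::cor(rx, ry[pp]))
    eps <- 1e-9
    p <- mean(abs(rhos) >= abs(rho) - eps)
    method <- "Spearman rho (exact permutation)"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "Spearman rho (t approx)"
  }
  new_test_result(rho, min(1, p), method, n, estimate = rho)
}

## all permutations of 1..n as an (n!)-row matrix; n <= 8 only
permute_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permute_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing at least `k` successes when drawing `n`
#' items without replacement from a population of `N` containing `K`
#' successes. This is the enrichment p-value used for cluster-group tables.
#'
#' @param N population size.
#' @param K number of successes in the population.
#' @param n number of draws.
#' @param k observed successes.
#' @return p = P(X >= k), exact.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0, K <= N, n <= N, k <= min(K, n))
  if (k == 0) return(1)
  j <- k:min(K, n)
  lo <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  min(1, sum(exp(lo)))
}
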
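# Exact enumeration oracles, independent of the stats implementations.

## Mann-Whitney U two-sided p by brute force over all group labelings
oracle_mw <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

## Wilcoxon signed-rank two-sided p over all 2^n sign patterns
oracle_wsr <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

## all permutations (n <= 6 for the oracle sweep)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}

## Spearman exact two-sided p by full permutation of y
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  pm <- oracle_perms(length(y))
  rhos <- apply(pm, 1, function(pp) stats::cor(rx, ry[pp]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

## hypergeometric upper tail by direct combinatorial sum
oracle_hyper <- function(N, K, n, k) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## BH rejections by explicitly checking every step-up threshold
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  passing <- which(p[o] <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(passing)) rej[o[seq_len(max(passing))]] <- TRUE
  rej
}
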
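# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.

# Benjamini-Hochberg step-up, written directly from the definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      k <- sum(p <= p[j])              # rank of p_j (max rank under ties)
      m * p[j] / k
    }, numeric(1))
    min(1, min(cand[p >= p[i]]))
  }, numeric(1))
}

# doubly trimmed mean of M-values between two samples, by explicit
# sort-and-drop on both M and A
tmm_oracle_pair <- function(x, r, trim_m = 0.3, trim_a = 0.05) {
  nx <- sum(x); nr <- sum(r)
  keep <- x > 0 & r > 0
  m <- log2((x[keep] / nx) / (r[keep] / nr))
  a <- 0.5 * log2((x[keep] / nx) * (r[keep] / nr))
  n <- length(m)
  drop_m <- floor(n * trim_m)
  drop_a <- floor(n * trim_a)
  ord_m <- order(m)
  in_m <- seq_len(n) %in% ord_m[(drop_m + 1):(n - drop_m)]
  ord_a <- order(a)
  in_a <- seq_len(n) %in% ord_a[(drop_a + 1):(n - drop_a)]
  2^mean(m[in_m & in_a])
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% rk
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# exact two-sided rank-sum p by enumeration of all group assignments
rank_sum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(nx)])
  combos <- utils::combn(n, nx)
  w_all <- apply(combos, 2, function(idx) sum(rk[idx]))
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# exact two-sided McNemar p by direct enumeration of the Binomial(n, 1/2)
# distribution of the discordant count
mcnemar_oracle <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  probs <- vapply(0:n, function(k) choose(n, k) * 0.5^n, numeric(1))
  k <- min(b, c)
  min(1, 2 * sum(probs[seq_len(k + 1)]))
}

# adjusted Rand index from the contingency table (direct formula)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
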
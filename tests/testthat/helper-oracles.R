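# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (grid search, full enumeration) and share no code
# with the implementation paths they check.

# exhaustive maximization of the joint BS/oxBS binomial log-likelihood
# over a grid of total modification t = p_m + p_h (step `step`); for each
# t the inner maximum over p_m <= t is at min(k_ox/n_ox, t) because the
# binomial log-likelihood is strictly concave in p_m.
oracle_mlml_grid <- function(k_bs, n_bs, k_ox, n_ox, step = 1e-3) {
  t <- seq(0, 1, by = step)
  m <- pmin(t, k_ox / n_ox)
  tt <- pmin(pmax(t, 1e-12), 1 - 1e-12)
  mm <- pmin(pmax(m, 1e-12), 1 - 1e-12)
  ll <- k_bs * log(tt) + (n_bs - k_bs) * log(1 - tt) +
    k_ox * log(mm) + (n_ox - k_ox) * log(1 - mm)
  i <- which.max(ll)
  c(p_m = m[i], p_h = t[i] - m[i])
}

# full 2D grid (coarser), used to validate the profile trick itself
oracle_mlml_grid2d <- function(k_bs, n_bs, k_ox, n_ox, step = 2e-3) {
  pm <- seq(0, 1, by = step)
  best <- c(-Inf, 0, 0)
  for (m in pm) {
    ph <- seq(0, 1 - m, by = step)
    t <- pmin(pmax(m + ph, 1e-12), 1 - 1e-12)
    mm <- min(max(m, 1e-12), 1 - 1e-12)
    ll <- k_bs * log(t) + (n_bs - k_bs) * log(1 - t) +
      k_ox * log(mm) + (n_ox - k_ox) * log(1 - mm)
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], m, ph[i])
  }
  c(p_m = best[2], p_h = best[3])
}

# exact two-sided Mann-Whitney p by complete enumeration of all
# C(m+n, m) group assignments of the observed values (ties via average
# ranks, p = 2 * min(P(W <= w), P(W >= w)) capped at 1)
oracle_mwu_enum <- function(x, y) {
  m <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(m)])
  splits <- utils::combn(length(vals), m)
  w_all <- apply(splits, 2, function(ix) sum(r[ix]))
  tol <- 1e-9
  p_le <- mean(w_all <= w_obs + tol)
  p_ge <- mean(w_all >= w_obs - tol)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher exact p for a 2x2 table by explicit hypergeometric
# enumeration: sum the probabilities of all tables (same margins) whose
# probability does not exceed the observed one
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  kk <- max(0, c1 - (N - r1)):min(r1, c1)
  logp <- lchoose(r1, kk) + lchoose(N - r1, c1 - kk) - lchoose(N, c1)
  p <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(N - r1, c1 - a) - lchoose(N, c1))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# best contiguous interval by exhaustive scan: over all [i, j] windows of
# at least `min_cpg` sites, the one maximizing |mean delta|
oracle_best_interval <- function(d, min_cpg) {
  n <- length(d)
  best <- c(score = -Inf, lo = NA, hi = NA)
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1L < min_cpg) next
    s <- abs(mean(d[i:j]))
    if (s > best["score"]) best <- c(score = s, lo = i, hi = j)
  }
  best
}
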
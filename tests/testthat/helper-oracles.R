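# Independent brute-force oracles. These deliberately avoid the package's
# code paths: rank statistics are enumerated from first principles.

# Exact two-sided rank-sum p by enumerating every split of the pooled data.
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- combn(n, na)
  w_all <- apply(splits, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  pl <- mean(w_all <= w_obs + 1e-12)
  pu <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(pl, pu))
}

# Exact two-sided permutation p for a two-sample statistic.
oracle_permutation_p <- function(a, b, stat = function(x, y) median(x) - median(y)) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  obs <- abs(stat(a, b))
  splits <- combn(n, na)
  s_all <- apply(splits, 2, function(ix) abs(stat(pooled[ix], pooled[-ix])))
  mean(s_all >= obs - 1e-12)
}

# Kruskal-Wallis H from the definition (midranks, tie correction).
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Walk seconds in [t0, t0 + cut) by direct per-sample counting on a trace,
# given a per-sample walking flag.
oracle_walk_seconds <- function(walk_flags, dt, i0, cut_samples) {
  idx <- seq(i0, min(i0 + cut_samples - 1, length(walk_flags)))
  sum(walk_flags[idx]) * dt
}
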
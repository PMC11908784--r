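# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: numerical integration instead of log-gamma
# identities, enumeration instead of closed forms.

# beta-binomial pmf by numerical integration over the mixing density
bb_pmf_integrate <- function(x, n, mu, rho) {
  s <- 1 / rho - 1
  a <- mu * s; b <- (1 - mu) * s
  choose(n, x) * stats::integrate(
    function(p) p^x * (1 - p)^(n - x) * stats::dbeta(p, a, b),
    0, 1, rel.tol = 1e-13, abs.tol = 0)$value
}

# BH step-up by its definition: q_i = min over ranks j with p_(j) >= p_i
# of m * p_(j) / j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  q[order(o)]
}

# closed-form binomial likelihood-ratio statistic (one-sided handled by
# the caller)
binom_lrt_lambda <- function(x, n, xs, ns) {
  clamp <- function(p) min(max(p, 1e-8), 1 - 1e-8)
  mu0 <- clamp((x + sum(xs)) / (n + sum(ns)))
  mut <- clamp(x / n)
  mub <- clamp(sum(xs) / sum(ns))
  ll_alt <- dbinom(x, n, mut, log = TRUE) +
    sum(dbinom(xs, ns, mub, log = TRUE))
  ll_null <- dbinom(x, n, mu0, log = TRUE) +
    sum(dbinom(xs, ns, mu0, log = TRUE))
  max(0, 2 * (ll_alt - ll_null))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
# (no ties)
mw_exact_enum <- function(x, y) {
  v <- c(x, y)
  stopifnot(!anyDuplicated(v))
  n1 <- length(x)
  idx <- utils::combn(length(v), n1)
  ustat <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- ustat(x, y)
  us <- apply(idx, 2, function(i) ustat(v[i], v[-i]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# upper-tail hypergeometric by direct enumeration
hyper_tail_enum <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
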
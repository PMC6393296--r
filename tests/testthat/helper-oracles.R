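# Independent oracles used across the suite. These deliberately take the
# slowest, most literal route (double loops, grid enumeration, direct
# likelihood maximization) so they share no code with the implementation.

# MSD by direct double-loop evaluation of the defining average.
msd_brute <- function(y, n_max) {
  N <- length(y)
  vapply(seq_len(n_max), function(n) {
    acc <- 0
    for (i in seq_len(N - n)) acc <- acc + (y[i + n] - y[i])^2
    acc / (N - n)
  }, 1)
}

# Two-sample K-S statistic by enumerating the pooled ECDF breakpoints.
ks_stat_brute <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), 1)
  fy <- vapply(grid, function(g) mean(y <= g), 1)
  max(abs(fx - fy))
}

# Wald p-value for the group coefficient of a binomial logit model,
# by direct maximization of the log-likelihood with a numerical Hessian.
logistic_wald_brute <- function(k1, n1, k2, n2) {
  nll <- function(b) {
    p1 <- stats::plogis(b[1])
    p2 <- stats::plogis(b[1] + b[2])
    -(k1 * log(p1) + (n1 - k1) * log(1 - p1) +
        k2 * log(p2) + (n2 - k2) * log(1 - p2))
  }
  opt <- stats::optim(c(0, 0), nll, hessian = TRUE, method = "BFGS")
  se <- sqrt(diag(solve(opt$hessian)))[2]
  z <- opt$par[2] / se
  2 * stats::pnorm(-abs(z))
}

# Direct generation-by-generation birth process with mutation at each
# division: the brute-force counterpart of the Luria-Delbruck generator.
ld_birth_process <- function(n_cultures, generations, mu) {
  counts <- integer(n_cultures)
  for (j in seq_len(n_cultures)) {
    wt <- 1; mut <- 0
    for (k in seq_len(generations)) {
      new_mut <- stats::rbinom(1L, wt, mu)
      mut <- 2 * mut + new_mut
      wt <- 2 * wt - new_mut
    }
    counts[j] <- mut
  }
  counts
}

# Bisection to 10+ significant figures on g(mu) = mu*ln(n*mu) - f.
drake_bisect <- function(f, n, lo = NULL, hi = NULL) {
  g <- function(mu) mu * log(n * mu) - f
  if (is.null(lo)) lo <- (1 + 1e-9) / n
  if (is.null(hi)) { hi <- max(f, exp(1) / n); while (g(hi) < 0) hi <- 2 * hi }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Build a short noiseless trajectory around a zone for hand-traced cases.
zone_trajectory <- function(offsets, center = 1, dt = 0.05) {
  trajectory(center + offsets, frame_interval = dt)
}
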
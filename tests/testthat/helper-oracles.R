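# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the survival package) so that agreement is
# evidence, not tautology.

# Explicit Cox partial log-likelihood for untied data, one covariate:
# pl(beta) = sum_{i: event} [ x_i beta - log sum_{j: t_j >= t_i} exp(x_j beta) ]
cox_partial_loglik <- function(beta, times, events, x) {
  s <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    s <- s + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  s
}

# Brute-force maximizer of the partial likelihood over a bounded interval
cox_oracle_beta <- function(times, events, x, lower = -8, upper = 8) {
  stats::optimize(function(b) cox_partial_loglik(b, times, events, x),
                  interval = c(lower, upper), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Exhaustive-permutation two-sided p for the Wilcoxon rank-sum statistic
# (no ties). Enumerates every assignment of the pooled ranks to group x.
wilcoxon_perm_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(x)
  obs <- sum(r[seq_len(n)])
  idx <- utils::combn(length(pooled), n)
  stats_all <- colSums(matrix(r[idx], nrow = n))
  center <- n * (length(pooled) + 1) / 2
  mean(abs(stats_all - center) >= abs(obs - center))
}

# Small no-tie survival datasets for oracle-equivalence checks. A continuous
# covariate keeps monotone-likelihood (perfectly separable) draws rare; the
# caller still guards on convergence because tiny n can separate by chance.
make_small_cox_data <- function(n, seed) {
  set.seed(seed)
  repeat {
    times <- round(stats::rexp(n, 0.5), 3)
    if (anyDuplicated(times) == 0) break
  }
  events <- stats::rbinom(n, 1, 0.8)
  if (sum(events) == 0) events[1] <- 1L
  x <- round(stats::rnorm(n), 3)
  list(times = times, events = events, x = x)
}
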
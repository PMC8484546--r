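# Independent oracles used by the acceptance-style tests.

# Posterior mean of m by dense-grid quadrature over (m, A) with sigma_A^2
# fixed, for very small designs. Entirely independent of the MCMC code path:
# it evaluates the Bernoulli-logit likelihood and the normal priors directly
# on a tensor grid and normalises numerically.
grid_posterior_mean_m <- function(design, sigma2, m_var,
                                  m_grid = seq(-6, 6, by = 0.1),
                                  A_grid = seq(-4, 4, by = 0.5)) {
  n_act <- nrow(design$actors)
  stopifnot(n_act <= 5, ncol(design$X) == 0)
  d <- design$dyads
  A_comb <- as.matrix(expand.grid(rep(list(A_grid), n_act)))
  log_prior_A <- rowSums(dnorm(A_comb, 0, sqrt(sigma2), log = TRUE))
  # actor-effect sum per dyad, over all grid combinations
  re_sum <- sapply(seq_len(nrow(d)), function(r) {
    A_comb[, d$slot_i[r]] + A_comb[, d$slot_j[r]]
  })
  num <- 0
  den <- 0
  for (m in m_grid) {
    mu <- m + re_sum                     # (combinations x dyads)
    # log(1 - p), then add mu where y = 1 to get log p
    ll <- ifelse(mu > 0, -mu - log1p(exp(-mu)), -log1p(exp(mu)))
    if (any(d$y == 1)) {
      ll[, d$y == 1] <- ll[, d$y == 1] + mu[, d$y == 1, drop = FALSE]
    }
    logw <- rowSums(ll) + log_prior_A + dnorm(m, 0, sqrt(m_var), log = TRUE)
    w <- sum(exp(logw))
    num <- num + m * w
    den <- den + w
  }
  num / den
}
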
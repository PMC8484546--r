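# b2 likelihood, posterior, MAP and posterior summaries.

test_that("log-likelihood matches closed forms and a dbinom oracle", {
  d6 <- toy_design(n = 4, seed = 1, two_networks = FALSE)  # 6 dyads
  p0 <- b2_params(m = 0, sigma_A2 = 0, A = rep(0, 4))
  expect_equal(b2_loglik(p0, d6), -6 * log(2))

  # single dyad, y = 1, m = ln 3: P(edge) = 0.75
  one <- d6
  one$dyads <- one$dyads[1, , drop = FALSE]
  one$dyads$y <- 1L
  one$X <- one$X[1, , drop = FALSE]
  expect_equal(b2_loglik(b2_params(m = log(3), sigma_A2 = 0), one),
               log(0.75), tolerance = 1e-12)
  expect_gt(b2_loglik(b2_params(m = 1, sigma_A2 = 0), one),
            b2_loglik(b2_params(m = 0, sigma_A2 = 0), one))

  # general oracle: independent Bernoulli log densities via dbinom
  set.seed(4)
  d <- toy_design(n = 6, seed = 4, m = -0.4, sigma_A2 = 0.5)
  for (i in 1:5) {
    par <- b2_params(m = rnorm(1), beta_a = rnorm(1), sigma_A2 = 1,
                     A = rnorm(nrow(d$actors), 0, 0.7))
    mu <- par$m + as.vector(d$X %*% par$beta_a) +
      par$A[d$dyads$slot_i] + par$A[d$dyads$slot_j]
    expect_equal(b2_loglik(par, d),
                 sum(dbinom(d$dyads$y, 1, plogis(mu), log = TRUE)))
  }
})

test_that("log-likelihood is stable at extreme linear predictors", {
  d <- toy_design(n = 3, seed = 2, two_networks = FALSE)
  ll <- b2_loglik(b2_params(m = 700, sigma_A2 = 0), d)
  expect_true(is.finite(ll))
  ll2 <- b2_loglik(b2_params(m = -700, sigma_A2 = 0), d)
  expect_true(is.finite(ll2))
})

test_that("likelihood is invariant under swapping i and j within dyads", {
  set.seed(8)
  d <- toy_design(n = 6, seed = 8, m = -0.3, sigma_A2 = 0.5)
  par <- b2_params(m = -0.2, beta_a = 0.4, sigma_A2 = 1,
                   A = rnorm(nrow(d$actors), 0, 0.5))
  swapped <- d
  flip <- seq(1, nrow(d$dyads), by = 2)
  tmp <- swapped$dyads$slot_i[flip]
  swapped$dyads$slot_i[flip] <- swapped$dyads$slot_j[flip]
  swapped$dyads$slot_j[flip] <- tmp
  expect_equal(b2_loglik(par, swapped), b2_loglik(par, d))
})

test_that("log-posterior adds the stated prior and random-effect terms", {
  d <- toy_design(n = 4, seed = 3, two_networks = FALSE)
  n_act <- nrow(d$actors)

  # flat priors: only likelihood + random-effect normal terms remain
  parA <- b2_params(m = 0.3, sigma_A2 = 1, A = rnorm(n_act, 0, 0.4))
  expect_equal(b2_logposterior(parA, d, b2_priors(flat = TRUE)),
               b2_loglik(parA, d) + sum(dnorm(parA$A, 0, 1, log = TRUE)))

  # A = 0, sigma^2 = 1: random-effect term is -(n/2) log(2*pi)
  par0 <- b2_params(m = 0, sigma_A2 = 1, A = rep(0, n_act))
  expect_equal(b2_logposterior(par0, d, b2_priors(flat = TRUE)),
               b2_loglik(par0, d) - n_act / 2 * log(2 * pi))

  # degenerate: sigma^2 = 0 with nonzero A is rejected
  bad <- b2_params(m = 0, sigma_A2 = 0, A = c(0.1, rep(0, n_act - 1)))
  expect_equal(b2_logposterior(bad, d, b2_priors()), -Inf)

  # informative priors enter as normal log densities
  pr <- b2_priors(m_var = 4)
  expect_equal(b2_logposterior(par0, d, pr) -
                 b2_logposterior(par0, d, b2_priors(flat = TRUE)),
               dnorm(0, 0, 2, log = TRUE) + log_sinvchisq_ref(1, 1, 1))
})

test_that("sinv-chi^2 prior density integrates to 1", {
  f <- function(s2) exp(log_sinvchisq_ref(s2, 1, 1))
  expect_equal(integrate(f, 0, Inf)$value, 1, tolerance = 1e-5)
})

test_that("flat-prior MAP with sigma^2 = 0 equals the glm MLE", {
  set.seed(21)
  d <- toy_design(n = 15, seed = 21, m = -0.5, sigma_A2 = 0)
  map <- b2_map(d, b2_priors(flat = TRUE))
  ref <- glm(d$dyads$y ~ d$X[, 1], family = binomial())
  expect_equal(map$m, unname(coef(ref)[1]), tolerance = 1e-5)
  expect_equal(unname(map$beta_a), unname(coef(ref)[2]), tolerance = 1e-5)
})

test_that("the sampler is bit-reproducible given a seed", {
  d <- toy_design(n = 8, seed = 6, m = -0.5, sigma_A2 = 0.3)
  st <- b2_settings(n_chains = 2, n_iter = 400, burn_in = 100, thin = 2,
                    seed = 99)
  f1 <- fit_b2_mcmc(d, settings = st)
  f2 <- fit_b2_mcmc(d, settings = st)
  expect_identical(f1$draws, f2$draws)
  # a different seed gives different draws
  f3 <- fit_b2_mcmc(d, settings = b2_settings(n_chains = 2, n_iter = 400,
                                              burn_in = 100, thin = 2,
                                              seed = 100))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("with sigma^2 fixed at 0 the posterior mean of m tracks the MLE", {
  set.seed(31)
  sim <- simulate_b2_network(40, m = 0, sigma_A2 = 0, k = 1)
  d <- dyad_design(sim$network)
  fit <- fit_b2_mcmc(d, priors = b2_priors(flat = TRUE),
                     settings = b2_settings(n_chains = 2, n_iter = 3000,
                                            burn_in = 500, thin = 1,
                                            seed = 5),
                     fix_sigma2 = 0)
  mle <- qlogis(mean(d$dyads$y))
  m_hat <- mean(do.call(rbind, fit$draws)[, "m"])
  mcse <- mcse_mean(fit, "m")
  expect_lt(abs(m_hat - mle), 4 * mcse + 0.01)
  # density 0.5 truth: m near 0
  expect_lt(abs(m_hat), 0.15)
  # sigma is not sampled
  expect_true(all(do.call(rbind, fit$draws)[, "sigma_A2"] == 0))
})

test_that("swapping the reference network inverts the odds ratio", {
  set.seed(41)
  a <- simulate_b2_network(35, m = -1.5, sigma_A2 = 0.3, k = 1)$network
  b <- simulate_b2_network(35, m = -0.7, sigma_A2 = 0.3, k = 2)$network
  st <- b2_settings(n_chains = 2, n_iter = 4000, burn_in = 1500, thin = 2,
                    seed = 13)
  or_ab <- or_summary(fit_b2_mcmc(dyad_design(a, b), settings = st))
  or_ba <- or_summary(fit_b2_mcmc(dyad_design(b, a), settings = st))
  expect_equal(or_ab$or_point * or_ba$or_point, 1, tolerance = 0.08)
})

test_that("or_summary reports the posterior mean of exp(beta)", {
  mk_fit <- function(beta) {
    structure(list(draws = list(cbind(m = 0 * beta, condition = beta,
                                      sigma_A2 = 1 + 0 * beta))),
              class = "b2_fit")
  }
  # degenerate draws
  s <- or_summary(mk_fit(rep(log(2), 50)))
  expect_equal(c(s$or_point, s$ci_low, s$ci_high), c(2, 2, 2))
  # two-point draws: mean of exp, not exp of mean
  s2 <- or_summary(mk_fit(rep(c(0, log(2)), 50)))
  expect_equal(s2$or_point, 1.5)
  # no covariate draws is an error
  no_beta <- structure(list(draws = list(cbind(m = rnorm(10),
                                               sigma_A2 = rep(1, 10)))),
                       class = "b2_fit")
  expect_error(or_summary(no_beta), "no covariate draws")
})

test_that("diagnostics flag degenerate and diverged chains, pass healthy ones", {
  const <- list(cbind(m = rep(1, 100)), cbind(m = rep(1, 100)))
  dg <- mcmc_diagnostics(const)
  expect_true(dg$flagged)

  set.seed(2)
  diverged <- list(cbind(m = rnorm(200, 0)), cbind(m = rnorm(200, 10)))
  dd <- mcmc_diagnostics(diverged)
  expect_gt(dd$rhat, 3)
  expect_true(dd$flagged)

  healthy <- list(cbind(m = rnorm(2000)), cbind(m = rnorm(2000)))
  dh <- mcmc_diagnostics(healthy)
  expect_lt(abs(dh$rhat - 1), 0.02)
  expect_false(dh$flagged)
  expect_gt(dh$ess, 1000)

  expect_warning(mcmc_diagnostics(healthy[1]), "2 chains")
})

test_that("initialization failures are reported as such", {
  d <- toy_design(n = 4, seed = 1, two_networks = FALSE)
  d$dyads <- d$dyads[0, , drop = FALSE]
  expect_error(fit_b2_mcmc(d), "empty dyad design")
})
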
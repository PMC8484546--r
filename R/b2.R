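# The b2 model: Bayesian logistic regression for undirected dyadic network
# data. For dyad (i, j) in network k,
#
#   P(Y_kij = 1) = exp(mu_kij) / (1 + exp(mu_kij))
#   mu_kij = m + Xa_kij * beta_a + A_ki + A_kj,   A_ki ~ N(0, sigma_A^2)
#
# i.e. the undirected reduction of the multilevel p2 model: no reciprocity,
# no dyadic predictors, no network-level random effects, and identical
# sender/receiver effects. Estimation is Metropolis-within-Gibbs with
# adaptive random-walk proposals (adaptation frozen after burn-in) and a
# conjugate scaled inverse-chi^2 Gibbs step for sigma_A^2.

#' Prior specification for the b2 model
#'
#' Weakly informative defaults on the logit scale: `m` and `beta_a` are
#' normal with variance 100; `sigma_A^2` has a scaled inverse-chi-squared
#' prior with `nu0` degrees of freedom and scale `s02`. `flat = TRUE` gives
#' improper flat priors on `m`, `beta_a` and `sigma_A^2` (the random-effect
#' normal terms remain), mainly useful for checking the sampler against
#' maximum-likelihood limits.
#'
#' @param m_mean,m_var Normal prior mean/variance for the overall mean `m`.
#' @param beta_mean,beta_var Normal prior mean/variance for each covariate
#'   coefficient.
#' @param nu0,s02 Scaled inverse-chi-squared prior for `sigma_A^2`; `nu0 = 0`
#'   means a flat prior on `sigma_A^2`.
#' @param flat Shortcut setting all location priors flat and `nu0 = 0`.
#' @return A `b2_priors` list.
#' @export
b2_priors <- function(m_mean = 0, m_var = 100,
                      beta_mean = 0, beta_var = 100,
                      nu0 = 1, s02 = 1, flat = FALSE) {
  if (flat) {
    m_var <- Inf
    beta_var <- Inf
    nu0 <- 0
    s02 <- 0
  }
  stopifnot(m_var > 0, beta_var > 0, nu0 >= 0, s02 >= 0)
  structure(list(m_mean = m_mean, m_var = m_var, beta_mean = beta_mean,
                 beta_var = beta_var, nu0 = nu0, s02 = s02),
            class = "b2_priors")
}

#' Sampler settings for [fit_b2_mcmc()]
#'
#' @param n_chains Number of chains (>= 2 recommended, enables split-Rhat).
#' @param n_iter Iterations per chain, including burn-in.
#' @param burn_in Iterations discarded (and used for proposal adaptation;
#'   scales are frozen afterwards so the post-burn-in kernel satisfies
#'   detailed balance).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; the whole fit is bit-reproducible given the
#'   seed. `NULL` continues from the current RNG state.
#' @param target_accept Target acceptance rate of the scalar random-walk
#'   updates during adaptation.
#' @param save_actor_effects Store the per-actor random-effect draws
#'   (memory-hungry for large rosters; posterior means are always kept).
#' @return A `b2_settings` list.
#' @export
b2_settings <- function(n_chains = 2, n_iter = 40000, burn_in = 10000,
                        thin = 10, seed = NULL, target_accept = 0.44,
                        save_actor_effects = FALSE) {
  stopifnot(n_chains >= 1, n_iter > burn_in, burn_in >= 0, thin >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, target_accept = target_accept,
                 save_actor_effects = isTRUE(save_actor_effects)),
            class = "b2_settings")
}

#' Parameter bundle for the b2 model
#'
#' @param m Overall mean on the logit scale.
#' @param beta_a Covariate coefficient vector (may be empty).
#' @param sigma_A2 Actor random-effect variance (>= 0).
#' @param A Per-actor random effects, one per random-effect slot.
#' @return A `b2_params` list.
#' @export
b2_params <- function(m, beta_a = numeric(0), sigma_A2 = 0, A = numeric(0)) {
  stopifnot(is.numeric(m), length(m) == 1, sigma_A2 >= 0)
  structure(list(m = m, beta_a = beta_a, sigma_A2 = sigma_A2, A = A),
            class = "b2_params")
}

# Linear predictor per dyad.
b2_linpred <- function(params, design) {
  d <- design$dyads
  mu <- rep(params$m, nrow(d))
  if (ncol(design$X)) {
    if (length(params$beta_a) != ncol(design$X)) {
      stop("beta_a has length ", length(params$beta_a), ", design has ",
           ncol(design$X), " covariate(s)", call. = FALSE)
    }
    mu <- mu + as.vector(design$X %*% params$beta_a)
  }
  if (length(params$A)) {
    if (length(params$A) != nrow(design$actors)) {
      stop("A has length ", length(params$A), ", design has ",
           nrow(design$actors), " actor slots", call. = FALSE)
    }
    mu <- mu + params$A[d$slot_i] + params$A[d$slot_j]
  }
  mu
}

# Stable Bernoulli-logit log density: y*mu - log(1 + exp(mu)).
bern_loglik <- function(mu, y) {
  ifelse(mu > 0,
         (y - 1) * mu - log1p(exp(-mu)),
         y * mu - log1p(exp(mu)))
}

#' b2 log-likelihood
#'
#' Sum over all dyads of the Bernoulli-logit log density with linear
#' predictor `m + Xa * beta_a + A_i + A_j`, evaluated in log-sum-exp form so
#' it is finite and accurate for `|mu|` up to several hundred.
#'
#' @param params A [b2_params()] bundle dimensioned to the design (an empty
#'   `A` means all random effects zero).
#' @param design A [dyad_design()].
#' @return Scalar log-likelihood.
#' @export
b2_loglik <- function(params, design) {
  stopifnot(inherits(design, "dyad_design"))
  mu <- b2_linpred(params, design)
  sum(bern_loglik(mu, design$dyads$y))
}

# Log density of the scaled inverse-chi^2(nu0, s02) prior at s2.
log_sinvchisq <- function(s2, nu0, s02) {
  if (nu0 <= 0) return(0)  # flat-prior convention
  (nu0 / 2) * log(nu0 * s02 / 2) - lgamma(nu0 / 2) -
    (nu0 / 2 + 1) * log(s2) - nu0 * s02 / (2 * s2)
}

#' b2 log-posterior (unnormalised)
#'
#' Adds to [b2_loglik()] the log priors of `m` and `beta_a`, the prior of
#' `sigma_A^2`, and the random-effect terms `sum(log N(A_ki | 0, sigma_A^2))`.
#' `sigma_A2 = 0` is treated as the degenerate no-heterogeneity model: the
#' random-effect and variance-prior terms vanish if all `A` are zero, and the
#' value is `-Inf` otherwise (the reject region).
#'
#' @inheritParams b2_loglik
#' @param priors A [b2_priors()] specification.
#' @return Scalar log-posterior density (up to a constant).
#' @export
b2_logposterior <- function(params, design, priors = b2_priors()) {
  stopifnot(inherits(priors, "b2_priors"))
  s2 <- params$sigma_A2
  if (s2 < 0) return(-Inf)
  lp <- b2_loglik(params, design)
  if (is.finite(priors$m_var)) {
    lp <- lp + dnorm(params$m, priors$m_mean, sqrt(priors$m_var), log = TRUE)
  }
  if (length(params$beta_a) && is.finite(priors$beta_var)) {
    lp <- lp + sum(dnorm(params$beta_a, priors$beta_mean,
                         sqrt(priors$beta_var), log = TRUE))
  }
  if (s2 == 0) {
    if (length(params$A) && any(params$A != 0)) return(-Inf)
    return(lp)
  }
  lp + log_sinvchisq(s2, priors$nu0, priors$s02) +
    sum(dnorm(params$A, 0, sqrt(s2), log = TRUE))
}

#' Posterior mode of (m, beta_a) with random effects switched off
#'
#' Maximises the b2 log-posterior over `(m, beta_a)` with `sigma_A^2` fixed
#' at 0 (all `A = 0`). Under flat priors this is exactly the
#' maximum-likelihood logistic regression on the dyad table (the
#' independent-dyad model), which makes it a sharp correctness check for the
#' likelihood code.
#'
#' @inheritParams b2_logposterior
#' @return List with `m`, `beta_a`, `logpost` and the `optim` convergence
#'   code.
#' @export
b2_map <- function(design, priors = b2_priors(flat = TRUE)) {
  p <- ncol(design$X)
  y <- design$dyads$y
  X <- design$X
  dens <- min(max(mean(y), 1e-6), 1 - 1e-6)
  start <- c(qlogis(dens), rep(0, p))

  negpost <- function(theta) {
    mu <- theta[1] + if (p) as.vector(X %*% theta[-1]) else 0
    lp <- sum(bern_loglik(mu, y))
    if (is.finite(priors$m_var)) {
      lp <- lp + dnorm(theta[1], priors$m_mean, sqrt(priors$m_var), log = TRUE)
    }
    if (p && is.finite(priors$beta_var)) {
      lp <- lp + sum(dnorm(theta[-1], priors$beta_mean,
                           sqrt(priors$beta_var), log = TRUE))
    }
    -lp
  }
  neggrad <- function(theta) {
    mu <- theta[1] + if (p) as.vector(X %*% theta[-1]) else 0
    r <- y - plogis(mu)
    g <- c(sum(r), if (p) as.vector(crossprod(X, r)))
    if (is.finite(priors$m_var)) {
      g[1] <- g[1] - (theta[1] - priors$m_mean) / priors$m_var
    }
    if (p && is.finite(priors$beta_var)) {
      g[-1] <- g[-1] - (theta[-1] - priors$beta_mean) / priors$beta_var
    }
    -g
  }
  fit <- optim(start, negpost, neggrad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  list(m = fit$par[1],
       beta_a = if (p) setNames(fit$par[-1], colnames(X)) else numeric(0),
       logpost = -fit$value, convergence = fit$convergence)
}

#' Fit the b2 model by Metropolis-within-Gibbs MCMC
#'
#' Random-walk Metropolis updates for `m`, each `beta_a` coefficient and each
#' actor effect `A_ki`; a conjugate scaled inverse-chi-squared Gibbs draw for
#' `sigma_A^2`; and a joint translation move (`A -> A - c`, `m -> m + 2c`,
#' which leaves every linear predictor unchanged and is accepted on the prior
#' ratio) to break the posterior correlation between `m` and the mean of the
#' random effects. Proposal scales adapt towards `target_accept` during
#' burn-in only and are frozen afterwards. Given `settings$seed`, the draw
#' sequences are bit-reproducible.
#'
#' @param design A [dyad_design()].
#' @param priors A [b2_priors()].
#' @param settings A [b2_settings()].
#' @param fix_sigma2 If non-`NULL`, hold `sigma_A^2` fixed at this value
#'   (0 disables the random effects entirely — the independent-dyad model).
#' @return A `b2_fit`: `draws` (list of per-chain matrices with columns `m`,
#'   the coefficient names, `sigma_A2`, and optionally the `A` slots),
#'   `accept` (post-burn-in acceptance rates), `A_mean` (posterior mean
#'   random effect per slot), `diagnostics` (from [mcmc_diagnostics()] when
#'   `n_chains >= 2`), plus the settings/priors/design metadata.
#' @export
fit_b2_mcmc <- function(design, priors = b2_priors(),
                        settings = b2_settings(), fix_sigma2 = NULL) {
  stopifnot(inherits(design, "dyad_design"),
            inherits(priors, "b2_priors"),
            inherits(settings, "b2_settings"))
  d <- design$dyads
  if (!nrow(d)) stop("empty dyad design", call. = FALSE)
  n_actors <- nrow(design$actors)
  p <- ncol(design$X)

  fix <- !is.null(fix_sigma2)
  if (fix) stopifnot(length(fix_sigma2) == 1, fix_sigma2 >= 0)
  sigma2_0 <- if (fix) fix_sigma2 else 0.5

  dens <- min(max(mean(d$y), 1 / (nrow(d) + 1)), nrow(d) / (nrow(d) + 1))
  m0 <- qlogis(dens)
  init <- b2_params(m = m0, beta_a = rep(0, p), sigma_A2 = sigma2_0,
                    A = rep(0, n_actors))
  lp0 <- b2_logposterior(init, design, priors)
  if (!is.finite(lp0)) {
    stop("non-finite log-posterior at initialization; ",
         "check the design and priors or supply different settings",
         call. = FALSE)
  }

  if (!is.null(settings$seed)) set.seed(settings$seed)

  # actor -> incident dyad indices (0-based for the C++ core)
  slot_dyads <- vector("list", n_actors)
  inc <- split(rep(seq_len(nrow(d)) - 1L, 2L), c(d$slot_i, d$slot_j))
  slot_dyads[as.integer(names(inc))] <- inc
  empty <- vapply(slot_dyads, is.null, TRUE)
  slot_dyads[empty] <- list(integer(0))

  re_active <- !(fix && fix_sigma2 == 0)
  par_names <- c("m", colnames(design$X), "sigma_A2")
  if (settings$save_actor_effects && re_active) {
    par_names <- c(par_names, paste0("A", seq_len(n_actors)))
  }

  draws <- vector("list", settings$n_chains)
  accept <- vector("list", settings$n_chains)
  A_mean <- matrix(0, settings$n_chains, n_actors)
  for (ch in seq_len(settings$n_chains)) {
    m_init <- m0 + if (ch > 1) rnorm(1, 0, 0.25) else 0
    beta_init <- if (ch > 1 && p) rnorm(p, 0, 0.25) else rep(0, p)
    res <- b2_sampler(
      y = as.numeric(d$y), X = design$X,
      si = d$slot_i - 1L, sj = d$slot_j - 1L,
      slot_dyads = slot_dyads,
      m_init = m_init, beta_init = beta_init,
      sigma2_init = sigma2_0,
      m_mean = priors$m_mean, m_var = priors$m_var,
      beta_mean = priors$beta_mean, beta_var = priors$beta_var,
      nu0 = priors$nu0, s02 = priors$s02,
      fix_sigma2 = fix, re_active = re_active,
      n_iter = settings$n_iter, burn_in = settings$burn_in,
      thin = settings$thin, target_accept = settings$target_accept,
      save_A = settings$save_actor_effects && re_active
    )
    colnames(res$draws) <- par_names
    draws[[ch]] <- res$draws
    accept[[ch]] <- res$accept
    A_mean[ch, ] <- res$A_mean
  }

  fit <- structure(list(
    draws = draws,
    accept = accept,
    A_mean = setNames(colMeans(A_mean),
                      paste(design$actors$k, design$actors$actor, sep = ":")),
    settings = settings, priors = priors, coding = design$coding,
    n_dyads = nrow(d), n_actors = n_actors,
    networks = unique(d$k), fixed_sigma2 = if (fix) fix_sigma2 else NULL
  ), class = "b2_fit")
  fit$diagnostics <- tryCatch(mcmc_diagnostics(fit),
                              warning = function(w) NULL)
  fit
}

# Pooled draw matrix across chains.
pooled_draws <- function(fit) {
  stopifnot(inherits(fit, "b2_fit"))
  do.call(rbind, fit$draws)
}

#' @export
print.b2_fit <- function(x, digits = 3, ...) {
  dr <- pooled_draws(x)
  scalar <- intersect(c("m", setdiff(colnames(dr), c("m", "sigma_A2"))[
    !grepl("^A[0-9]+$", setdiff(colnames(dr), c("m", "sigma_A2")))],
    "sigma_A2"), colnames(dr))
  cat(sprintf("b2 fit: %d dyads, %d actors, networks %s; %d chains x %d draws\n",
              x$n_dyads, x$n_actors, paste(x$networks, collapse = " vs "),
              length(x$draws), nrow(x$draws[[1]])))
  tab <- t(vapply(scalar, function(pn) {
    v <- dr[, pn]
    c(mean = mean(v), sd = sd(v),
      `2.5%` = unname(quantile(v, 0.025)),
      `97.5%` = unname(quantile(v, 0.975)))
  }, numeric(4)))
  print(round(tab, digits))
  if (!is.null(x$diagnostics)) {
    bad <- x$diagnostics$flagged
    cat(if (any(bad)) "convergence flagged (split-Rhat > 1.1) for: " else
      "split-Rhat <= 1.1 for all scalar parameters",
      if (any(bad)) paste(x$diagnostics$parameter[bad], collapse = ", "),
      "\n", sep = "")
  }
  invisible(x)
}

#' Posterior odds-ratio summary for the condition effect
#'
#' The reported effect is the posterior mean of `exp(beta_a)` (the posterior
#' mean *of the odds ratio*, not the exponentiated posterior mean of
#' `beta_a`) with an equal-tailed 95% credible interval from the empirical
#' 2.5% and 97.5% percentiles of the `exp(beta_a)` draws. Under
#' `actor_additive` coding this is a per-actor odds ratio; under
#' `dyad_indicator` coding, per dyad.
#'
#' @param fit A `b2_fit` containing covariate draws.
#' @return An `or_summary` `data.frame` with one row per coefficient:
#'   `parameter`, `or_point`, `ci_low`, `ci_high`.
#' @export
or_summary <- function(fit) {
  dr <- pooled_draws(fit)
  cols <- setdiff(colnames(dr), c("m", "sigma_A2"))
  cols <- cols[!grepl("^A[0-9]+$", cols)]
  if (!length(cols) || !nrow(dr)) {
    stop("posterior contains no covariate draws", call. = FALSE)
  }
  out <- do.call(rbind, lapply(cols, function(pn) {
    orv <- exp(dr[, pn])
    data.frame(parameter = pn,
               or_point = mean(orv),
               ci_low = unname(quantile(orv, 0.025)),
               ci_high = unname(quantile(orv, 0.975)),
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(out$ci_low <= out$ci_high), all(out$or_point > 0))
  class(out) <- c("or_summary", class(out))
  out
}

#' Split-Rhat and effective sample size
#'
#' Computes the split-chain potential scale reduction factor and an
#' effective sample size for every scalar parameter. Each chain is split in
#' half; `Rhat = sqrt(((n-1)/n * W + B/n) / W)` with `W`/`B` the within/
#' between-sequence variances. The ESS uses the variogram autocorrelation
#' estimate, truncated at the first negative paired sum. Parameters with
#' `Rhat > 1.1` (or degenerate zero-variance chains) are flagged.
#'
#' @param fit A `b2_fit`, or a list of per-chain draw matrices with common
#'   column names.
#' @return `data.frame` with columns `parameter`, `rhat`, `ess`, `flagged`.
#'   With a single chain, `rhat` is `NA` (a warning is issued) and only the
#'   ESS is reported.
#' @export
mcmc_diagnostics <- function(fit) {
  chains <- if (inherits(fit, "b2_fit")) fit$draws else fit
  stopifnot(is.list(chains), length(chains) >= 1)
  pars <- colnames(chains[[1]])
  single <- length(chains) == 1L
  if (single) {
    warning("split-Rhat requires at least 2 chains; reporting ESS only",
            call. = FALSE)
  }
  out <- do.call(rbind, lapply(pars, function(pn) {
    seqs <- lapply(chains, function(m) m[, pn])
    # split each chain in half
    halves <- unlist(lapply(seqs, function(v) {
      n2 <- floor(length(v) / 2)
      list(v[seq_len(n2)], v[seq(length(v) - n2 + 1, length(v))])
    }), recursive = FALSE)
    n <- length(halves[[1]])
    M <- length(halves)
    mat <- vapply(halves, identity, numeric(n))
    W <- mean(apply(mat, 2, var))
    B <- n * var(colMeans(mat))
    varplus <- (n - 1) / n * W + B / n
    rhat <- if (single) NA_real_ else if (W <= 0) NaN else sqrt(varplus / W)
    ess <- if (varplus <= 0) NA_real_ else ess_variogram(mat, varplus)
    data.frame(parameter = pn, rhat = rhat, ess = ess,
               flagged = is.na(rhat) || is.nan(rhat) || rhat > 1.1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Effective sample size from the variogram estimate of the autocorrelation
# (rho_t = 1 - V_t / (2 var+)), truncated when a paired sum of
# autocorrelations turns negative.
ess_variogram <- function(mat, varplus) {
  n <- nrow(mat)
  M <- ncol(mat)
  rho <- numeric(0)
  t <- 1L
  while (t < n - 1) {
    Vt <- mean(colMeans((mat[seq_len(n - t), , drop = FALSE] -
                           mat[seq(t + 1, n), , drop = FALSE])^2))
    Vt1 <- mean(colMeans((mat[seq_len(n - t - 1), , drop = FALSE] -
                            mat[seq(t + 2, n), , drop = FALSE])^2))
    r1 <- 1 - Vt / (2 * varplus)
    r2 <- 1 - Vt1 / (2 * varplus)
    if (r1 + r2 < 0) break
    rho <- c(rho, r1, r2)
    t <- t + 2L
  }
  min(M * n / max(1 + 2 * sum(rho), 1e-12), M * n)
}

#' Monte-Carlo standard error of a posterior mean
#'
#' `sd(draws) / sqrt(ESS)` for one scalar parameter, pooling all chains.
#'
#' @param fit A `b2_fit`.
#' @param parameter Column name, e.g. `"m"`.
#' @return Scalar MCSE.
#' @export
mcse_mean <- function(fit, parameter = "m") {
  diag <- mcmc_diagnostics(fit$draws)
  ess <- diag$ess[diag$parameter == parameter]
  if (!length(ess) || is.na(ess)) return(NA_real_)
  sd(pooled_draws(fit)[, parameter]) / sqrt(ess)
}
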
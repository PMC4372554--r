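# Shared fixtures: small MCMC budgets, a well-identified synthetic scenario,
# and an independent straight-from-the-equations log-posterior evaluator used
# as the oracle for simm_log_posterior().

quick_mcmc <- function(burn_in = 3000, n_samples = 1500, thin = 3,
                       n_chains = 3) {
  mcmc_control(n_chains = n_chains, burn_in = burn_in, n_samples = n_samples,
               thin = thin, psrf_action = "none")
}

# Three sources spanning a proper (non-degenerate) mixing triangle
toy_sources <- function() {
  source_table(c("A", "B", "C"),
               mean = rbind(d13C = c(-24, -18, -12), d15N = c(3, 9, 4)),
               sd = rbind(d13C = c(0.8, 0.8, 0.8), d15N = c(0.6, 0.6, 0.6)))
}

toy_scenario <- function(p = c(0.5, 0.3, 0.2), I = 50, seed = 1,
                         sigma = c(0.4, 0.3),
                         tdf = tdf_set(c(1.5, 3.0), c(0, 0))) {
  synthetic_scenario(p, toy_sources(), tdf, n_consumers = I, sigma = sigma,
                     seed = seed)
}

# Independent density oracle: per-consumer normal likelihood plus priors,
# written directly from the model equations with stats::dnorm / lgamma.
oracle_log_posterior <- function(spec, state) {
  X <- unclass(spec$consumers)
  mu <- spec$mu
  omega <- spec$omega
  J <- nrow(mu); K <- ncol(mu)
  p <- as.numeric(state$p)
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-8) return(-Inf)
  cvec <- if (spec$mode == "tdf") as.numeric(state$c)
  else as.numeric(spec$tdf$mean)
  tau <- if (spec$mode == "diet" && spec$tdf_uncertainty == "variance")
    as.numeric(spec$tdf$sd) else rep(0, J)
  sigma <- if (spec$residual) as.numeric(state$sigma) else rep(0, J)
  if (spec$mode == "tdf" &&
      (any(cvec <= spec$c_bounds[1]) || any(cvec >= spec$c_bounds[2])))
    return(-Inf)
  if (spec$residual &&
      (any(sigma <= spec$sigma_bounds[1]) ||
       any(sigma >= spec$sigma_bounds[2])))
    return(-Inf)
  ll <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(J)) {
      m <- sum(p * (mu[j, ] + cvec[j]))
      v <- sum(p^2 * (omega[j, ]^2 + tau[j]^2)) + sigma[j]^2
      ll <- ll + stats::dnorm(X[i, j], m, sqrt(v), log = TRUE)
    }
  }
  alpha <- if (spec$mode == "diet") spec$prior$alpha else spec$diet$alpha
  lp <- ll + lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum((alpha - 1) * log(p))
  if (spec$mode == "tdf")
    lp <- lp + sum(stats::dunif(cvec, spec$c_bounds[1], spec$c_bounds[2],
                                log = TRUE))
  if (spec$residual)
    lp <- lp + sum(stats::dunif(sigma, spec$sigma_bounds[1],
                                spec$sigma_bounds[2], log = TRUE))
  as.numeric(lp)
}

# Random in-support state for a spec
random_state <- function(spec, seed) {
  set.seed(seed)
  K <- length(spec$species); J <- length(spec$isotopes)
  st <- list(p = as.numeric(rdirichlet(1, rep(2, K))))
  if (spec$residual)
    st$sigma <- runif(J, spec$sigma_bounds[1] + 0.05,
                      min(spec$sigma_bounds[2], 3))
  if (spec$mode == "tdf")
    st$c <- runif(J, spec$c_bounds[1] + 0.1, spec$c_bounds[2] - 0.1)
  st
}
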
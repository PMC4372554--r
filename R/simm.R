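#' MCMC control settings for the mixing model
#'
#' Defaults follow the study protocol: 3 parallel chains, 50,000 burn-in
#' iterations, 15,000 sampling iterations thinned by 15, convergence judged by
#' the Gelman-Rubin potential scale reduction factor (PSRF) < 1.1.
#'
#' @param n_chains Number of parallel chains (>= 2 for PSRF).
#' @param burn_in Burn-in iterations per chain (adaptation happens here only).
#' @param n_samples Post-burn-in iterations per chain.
#' @param thin Thinning interval; `n_samples` must be a multiple of `thin`.
#' @param psrf_threshold PSRF above which convergence is flagged.
#' @param psrf_action What to do when any PSRF >= threshold: `"warn"`
#'   (default), `"error"`, or `"none"`.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 3L, burn_in = 50000L, n_samples = 15000L,
                         thin = 15L, psrf_threshold = 1.1,
                         psrf_action = c("warn", "error", "none")) {
  psrf_action <- match.arg(psrf_action)
  stopifnot(n_chains >= 1L, burn_in >= 0L, n_samples >= 1L, thin >= 1L,
            psrf_threshold > 0)
  if (n_samples %% thin != 0L)
    stop("n_samples must be a multiple of thin")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples), thin = as.integer(thin),
                 psrf_threshold = psrf_threshold, psrf_action = psrf_action),
            class = "mcmc_control")
}

#' Specify a stable isotope mixing model
#'
#' The likelihood for consumer i and isotope j is normal with mean
#' `sum_k p_k (mu_jk + c_j)` and variance
#' `sum_k p_k^2 (omega_jk^2 + tau_j^2) + sigma_j^2`, where `p` are diet
#' proportions, `mu_jk` / `omega_jk` the source means and SDs, `c_j` the
#' per-isotope trophic discrimination factor (TDF), `tau_j` its SD, and
#' `sigma_j` a residual SD. Two modes:
#' \describe{
#'   \item{`"diet"`}{`p` is estimated under a Dirichlet prior; `c_j` is fixed
#'     at the TDF means and `tau_j` at the TDF SDs (entering the combined
#'     variance when `tdf_uncertainty = "variance"`).}
#'   \item{`"tdf"`}{`c_j` is estimated under independent Uniform priors
#'     (`c_bounds`, default 0-10); `p` carries the informative diet Dirichlet
#'     and `tau_j = 0`.}
#' }
#' In both modes `sigma_j` gets a Uniform prior on `sigma_bounds` unless
#' `residual = FALSE`, which pins it to zero.
#'
#' @param sources A `source_table` (see [source_table()],
#'   [summarize_sources()]).
#' @param consumers A `consumer_data` matrix or coercible data frame.
#' @param mode `"diet"` or `"tdf"`.
#' @param tdf A [tdf_set()] (diet mode).
#' @param prior A [dirichlet_spec()] prior on diet proportions (diet mode).
#' @param diet A [dirichlet_spec()] describing the known diet (tdf mode).
#' @param c_bounds Uniform prior bounds on each TDF (tdf mode).
#' @param sigma_bounds Uniform prior bounds on each residual SD.
#' @param residual Include the residual error term? Disabling it removes
#'   `sigma` from the model.
#' @param tdf_uncertainty `"variance"` (default) propagates TDF SDs into the
#'   combined variance in diet mode; `"none"` ignores them.
#' @return An object of class `simm_spec`.
#' @export
simm_spec <- function(sources, consumers, mode = c("diet", "tdf"),
                      tdf = NULL, prior = NULL, diet = NULL,
                      c_bounds = c(0, 10), sigma_bounds = c(0, 10),
                      residual = TRUE,
                      tdf_uncertainty = c("variance", "none")) {
  mode <- match.arg(mode)
  tdf_uncertainty <- match.arg(tdf_uncertainty)
  sm <- source_matrices(sources)
  if (!inherits(consumers, "consumer_data"))
    consumers <- consumer_data(consumers, isotopes = sm$isotopes)
  if (!identical(colnames(consumers), sm$isotopes))
    stop("consumer isotopes must match source isotopes (same order)")
  chk_bounds <- function(b, nm) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1L] >= b[2L])
      stop(nm, " must be finite bounds with lower < upper")
  }
  chk_bounds(c_bounds, "c_bounds"); chk_bounds(sigma_bounds, "sigma_bounds")
  if (sigma_bounds[1L] < 0) sigma_bounds[1L] <- 0
  if (mode == "diet") {
    if (is.null(tdf) || is.null(prior))
      stop("diet mode requires both a tdf_set and a Dirichlet prior")
    if (!identical(tdf$isotopes, sm$isotopes))
      stop("TDF isotopes must match source isotopes")
    if (length(prior$alpha) != length(sm$species))
      stop("prior alpha length must equal the number of sources")
    # align prior entries to the source order when names are given
    if (all(sm$species %in% prior$species))
      prior <- dirichlet_spec(prior$alpha[sm$species], sm$species)
  } else {
    if (is.null(diet))
      stop("tdf mode requires a diet Dirichlet specification")
    if (length(diet$alpha) != length(sm$species))
      stop("diet alpha length must equal the number of sources")
    if (all(sm$species %in% diet$species))
      diet <- dirichlet_spec(diet$alpha[sm$species], sm$species)
  }
  structure(list(mode = mode, sources = sources, consumers = consumers,
                 tdf = tdf, prior = prior, diet = diet,
                 c_bounds = as.numeric(c_bounds),
                 sigma_bounds = as.numeric(sigma_bounds),
                 residual = isTRUE(residual),
                 tdf_uncertainty = tdf_uncertainty,
                 mu = sm$mu, omega = sm$omega,
                 species = sm$species, isotopes = sm$isotopes),
            class = "simm_spec")
}

# Internal: everything the density needs, precomputed once
simm_precompute <- function(spec) {
  X <- unclass(spec$consumers)
  I <- nrow(X); J <- length(spec$isotopes); K <- length(spec$species)
  xbar <- colMeans(X)
  ss <- colSums(sweep(X, 2L, xbar)^2)
  tau <- if (spec$mode == "diet" && spec$tdf_uncertainty == "variance")
    spec$tdf$sd else rep(0, J)
  w2 <- spec$omega^2 + tau^2  # J x K per-source variance entering the mixture
  alpha <- if (spec$mode == "diet") spec$prior$alpha else spec$diet$alpha
  list(I = I, J = J, K = K, xbar = xbar, ss = ss, mu = spec$mu, w2 = w2,
       alpha = as.numeric(alpha),
       cfix = if (spec$mode == "diet") as.numeric(spec$tdf$mean) else NULL,
       c_lo = spec$c_bounds[1L], c_hi = spec$c_bounds[2L],
       s_lo = spec$sigma_bounds[1L], s_hi = spec$sigma_bounds[2L],
       residual = spec$residual, mode = spec$mode)
}

# Internal: log-likelihood given p (K), c (J), sigma (J); -Inf if any
# per-isotope variance is non-positive
simm_loglik <- function(pc, p, cvec, sigma) {
  m <- as.numeric(pc$mu %*% p) + cvec
  v <- as.numeric(pc$w2 %*% (p * p)) + sigma * sigma
  if (any(v <= 0)) return(-Inf)
  sum(-0.5 * pc$I * log(2 * pi * v) -
        (pc$ss + pc$I * (pc$xbar - m)^2) / (2 * v))
}

#' Log posterior density of a mixing-model state
#'
#' Evaluates the unnormalized-in-nothing (all prior and likelihood constants
#' included) log posterior density on the natural parameter scale. States
#' outside the support return `-Inf`.
#'
#' @param spec A [simm_spec()].
#' @param state Named list with `p` (simplex vector over sources), `sigma`
#'   (per-isotope residual SDs; omit when the spec has `residual = FALSE`),
#'   and, in tdf mode, `c` (per-isotope TDFs).
#' @return A single log-density value.
#' @export
simm_log_posterior <- function(spec, state) {
  stopifnot(inherits(spec, "simm_spec"))
  pc <- simm_precompute(spec)
  p <- as.numeric(state$p)
  if (length(p) != pc$K) stop("state$p must have one entry per source")
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-8) return(-Inf)
  sigma <- if (pc$residual) as.numeric(state$sigma) else rep(0, pc$J)
  if (pc$residual) {
    if (length(sigma) != pc$J) stop("state$sigma must have one entry per isotope")
    if (any(sigma <= pc$s_lo) || any(sigma >= pc$s_hi)) return(-Inf)
  }
  if (pc$mode == "tdf") {
    cvec <- as.numeric(state$c)
    if (length(cvec) != pc$J) stop("state$c must have one entry per isotope")
    if (any(cvec <= pc$c_lo) || any(cvec >= pc$c_hi)) return(-Inf)
  } else {
    cvec <- pc$cfix
  }
  lp <- simm_loglik(pc, p, cvec, sigma)
  lp <- lp + ddirichlet_log(p, pc$alpha)
  if (pc$mode == "tdf") lp <- lp - pc$J * log(pc$c_hi - pc$c_lo)
  if (pc$residual) lp <- lp - pc$J * log(pc$s_hi - pc$s_lo)
  as.numeric(lp)
}

# Internal: one chain of adaptive Metropolis-within-Gibbs.
# Parameterization: z in R^(K-1) with p = softmax(c(z, 0)) (log-Jacobian
# sum(log p)); c sampled directly with bound rejection; sigma via log(sigma)
# (log-Jacobian sum(log sigma)). Step sizes adapt in batches of 50 during
# burn-in toward 28% acceptance, then freeze so retained draws are valid MCMC.
simm_chain <- function(pc, cfg, seed, init) {
  set.seed(seed)
  K <- pc$K; J <- pc$J
  tdf_mode <- pc$mode == "tdf"
  z <- init$z
  cv <- if (tdf_mode) init$c else pc$cfix
  ls <- if (pc$residual) init$ls else NULL

  softmax <- function(z) {
    e <- exp(c(z, 0) - max(z, 0))
    e / sum(e)
  }
  target <- function(z, cv, ls) {
    p <- softmax(z)
    sigma <- if (pc$residual) exp(ls) else rep(0, J)
    if (pc$residual && any(sigma >= pc$s_hi)) return(-Inf)
    if (tdf_mode && (any(cv <= pc$c_lo) || any(cv >= pc$c_hi))) return(-Inf)
    ll <- simm_loglik(pc, p, cv, sigma)
    if (!is.finite(ll)) return(-Inf)
    lp <- ll + sum((pc$alpha - 1) * log(p)) + sum(log(p))
    if (pc$residual) lp <- lp + sum(ls)
    lp
  }

  cur <- target(z, cv, ls)
  if (!is.finite(cur))
    stop("non-finite log-posterior at initialization")

  steps <- c(z = 0.4, c = 0.4, s = 0.4)
  acc <- c(z = 0L, c = 0L, s = 0L)
  n_keep <- cfg$n_samples %/% cfg$thin
  P <- matrix(NA_real_, n_keep, K)
  C <- if (tdf_mode) matrix(NA_real_, n_keep, J) else NULL
  S <- if (pc$residual) matrix(NA_real_, n_keep, J) else NULL
  keep <- 0L
  total <- cfg$burn_in + cfg$n_samples
  batch <- 0L

  for (it in seq_len(total)) {
    # p block
    zp <- z + stats::rnorm(K - 1L, 0, steps["z"])
    new <- target(zp, cv, ls)
    if (log(stats::runif(1)) < new - cur) {
      z <- zp; cur <- new; acc["z"] <- acc["z"] + 1L
    }
    # c block (tdf mode)
    if (tdf_mode) {
      cp <- cv + stats::rnorm(J, 0, steps["c"])
      new <- target(z, cp, ls)
      if (log(stats::runif(1)) < new - cur) {
        cv <- cp; cur <- new; acc["c"] <- acc["c"] + 1L
      }
    }
    # sigma block
    if (pc$residual) {
      lsp <- ls + stats::rnorm(J, 0, steps["s"])
      new <- target(z, cv, lsp)
      if (log(stats::runif(1)) < new - cur) {
        ls <- lsp; cur <- new; acc["s"] <- acc["s"] + 1L
      }
    }
    # adapt during burn-in only
    if (it <= cfg$burn_in && it %% 50L == 0L) {
      batch <- batch + 1L
      gain <- 1 / sqrt(batch)
      for (b in c("z", "c", "s")) {
        rate <- acc[b] / 50
        steps[b] <- exp(log(steps[b]) + gain * (rate - 0.28))
      }
      steps <- pmin(pmax(steps, 1e-3), 5)
      acc[] <- 0L
    }
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      keep <- keep + 1L
      P[keep, ] <- softmax(z)
      if (tdf_mode) C[keep, ] <- cv
      if (pc$residual) S[keep, ] <- exp(ls)
    }
  }
  list(p = P, c = C, sigma = S,
       accept = acc / cfg$n_samples, steps = steps)
}

#' Fit a Bayesian stable isotope mixing model
#'
#' The central fitting function. Builds (or accepts) a [simm_spec()] and
#' samples its posterior with an adaptive Metropolis-within-Gibbs sampler:
#' diet proportions move by a random walk on the softmax-transformed simplex
#' (with the change-of-variables Jacobian), TDFs and log residual SDs by
#' Gaussian random walks. Step sizes adapt during burn-in only. PSRF is
#' computed for every monitored scalar across chains and compared to the
#' configured threshold.
#'
#' @param sources A `source_table`, or a ready-made [simm_spec()] (in which
#'   case all spec arguments are ignored).
#' @param consumers Consumer isotope matrix (see [consumer_data()]).
#' @param mode `"diet"` or `"tdf"`; see [simm_spec()].
#' @param tdf,prior,diet,c_bounds,sigma_bounds,residual,tdf_uncertainty
#'   Passed to [simm_spec()].
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed; per-chain seeds are derived deterministically, so
#'   the same seed reproduces the draws exactly.
#' @return An object of class `simm` with components `draws` (list of
#'   matrices `p`, `c`, `sigma`), `chain` (chain index per draw), `psrf`
#'   (named vector), `spec`, `mcmc`, `accept`.
#' @examples
#' inp <- captive_study_inputs()
#' cons <- simulate_consumers(inp$consumer_summary, 10, seed = 7)
#' fit <- simm(inp$sources, cons, mode = "tdf", diet = inp$diet_alpha,
#'             mcmc = mcmc_control(burn_in = 500, n_samples = 500, thin = 1),
#'             seed = 1)
#' coef(fit)
#' @export
simm <- function(sources, consumers = NULL, mode = c("diet", "tdf"),
                 tdf = NULL, prior = NULL, diet = NULL, c_bounds = c(0, 10),
                 sigma_bounds = c(0, 10), residual = TRUE,
                 tdf_uncertainty = c("variance", "none"),
                 mcmc = mcmc_control(), seed = 1L) {
  spec <- if (inherits(sources, "simm_spec")) sources else
    simm_spec(sources, consumers, mode, tdf = tdf, prior = prior, diet = diet,
              c_bounds = c_bounds, sigma_bounds = sigma_bounds,
              residual = residual, tdf_uncertainty = tdf_uncertainty)
  pc <- simm_precompute(spec)
  K <- pc$K; J <- pc$J
  tdf_mode <- pc$mode == "tdf"

  # overdispersed initial values around prior-mean p, prior-midpoint c,
  # sigma = 0.5
  p0 <- pc$alpha / sum(pc$alpha)
  z0 <- log(p0[-K]) - log(p0[K])
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(derive_seed(seed, 10L, ch))
    init <- list(
      z = z0 + stats::rnorm(K - 1L, 0, 0.7),
      c = if (tdf_mode)
        pmin(pmax((pc$c_lo + pc$c_hi) / 2 + stats::rnorm(J, 0, 0.5),
                  pc$c_lo + 1e-3), pc$c_hi - 1e-3) else NULL,
      ls = if (pc$residual)
        pmin(log(0.5) + stats::rnorm(J, 0, 0.3), log(pc$s_hi) - 1e-3)
      else NULL)
    chains[[ch]] <- simm_chain(pc, mcmc, derive_seed(seed, 20L, ch), init)
  }

  n_keep <- mcmc$n_samples %/% mcmc$thin
  bindp <- do.call(rbind, lapply(chains, `[[`, "p"))
  colnames(bindp) <- spec$species
  draws <- list(p = bindp)
  if (tdf_mode) {
    draws$c <- do.call(rbind, lapply(chains, `[[`, "c"))
    colnames(draws$c) <- spec$isotopes
  }
  if (pc$residual) {
    draws$sigma <- do.call(rbind, lapply(chains, `[[`, "sigma"))
    colnames(draws$sigma) <- spec$isotopes
  }
  chain_id <- rep(seq_len(mcmc$n_chains), each = n_keep)

  # PSRF for every monitored scalar
  scal <- cbind(stats::setNames(as.data.frame(draws$p),
                                paste0("p[", spec$species, "]")))
  if (tdf_mode)
    scal <- cbind(scal, stats::setNames(as.data.frame(draws$c),
                                        paste0("c[", spec$isotopes, "]")))
  if (pc$residual)
    scal <- cbind(scal, stats::setNames(as.data.frame(draws$sigma),
                                        paste0("sigma[", spec$isotopes, "]")))
  psrf <- if (mcmc$n_chains >= 2L && n_keep >= 10L) {
    vapply(scal, function(v) gelman_rubin(split(v, chain_id)), 0)
  } else stats::setNames(rep(NA_real_, ncol(scal)), names(scal))

  if (any(is.finite(psrf) & psrf >= mcmc$psrf_threshold)) {
    msg <- paste0("PSRF >= ", mcmc$psrf_threshold, " for: ",
                  paste(names(psrf)[is.finite(psrf) &
                                      psrf >= mcmc$psrf_threshold],
                        collapse = ", "))
    if (mcmc$psrf_action == "error") stop(msg)
    if (mcmc$psrf_action == "warn") warning(msg)
  }

  structure(list(draws = draws, chain = chain_id, psrf = psrf, spec = spec,
                 mcmc = mcmc, seed = seed,
                 accept = lapply(chains, `[[`, "accept")),
            class = "simm")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the PSRF from between- and within-chain variances:
#' with m chains of n draws, `W` the mean within-chain variance and `B/n` the
#' variance of the chain means, the pooled estimate is
#' `V = (n - 1)/n * W + B/n` and PSRF `= sqrt(V / W)`.
#'
#' @param chains List of numeric vectors (one per chain, equal lengths), or a
#'   matrix with one column per chain.
#' @return The PSRF value.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(i) chains[, i])
  m <- length(chains)
  if (m < 2L) stop("PSRF needs at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 10L) stop("PSRF needs at least 10 draws per chain")
  means <- vapply(chains, mean, 0)
  W <- mean(vapply(chains, stats::var, 0))
  B_over_n <- stats::var(means)
  if (W <= 0) return(if (B_over_n <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Extract posterior draws from a fitted mixing model
#'
#' @param fit A `simm` object.
#' @param param `"p"` (diet proportions), `"c"` (TDFs), or `"sigma"`
#'   (residual SDs).
#' @param chain Optional chain index to restrict to.
#' @return A draws x parameters matrix.
#' @export
posterior_draws <- function(fit, param = c("p", "c", "sigma"), chain = NULL) {
  stopifnot(inherits(fit, "simm"))
  param <- match.arg(param)
  d <- fit$draws[[param]]
  if (is.null(d)) stop("this fit has no '", param, "' draws")
  if (!is.null(chain)) d <- d[fit$chain == chain, , drop = FALSE]
  d
}
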
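#' @export
print.simm <- function(x, digits = 3, ...) {
  cat("Bayesian stable isotope mixing model (", x$spec$mode, " mode)\n",
      sep = "")
  cat(length(x$spec$species), "sources,",
      nrow(x$spec$consumers), "consumers,",
      length(x$spec$isotopes), "isotopes;",
      nrow(x$draws$p), "retained draws from", x$mcmc$n_chains, "chains\n")
  cat("Posterior means:\n")
  print(round(coef(x), digits))
  if (any(is.finite(x$psrf)))
    cat("max PSRF:", round(max(x$psrf, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' Summarize a fitted mixing model
#'
#' Posterior mean, SD, 95% credible interval (percentile), and PSRF for every
#' monitored scalar: diet proportions `p[...]`, discrimination factors
#' `c[...]` (tdf mode), and residual SDs `sigma[...]`.
#'
#' @param object A `simm` fit.
#' @param ... Unused.
#' @return A `summary.simm` data frame.
#' @export
summary.simm <- function(object, ...) {
  blocks <- list(p = object$draws$p, c = object$draws$c,
                 sigma = object$draws$sigma)
  rows <- list()
  for (nm in names(blocks)) {
    d <- blocks[[nm]]
    if (is.null(d)) next
    for (j in seq_len(ncol(d))) {
      lab <- paste0(nm, "[", colnames(d)[j], "]")
      q <- stats::quantile(d[, j], c(0.025, 0.975), names = FALSE)
      rows[[lab]] <- data.frame(
        parameter = lab, mean = mean(d[, j]), sd = stats::sd(d[, j]),
        lower95 = q[1L], upper95 = q[2L],
        psrf = unname(object$psrf[lab]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.simm", "data.frame")
  out
}

#' @export
print.summary.simm <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y[-1L] <- lapply(y[-1L], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Posterior means of the primary parameters
#'
#' Diet mode: posterior mean diet proportions. TDF mode: posterior mean
#' discrimination factors.
#'
#' @param object A `simm` fit.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.simm <- function(object, ...) {
  if (object$spec$mode == "diet") colMeans(object$draws$p)
  else colMeans(object$draws$c)
}

# Internal: posterior-mean mixture mean per isotope
simm_fitted_mean <- function(object) {
  pc <- simm_precompute(object$spec)
  pbar <- colMeans(object$draws$p)
  cbar <- if (object$spec$mode == "tdf") colMeans(object$draws$c) else pc$cfix
  stats::setNames(as.numeric(pc$mu %*% pbar) + cbar, object$spec$isotopes)
}

#' @export
fitted.simm <- function(object, ...) {
  mu <- simm_fitted_mean(object)
  X <- unclass(object$spec$consumers)
  matrix(mu, nrow(X), length(mu), byrow = TRUE,
         dimnames = list(NULL, names(mu)))
}

#' @export
residuals.simm <- function(object, ...) {
  unclass(object$spec$consumers) - fitted(object)
}

#' Simulate posterior-predictive consumer datasets
#'
#' Each replicate picks one retained posterior draw and generates a full
#' consumer matrix from the model's marginal normal likelihood.
#'
#' @param object A `simm` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` consumer matrices.
#' @export
simulate.simm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pc <- simm_precompute(object$spec)
  n <- nrow(object$draws$p)
  picks <- sample.int(n, nsim, replace = nsim > n)
  lapply(picks, function(t) {
    p <- object$draws$p[t, ]
    cvec <- if (pc$mode == "tdf") object$draws$c[t, ] else pc$cfix
    sigma <- if (pc$residual) object$draws$sigma[t, ] else rep(0, pc$J)
    m <- as.numeric(pc$mu %*% p) + cvec
    v <- as.numeric(pc$w2 %*% (p * p)) + sigma^2
    X <- vapply(seq_len(pc$J),
                function(j) stats::rnorm(pc$I, m[j], sqrt(v[j])),
                numeric(pc$I))
    colnames(X) <- object$spec$isotopes
    X
  })
}

#' Trace and density plots for a fitted mixing model
#'
#' Base-graphics traces (colored by chain) and posterior densities for the
#' primary parameters.
#'
#' @param x A `simm` fit.
#' @param param Parameter block to plot (default: the primary block).
#' @param ... Passed to `plot`.
#' @export
plot.simm <- function(x, param = if (x$spec$mode == "diet") "p" else "c",
                      ...) {
  d <- posterior_draws(x, param)
  J <- ncol(d)
  op <- graphics::par(mfrow = c(J, 2), mar = c(3, 3, 2, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  for (j in seq_len(J)) {
    graphics::plot(d[, j], type = "l", col = x$chain,
                   xlab = "draw", ylab = colnames(d)[j],
                   main = paste0(param, "[", colnames(d)[j], "] trace"), ...)
    graphics::plot(stats::density(d[, j]), main = paste0(
      param, "[", colnames(d)[j], "] density"), xlab = colnames(d)[j])
  }
  invisible(x)
}
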
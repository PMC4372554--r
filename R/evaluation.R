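#' Bias, precision, and accuracy of a posterior against a reference diet
#'
#' Pairs `n` randomly sampled posterior proportion vectors with `n` reference
#' vectors and computes, per source: bias (mean of the paired differences),
#' Monte Carlo variance (sample variance, n - 1 denominator, of the sampled
#' posterior draws themselves — smaller is more precise), and mean squared
#' error `MSE = variance + bias^2` (smaller is more accurate). The percentile
#' 95% CI of the differences is also returned, with a significance flag per
#' source (CI overlaps zero).
#'
#' @param posterior A `simm` fit (diet mode), `diet_estimate`, or proportion
#'   draw matrix.
#' @param reference A [dirichlet_spec()], `diet_estimate`, or B x K draw
#'   matrix over the same sources.
#' @param n Number of draw pairs (default 1000); must not exceed the
#'   available draws on either side.
#' @param seed Optional RNG seed (pairing is random without replacement).
#' @return An object of class `evaluation_metrics`: data frame with columns
#'   `source`, `mean`, `sd`, `bias`, `variance`, `mse`, `ci_lower`,
#'   `ci_upper`, `overlaps_zero`, `n`.
#' @export
evaluate_posterior <- function(posterior, reference, n = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  post <- as_p_draws(posterior)
  if (nrow(post) < n)
    stop("posterior has only ", nrow(post), " draws; n = ", n, " requested")
  sel <- post[sample.int(nrow(post), n), , drop = FALSE]
  ref <- reference_draws(reference, n)
  if (!is.null(colnames(sel)) && !is.null(colnames(ref)) &&
      !identical(colnames(sel), colnames(ref)))
    stop("posterior and reference source sets differ")
  diffs <- sel - ref
  bias <- colMeans(diffs)
  variance <- apply(sel, 2L, stats::var)
  mse <- variance + bias^2
  ci <- apply(diffs, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(source = colnames(sel), mean = colMeans(sel),
                    sd = apply(sel, 2L, stats::sd), bias = bias,
                    variance = variance, mse = mse,
                    ci_lower = ci[1L, ], ci_upper = ci[2L, ],
                    overlaps_zero = ci[1L, ] <= 0 & ci[2L, ] >= 0,
                    n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("evaluation_metrics", "data.frame")
  out
}

#' Compare mixing models against a baseline
#'
#' Evaluates each fitted model's posterior diet proportions against the
#' baseline model's, reporting per prey and per model the 95% CI of the
#' posterior difference, bias, the variance difference (model variance minus
#' baseline variance), and MSE.
#'
#' @param fits Named list of `simm` fits (diet mode), e.g. the four
#'   combinations of two priors and two TDF sets.
#' @param baseline A `simm` fit (or draw matrix) treated as the reference.
#' @param n Draw pairs per comparison.
#' @param seed Optional RNG seed; each model gets a derived sub-seed.
#' @return A data frame with columns `model`, `source`, `mean`, `sd`,
#'   `overlaps_zero`, `ci_lower`, `ci_upper`, `bias`, `variance`,
#'   `variance_diff`, `mse`.
#' @export
compare_models <- function(fits, baseline, n = 1000L, seed = NULL) {
  if (inherits(fits, "simm")) fits <- list(model = fits)
  base_draws <- as_p_draws(baseline)
  base_var <- apply(base_draws, 2L, stats::var)
  labels <- names(fits)
  if (is.null(labels)) labels <- paste0("model", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    pd <- as_p_draws(fits[[i]])
    if (!identical(colnames(pd), colnames(base_draws)))
      stop("model '", labels[i], "' and baseline have different sources")
    ev <- evaluate_posterior(pd, base_draws, n = n,
                             seed = if (is.null(seed)) NULL
                             else derive_seed(seed, 50L, i))
    data.frame(model = labels[i], source = ev$source, mean = ev$mean,
               sd = ev$sd, overlaps_zero = ev$overlaps_zero,
               ci_lower = ev$ci_lower, ci_upper = ev$ci_upper,
               bias = ev$bias, variance = ev$variance,
               variance_diff = ev$variance - base_var[ev$source],
               mse = ev$mse, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
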
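#' Bootstrap diet composition from feeding records
#'
#' Estimates the proportional contribution of each prey species to the
#' consumer's diet from item counts with uncertain body masses. Records after
#' `cutoff_date` are excluded (food eaten after the tissue stopped growing
#' does not contribute). In each bootstrap iteration every consumed item gets
#' an independent mass drawn Uniform(min_kg, max_kg) for its species, and the
#' diet proportion of a species is its total mass over the grand total.
#' Per-individual estimates are computed first and their 95% CIs checked for
#' overlap (a warning gate), then all records are pooled and the bootstrap is
#' repeated `B` times on the pooled item history.
#'
#' @param records A `feeding_records` data frame (columns `individual_id`,
#'   `species`, `date`, `count`); `date` may be absent if `cutoff_date` is
#'   `NULL`.
#' @param ranges A [mass_ranges()] table covering every species in `records`.
#' @param cutoff_date Last date (inclusive) contributing to the estimate, or
#'   `NULL` to use all records.
#' @param B Number of bootstrap iterations.
#' @param seed Optional RNG seed.
#' @param per_individual If `TRUE` (default), run the per-individual stage and
#'   warn when any species' 95% CIs fail to overlap across individuals.
#' @return An object of class `diet_estimate`: list with `mean`, `sd`, `ci`
#'   (2 x K percentile bounds), `draws` (B x K matrix of proportions),
#'   `species`, `per_individual` (per-individual mean and CI), `n_items`.
#' @examples
#' rec <- generate_feeding_records(c(deer = 106, beaver = 14, goose = 121),
#'                                 c("2011-06-07", "2011-10-31"), 10, seed = 1)
#' rng <- mass_ranges(c("deer", "beaver", "goose"), c(41, 5, 3), c(223, 35, 6))
#' bootstrap_diet(rec, rng, B = 200, seed = 1)
#' @export
bootstrap_diet <- function(records, ranges, cutoff_date = NULL, B = 1000L,
                           seed = NULL, per_individual = TRUE) {
  if (B < 1L) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rec <- as.data.frame(records)
  if (!is.null(cutoff_date)) {
    if (is.null(rec$date)) stop("records need a date column to apply a cutoff")
    rec <- rec[as.Date(rec$date) <= as.Date(cutoff_date), , drop = FALSE]
    if (nrow(rec) == 0L)
      stop("all feeding records fall after the cutoff date")
  }
  if (nrow(rec) == 0L) stop("no feeding records supplied")
  miss <- setdiff(unique(rec$species), ranges$species)
  if (length(miss))
    stop("no mass range for species: ", paste(miss, collapse = ", "))
  species <- ranges$species[ranges$species %in% rec$species]

  # expand counts into individual items
  idx <- rep(seq_len(nrow(rec)), rec$count)
  item_sp <- factor(rec$species[idx], levels = species)
  item_id <- rec$individual_id[idx]
  rmatch <- match(species, ranges$species)
  lo <- ranges$min_kg[rmatch][as.integer(item_sp)]
  hi <- ranges$max_kg[rmatch][as.integer(item_sp)]

  # one uniform mass per item per iteration; rowsum drops empty factor
  # levels, so rebuild the full K x B matrix before normalizing
  boot_props <- function(sel) {
    n <- sum(sel)
    m <- matrix(stats::runif(n * B, rep(lo[sel], B), rep(hi[sel], B)), n, B)
    tot <- rowsum(m, group = item_sp[sel], reorder = FALSE)
    full <- matrix(0, length(species), B, dimnames = list(species, NULL))
    full[rownames(tot), ] <- tot
    p <- sweep(full, 2L, colSums(full), "/")
    t(p)
  }

  indiv <- NULL
  if (per_individual && length(unique(item_id)) > 1L) {
    ids <- unique(item_id)
    indiv <- lapply(ids, function(id) {
      d <- boot_props(item_id == id)
      list(id = id, mean = colMeans(d),
           ci = apply(d, 2L, stats::quantile, probs = c(0.025, 0.975)))
    })
    names(indiv) <- ids
    for (k in seq_along(species)) {
      los <- vapply(indiv, function(s) s$ci[1L, k], 0)
      his <- vapply(indiv, function(s) s$ci[2L, k], 0)
      if (max(los) > min(his))
        warning("per-individual 95% CIs for '", species[k],
                "' do not all overlap; pooling anyway")
    }
  }

  draws <- boot_props(rep(TRUE, length(item_sp)))
  stopifnot(all(abs(rowSums(draws) - 1) < 1e-9))
  structure(list(
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    ci = apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975)),
    draws = draws, species = species, per_individual = indiv,
    n_items = length(item_sp), B = B), class = "diet_estimate")
}

#' @export
print.diet_estimate <- function(x, digits = 3, ...) {
  cat("Bootstrap diet estimate (", x$B, " iterations, ", x$n_items,
      " items)\n", sep = "")
  tab <- rbind(mean = x$mean, sd = x$sd, x$ci)
  print(round(tab, digits))
  invisible(x)
}

#' Dirichlet log-likelihood of a proportion matrix
#'
#' @param alpha Positive concentration vector.
#' @param draws B x K matrix of simplex rows (strictly positive).
#' @return Total log-likelihood.
#' @export
dirichlet_loglik <- function(alpha, draws) {
  draws <- rbind(draws)
  n <- nrow(draws)
  n * (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum(colSums(log(draws)) * (alpha - 1))
}

# Minka's inverse digamma: solve digamma(x) = y
inv_digamma <- function(y) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y - digamma(1)))
  for (i in 1:6) x <- x - (digamma(x) - y) / trigamma(x)
  x
}

#' Maximum-likelihood Dirichlet fit to proportion draws
#'
#' Fits the concentration vector alpha of a Dirichlet distribution to a matrix
#' of simplex draws (e.g. bootstrap diet proportions) by maximum likelihood:
#' moment-matched initialization, digamma fixed-point iterations, then Newton
#' polishing on the digamma system until the per-draw gradient norm falls
#' below `tol`. Zeros are clipped to `floor` and rows renormalized before
#' fitting.
#'
#' @param draws B x K matrix of proportions (rows sum to 1), or a
#'   `diet_estimate`.
#' @param floor Simplex floor applied to exact zeros.
#' @param tol Convergence tolerance on the infinity norm of the per-draw
#'   gradient.
#' @param max_iter Iteration cap.
#' @return A [dirichlet_spec()] with attributes `loglik` and `iterations`.
#' @export
fit_dirichlet_mle <- function(draws, floor = 1e-6, tol = 1e-8,
                              max_iter = 1000L) {
  if (inherits(draws, "diet_estimate")) draws <- draws$draws
  draws <- rbind(draws)
  K <- ncol(draws); n <- nrow(draws)
  if (n < K + 1L) stop("need at least K + 1 draws to fit a Dirichlet")
  draws[draws < floor] <- floor
  draws <- draws / rowSums(draws)
  if (any(apply(draws, 2L, stats::var) < 1e-14))
    stop("degenerate draws: at least one component has (near) zero variance; ",
         "Dirichlet MLE does not converge")
  logp <- colMeans(log(draws))
  m <- colMeans(draws); v <- apply(draws, 2L, stats::var)
  s0 <- stats::median(m * (1 - m) / v - 1)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  alpha <- m * s0

  grad <- function(a) digamma(sum(a)) - digamma(a) + logp
  for (it in seq_len(max_iter)) {
    g <- grad(alpha)
    if (max(abs(g)) < tol) {
      out <- dirichlet_spec(alpha, colnames(draws))
      attr(out, "loglik") <- dirichlet_loglik(alpha, draws)
      attr(out, "iterations") <- it
      return(out)
    }
    # Newton step with the diagonal-plus-rank-one Hessian
    q <- -trigamma(alpha)
    z <- trigamma(sum(alpha))
    b <- sum(g / q) / (1 / z + sum(1 / q))
    step <- (g - b) / q
    cand <- alpha - step
    if (all(cand > 0) && all(is.finite(cand))) {
      alpha <- cand
    } else {
      # fall back to the fixed-point update, which preserves positivity
      alpha <- inv_digamma(digamma(sum(alpha)) + logp)
    }
  }
  stop("Dirichlet MLE did not converge in ", max_iter,
       " iterations; final gradient norm ", signif(max(abs(grad(alpha))), 3))
}
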
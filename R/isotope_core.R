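#' tdfmix: trophic discrimination factors and prior sensitivity for Bayesian
#' stable isotope mixing models
#'
#' Bayesian stable isotope mixing models (SIMMs) infer the proportional
#' contribution of food sources to a consumer's diet from carbon and nitrogen
#' stable isotope values. This package implements the machinery of a
#' controlled-feeding-study analysis: a bootstrap estimate of diet composition
#' from feeding records ([bootstrap_diet()]), maximum-likelihood fitting of a
#' Dirichlet distribution to proportion draws ([fit_dirichlet_mle()]), a mixing
#' model that runs in two modes — estimating trophic discrimination factors
#' (TDFs) given a known diet, or estimating diet proportions given TDFs
#' ([simm()]) — a stepwise search for the minimum informative Dirichlet prior
#' ([minimum_informative_prior()]), and bias / Monte Carlo variance / mean
#' squared error evaluation of posterior diet estimates
#' ([evaluate_posterior()], [compare_models()]).
#'
#' @keywords internal
"_PACKAGE"

#' Default ordered isotope labels
#'
#' All matrices in the package index isotopes in a fixed, declared order.
#' The default is carbon then nitrogen.
#'
#' @return Character vector of isotope labels.
#' @export
default_isotopes <- function() c("d13C", "d15N")

#' Convert an isotope ratio to delta notation
#'
#' Expresses a heavy/light isotope ratio as the per-mil (permil) deviation from
#' an international standard: `delta = (r_sample / r_standard - 1) * 1000`.
#'
#' @param r_sample Sample isotope ratio (e.g. 13C/12C); must be > 0.
#' @param r_standard Standard isotope ratio; must be > 0. Recycled against
#'   `r_sample`.
#' @return Delta value(s) in permil.
#' @examples
#' delta_from_ratio(0.0112, 0.0112372)
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard))
    stop("ratios must be numeric")
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)))
    stop("ratios must be finite")
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be strictly positive")
  (r_sample / r_standard - 1) * 1000
}

#' Construct a table of isotope samples
#'
#' One row per measured individual, with delta values in permil for each
#' isotope. This is the long-form container behind [summarize_sources()].
#'
#' @param individual_id Character vector of individual identifiers.
#' @param species Character vector of species names.
#' @param tissue Character vector of tissue types (e.g. "muscle", "hair").
#' @param ... Named numeric vectors of delta values, one per isotope label
#'   (default labels `d13C`, `d15N`).
#' @return A `data.frame` of class `isotope_samples`.
#' @export
isotope_samples <- function(individual_id, species, tissue, ...) {
  deltas <- list(...)
  if (length(deltas) == 0L) stop("at least one isotope column is required")
  if (is.null(names(deltas)) || any(!nzchar(names(deltas))))
    stop("isotope columns must be named (e.g. d13C = ...)")
  out <- data.frame(individual_id = as.character(individual_id),
                    species = as.character(species),
                    tissue = as.character(tissue),
                    stringsAsFactors = FALSE)
  for (nm in names(deltas)) {
    v <- as.numeric(deltas[[nm]])
    if (any(!is.finite(v))) stop("delta values must be finite in column ", nm)
    out[[nm]] <- v
  }
  class(out) <- c("isotope_samples", "data.frame")
  out
}

#' Read an isotope sample table from CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `individual_id`,
#' `species`, `tissue`, plus one numeric column per isotope label.
#'
#' @param path Path to the CSV file.
#' @param isotopes Ordered isotope labels expected as columns.
#' @return An `isotope_samples` data frame.
#' @export
read_isotope_csv <- function(path, isotopes = default_isotopes()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("individual_id", "species", "tissue", isotopes)
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("isotope CSV is missing columns: ", paste(missing, collapse = ", "))
  do.call(isotope_samples,
          c(list(individual_id = d$individual_id, species = d$species,
                 tissue = d$tissue),
            stats::setNames(lapply(isotopes, function(j) d[[j]]), isotopes)))
}

#' Write an isotope sample table to CSV
#'
#' @param samples An `isotope_samples` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotope_csv <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Summarize source samples into per-species isotope distributions
#'
#' Computes the sample mean and sample SD (n - 1 denominator) of each isotope
#' for every (species, tissue) group. These summaries parameterize the normal
#' source distributions `s_jk ~ Normal(mu_jk, omega_jk^2)` of the mixing model.
#'
#' @param samples An `isotope_samples` data frame.
#' @param isotopes Ordered isotope labels to summarize.
#' @return A `source_table`: data frame with columns `species`, `tissue`,
#'   `isotope`, `mean`, `sd`, `n`.
#' @examples
#' s <- isotope_samples(c("a", "b"), "deer", "muscle", d13C = c(-24, -26),
#'                      d15N = c(4, 5))
#' summarize_sources(s)
#' @export
summarize_sources <- function(samples, isotopes = default_isotopes()) {
  if (!all(isotopes %in% names(samples)))
    stop("samples lack isotope columns: ",
         paste(setdiff(isotopes, names(samples)), collapse = ", "))
  key <- interaction(samples$species, samples$tissue, drop = TRUE, sep = " / ")
  rows <- lapply(levels(key), function(g) {
    sub <- samples[key == g, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("group '", g, "' has fewer than 2 samples; cannot estimate an SD")
    do.call(rbind, lapply(isotopes, function(j) {
      data.frame(species = sub$species[1L], tissue = sub$tissue[1L],
                 isotope = j, mean = mean(sub[[j]]), sd = stats::sd(sub[[j]]),
                 n = nrow(sub), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("source_table", "data.frame")
  out
}

#' Construct a source distribution table from summary statistics
#'
#' Builds the per-source, per-isotope normal summaries (`mu_jk`, `omega_jk`)
#' directly, for use when raw samples are unavailable but published means and
#' SDs are.
#'
#' @param species Character vector of K source names (order is kept).
#' @param mean J x K matrix of means (rows = isotopes) or a vector for J = 1.
#' @param sd J x K matrix of SDs, all >= 0.
#' @param n Optional sample counts per source (length K).
#' @param isotopes Ordered isotope labels (length J).
#' @param tissue Tissue label, recycled.
#' @return A `source_table` data frame.
#' @export
source_table <- function(species, mean, sd, n = NA_integer_,
                         isotopes = default_isotopes(), tissue = "muscle") {
  mean <- rbind(mean); sd <- rbind(sd)
  K <- length(species); J <- length(isotopes)
  if (!all(dim(mean) == c(J, K)) || !all(dim(sd) == c(J, K)))
    stop("mean and sd must be J x K (isotopes x sources)")
  if (any(sd < 0)) stop("source SDs must be non-negative")
  n <- rep_len(n, K)
  out <- do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(species = species[k], tissue = rep_len(tissue, K)[k],
               isotope = isotopes, mean = mean[, k], sd = sd[, k], n = n[k],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("source_table", "data.frame")
  out
}

# Internal: source_table -> list(mu = JxK, omega = JxK, species, isotopes)
source_matrices <- function(sources, isotopes = NULL, species = NULL) {
  stopifnot(is.data.frame(sources))
  if (is.null(isotopes)) isotopes <- unique(sources$isotope)
  if (is.null(species)) species <- unique(sources$species)
  mu <- matrix(NA_real_, length(isotopes), length(species),
               dimnames = list(isotopes, species))
  omega <- mu
  for (r in seq_len(nrow(sources))) {
    j <- match(sources$isotope[r], isotopes)
    k <- match(sources$species[r], species)
    if (is.na(j) || is.na(k)) next
    mu[j, k] <- sources$mean[r]
    omega[j, k] <- sources$sd[r]
  }
  if (any(is.na(mu)) || any(is.na(omega)))
    stop("sources must provide one (mean, sd) per isotope x species pair")
  list(mu = mu, omega = omega, species = species, isotopes = isotopes)
}

#' Construct a consumer isotope matrix
#'
#' @param x A numeric matrix (I consumers x J isotopes), a data frame with
#'   isotope columns, or an `isotope_samples` table filtered to the consumer.
#' @param isotopes Ordered isotope labels.
#' @return A numeric matrix with isotope column names, class `consumer_data`.
#' @export
consumer_data <- function(x, isotopes = default_isotopes()) {
  if (is.data.frame(x)) {
    if (!all(isotopes %in% names(x)))
      stop("consumer data frame lacks isotope columns: ",
           paste(setdiff(isotopes, names(x)), collapse = ", "))
    x <- as.matrix(x[, isotopes, drop = FALSE])
  }
  x <- as.matrix(x)
  if (ncol(x) != length(isotopes))
    stop("consumer matrix must have one column per isotope")
  colnames(x) <- isotopes
  if (any(!is.finite(x))) stop("consumer values must be finite (no missing cells)")
  if (nrow(x) < 1L) stop("at least one consumer is required")
  class(x) <- c("consumer_data", class(matrix()))
  x
}

#' Construct a trophic discrimination factor (TDF) set
#'
#' One mean and SD per isotope, shared across sources: the systematic offset
#' between consumer tissue and diet, with its uncertainty.
#'
#' @param mean Numeric vector of per-isotope TDF means (permil).
#' @param sd Numeric vector of per-isotope TDF SDs (permil, >= 0).
#' @param isotopes Ordered isotope labels.
#' @param label Provenance label (e.g. "wolf", "fox").
#' @return An object of class `tdf_set`.
#' @export
tdf_set <- function(mean, sd, isotopes = default_isotopes(), label = "tdf") {
  if (length(mean) != length(isotopes) || length(sd) != length(isotopes))
    stop("mean and sd must have one entry per isotope")
  if (any(sd < 0)) stop("TDF SDs must be non-negative")
  structure(list(mean = stats::setNames(as.numeric(mean), isotopes),
                 sd = stats::setNames(as.numeric(sd), isotopes),
                 isotopes = isotopes, label = label),
            class = "tdf_set")
}

#' @export
print.tdf_set <- function(x, ...) {
  cat("TDF set '", x$label, "':\n", sep = "")
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Construct a Dirichlet specification over diet sources
#'
#' @param alpha Numeric vector of strictly positive concentration parameters.
#' @param species Source names, one per alpha entry.
#' @return An object of class `dirichlet_spec`.
#' @export
dirichlet_spec <- function(alpha, species = names(alpha)) {
  force(species)
  alpha <- as.numeric(alpha)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("all Dirichlet alpha values must be finite and strictly positive")
  if (is.null(species)) species <- paste0("source", seq_along(alpha))
  if (length(species) != length(alpha))
    stop("species names must match the length of alpha")
  structure(list(alpha = stats::setNames(alpha, species), species = species),
            class = "dirichlet_spec")
}

#' @export
print.dirichlet_spec <- function(x, ...) {
  cat("Dirichlet prior: alpha = (",
      paste(formatC(x$alpha, format = "fg"), collapse = ", "), ") over ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mean of a Dirichlet specification
#' @param spec A `dirichlet_spec`.
#' @return Named vector of expected proportions.
#' @export
dirichlet_mean <- function(spec) spec$alpha / sum(spec$alpha)

#' Draw from a Dirichlet distribution
#'
#' Samples via normalized gammas.
#'
#' @param n Number of draws.
#' @param alpha Concentration vector (or a `dirichlet_spec`).
#' @return n x K matrix of simplex rows.
#' @export
rdirichlet <- function(n, alpha) {
  if (inherits(alpha, "dirichlet_spec")) alpha <- alpha$alpha
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  sw <- rowSums(g)
  out <- g / sw
  colnames(out) <- names(alpha)
  out
}

# Internal: Dirichlet log-density, rows of x on the simplex
ddirichlet_log <- function(x, alpha) {
  x <- rbind(x)
  lognorm <- lgamma(sum(alpha)) - sum(lgamma(alpha))
  lognorm + as.numeric(log(x) %*% (alpha - 1))
}

# Internal: deterministic sub-stream seeds below 2^31
derive_seed <- function(seed, stage, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 7919 + stage * 104729 + k * 1299721) %%
               2147483629)
}
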
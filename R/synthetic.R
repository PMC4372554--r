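#' Construct a species body-mass range table
#'
#' Minimum and maximum body mass per species, used to draw uniform per-item
#' masses in the diet bootstrap.
#'
#' @param species Character vector of species names.
#' @param min_kg,max_kg Numeric vectors, 0 < min_kg <= max_kg.
#' @return A data frame of class `mass_ranges`.
#' @export
mass_ranges <- function(species, min_kg, max_kg) {
  min_kg <- as.numeric(min_kg); max_kg <- as.numeric(max_kg)
  if (length(min_kg) != length(species) || length(max_kg) != length(species))
    stop("min_kg and max_kg must have one entry per species")
  if (any(min_kg <= 0) || any(max_kg < min_kg))
    stop("mass ranges require 0 < min_kg <= max_kg")
  out <- data.frame(species = as.character(species), min_kg = min_kg,
                    max_kg = max_kg, stringsAsFactors = FALSE)
  class(out) <- c("mass_ranges", "data.frame")
  out
}

#' Generate synthetic feeding records
#'
#' Distributes a requested number of consumed items per species across
#' individuals and dates. Each item becomes one count-1 record with an
#' individual chosen uniformly at random and a date uniform in the window, so
#' the per-species totals always equal the requested counts.
#'
#' @param counts Named integer vector: items consumed per species.
#' @param window Length-2 `Date` (or coercible) vector: first and last feeding
#'   date, inclusive.
#' @param n_individuals Number of consumers to spread items over.
#' @param seed Optional RNG seed.
#' @return A data frame of class `feeding_records` with columns
#'   `individual_id`, `species`, `date`, `count`.
#' @examples
#' generate_feeding_records(c(deer = 5, goose = 2),
#'                          c("2011-06-07", "2011-10-31"), 3, seed = 1)
#' @export
generate_feeding_records <- function(counts, window, n_individuals,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- round(counts)
  if (any(counts < 0)) stop("species counts must be non-negative")
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  window <- as.Date(window)
  if (length(window) != 2L || any(is.na(window)) || window[2L] < window[1L])
    stop("date window must be two ordered dates")
  total <- sum(counts)
  ids <- sprintf("ind%02d", seq_len(n_individuals))
  if (total == 0L) {
    out <- data.frame(individual_id = character(0), species = character(0),
                      date = as.Date(character(0)), count = integer(0))
  } else {
    species <- rep(names(counts), counts)
    days <- as.integer(window[2L] - window[1L])
    out <- data.frame(
      individual_id = sample(ids, total, replace = TRUE),
      species = species,
      date = window[1L] + sample.int(days + 1L, total, replace = TRUE) - 1L,
      count = 1L, stringsAsFactors = FALSE)
    out <- out[order(out$date, out$individual_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("feeding_records", "data.frame")
  out
}

#' Read / write feeding records as CSV
#'
#' Columns: `individual_id`, `species`, `date` (ISO-8601), `count`.
#'
#' @param path CSV path.
#' @return `read_feeding_csv()` returns a `feeding_records` data frame;
#'   `write_feeding_csv()` returns `path` invisibly.
#' @export
read_feeding_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("individual_id", "species", "date", "count")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("feeding CSV is missing columns: ", paste(missing, collapse = ", "))
  d$date <- as.Date(d$date)
  if (any(is.na(d$date))) stop("dates must be ISO-8601 (YYYY-MM-DD)")
  d$count <- as.integer(d$count)
  if (any(d$count < 1L)) stop("counts must be >= 1")
  class(d) <- c("feeding_records", "data.frame")
  d
}

#' @rdname read_feeding_csv
#' @param records A `feeding_records` data frame.
#' @export
write_feeding_csv <- function(records, path) {
  d <- as.data.frame(records)
  d$date <- format(d$date)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Define a synthetic mixing-model scenario
#'
#' Bundles the true diet proportions, source distributions, TDFs, residual
#' SDs, and consumer sample size that drive [generate_isotope_dataset()].
#'
#' @param p True diet proportions (non-negative, summing to 1; names taken as
#'   source species when present).
#' @param sources A `source_table` over the same species.
#' @param tdf A `tdf_set` (means shift the consumer mixture; SDs unused in
#'   generation, which conditions on the stated TDF means).
#' @param n_consumers Number of consumers I.
#' @param sigma Per-isotope residual SDs (>= 0).
#' @param seed Master seed for the scenario.
#' @param n_source_samples Samples drawn per source when emitting raw source
#'   tables.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(p, sources, tdf, n_consumers = 10L,
                               sigma = c(0.5, 0.25), seed = 1L,
                               n_source_samples = 15L) {
  p <- as.numeric(p) / 1
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("true proportions must be non-negative and sum to 1")
  sm <- source_matrices(sources)
  if (length(p) != length(sm$species))
    stop("length of p must match the number of sources")
  if (length(sigma) != length(sm$isotopes))
    stop("sigma must have one entry per isotope")
  if (any(sigma < 0)) stop("residual SDs must be non-negative")
  structure(list(p = stats::setNames(p, sm$species), sources = sources,
                 tdf = tdf, n_consumers = as.integer(n_consumers),
                 sigma = stats::setNames(as.numeric(sigma), sm$isotopes),
                 seed = as.integer(seed),
                 n_source_samples = as.integer(n_source_samples)),
            class = "synthetic_scenario")
}

#' Generate a synthetic isotope dataset from a scenario
#'
#' Consumers are drawn from the marginal normal the mixing model assumes:
#' mean `sum_k p_k (mu_jk + c_j)` and variance
#' `sum_k p_k^2 omega_jk^2 + sigma_j^2` per isotope j. Source samples are
#' drawn `Normal(mu_jk, omega_jk^2)`. Sub-stream seeds are derived
#' deterministically from the scenario seed, so the whole dataset is
#' reproducible.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `consumers` (a `consumer_data` matrix) and
#'   `source_samples` (an `isotope_samples` data frame).
#' @export
generate_isotope_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sm <- source_matrices(scenario$sources)
  J <- length(sm$isotopes); K <- length(sm$species)
  p <- scenario$p
  cj <- scenario$tdf$mean[sm$isotopes]
  mix_mean <- as.numeric(sm$mu %*% p) + cj
  mix_var <- as.numeric((sm$omega^2) %*% (p^2)) + scenario$sigma^2

  set.seed(derive_seed(scenario$seed, 1L))
  X <- vapply(seq_len(J), function(j)
    stats::rnorm(scenario$n_consumers, mix_mean[j], sqrt(mix_var[j])),
    numeric(scenario$n_consumers))
  consumers <- consumer_data(
    matrix(X, nrow = scenario$n_consumers,
           dimnames = list(NULL, sm$isotopes)), isotopes = sm$isotopes)

  set.seed(derive_seed(scenario$seed, 2L))
  ns <- scenario$n_source_samples
  src <- do.call(rbind, lapply(seq_len(K), function(k) {
    vals <- lapply(seq_len(J), function(j)
      stats::rnorm(ns, sm$mu[j, k], sm$omega[j, k]))
    d <- data.frame(individual_id = sprintf("%s%03d", sm$species[k],
                                            seq_len(ns)),
                    species = sm$species[k], tissue = "muscle",
                    stringsAsFactors = FALSE)
    for (j in seq_len(J)) d[[sm$isotopes[j]]] <- vals[[j]]
    d
  }))
  rownames(src) <- NULL
  class(src) <- c("isotope_samples", "data.frame")
  list(consumers = consumers, source_samples = src)
}
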
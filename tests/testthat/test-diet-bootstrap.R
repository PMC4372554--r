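captive_records <- function(seed = 1) {
  inp <- captive_study_inputs()
  list(inp = inp,
       rec = generate_feeding_records(inp$counts, inp$window,
                                      inp$n_consumers, seed = seed))
}

test_that("bootstrap means match the closed-form midpoint-mass expectation", {
  cr <- captive_records()
  bd <- suppressWarnings(
    bootstrap_diet(cr$rec, cr$inp$mass_ranges, B = 1000, seed = 2))
  # oracle: with per-item masses uniform on (lo, hi), the expected species
  # biomass is count * midpoint, giving 132*106 : 20*14 : 4.5*121
  mid <- with(cr$inp$mass_ranges, (min_kg + max_kg) / 2)
  counts <- cr$inp$counts[cr$inp$mass_ranges$species]
  oracle <- mid * counts / sum(mid * counts)
  expect_equal(unname(bd$mean), unname(oracle), tolerance = 0.003)
  expect_true(all(abs(rowSums(bd$draws) - 1) < 1e-9))
  expect_true(all(bd$mean >= 0 & bd$mean <= 1))
})

test_that("a single-species history gives proportion exactly 1 with SD 0", {
  rec <- generate_feeding_records(c(deer = 12), c("2011-06-07", "2011-06-30"),
                                  2, seed = 3)
  bd <- bootstrap_diet(rec, mass_ranges("deer", 41, 223), B = 50, seed = 4)
  expect_equal(unname(bd$mean), 1)
  expect_equal(unname(bd$sd), 0)
})

test_that("bootstrap means are invariant to rescaling all mass ranges", {
  cr <- captive_records(seed = 5)
  r1 <- cr$inp$mass_ranges
  r10 <- mass_ranges(r1$species, r1$min_kg * 10, r1$max_kg * 10)
  a <- suppressWarnings(bootstrap_diet(cr$rec, r1, B = 300, seed = 6))
  b <- suppressWarnings(bootstrap_diet(cr$rec, r10, B = 300, seed = 6))
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
})

test_that("cutoff excludes late records and error paths are guarded", {
  rec <- data.frame(individual_id = "w1", species = "deer",
                    date = as.Date(c("2011-07-01", "2011-12-01")),
                    count = c(3L, 50L))
  rng <- mass_ranges(c("deer", "goose"), c(41, 3), c(223, 6))
  bd <- bootstrap_diet(rec, rng, cutoff_date = "2011-10-31", B = 20, seed = 1)
  expect_equal(bd$n_items, 3L)
  expect_error(bootstrap_diet(rec, rng, cutoff_date = "2011-01-01", B = 20),
               "cutoff")
  expect_error(bootstrap_diet(rec, mass_ranges("goose", 3, 6),
                              cutoff_date = "2011-10-31", B = 20), "deer")
})

test_that("disjoint per-individual diets trigger the CI-overlap warning", {
  rec <- data.frame(individual_id = rep(c("w1", "w2"), each = 5),
                    species = rep(c("deer", "goose"), each = 5),
                    date = as.Date("2011-07-01"), count = 1L)
  rng <- mass_ranges(c("deer", "goose"), c(41, 3), c(223, 6))
  expect_warning(bootstrap_diet(rec, rng, B = 50, seed = 2), "overlap")
})

test_that("Dirichlet MLE recovers generating alpha from large samples", {
  set.seed(31)
  d <- rdirichlet(20000, c(5, 3, 2))
  fit <- fit_dirichlet_mle(d)
  expect_true(all(abs(fit$alpha / c(5, 3, 2) - 1) < 0.05))

  d1 <- rdirichlet(20000, c(1, 1, 1))
  fit1 <- fit_dirichlet_mle(d1)
  expect_true(all(abs(fit1$alpha - 1) < 0.05))
})

test_that("fitted Dirichlet mean matches the empirical draw mean", {
  set.seed(32)
  d <- rdirichlet(10000, c(8, 2, 4))
  fit <- fit_dirichlet_mle(d)
  expect_equal(unname(dirichlet_mean(fit)), unname(colMeans(d)),
               tolerance = 1e-3)
})

test_that("MLE log-likelihood dominates the moment-matched initializer", {
  set.seed(33)
  d <- rdirichlet(3000, c(10, 3, 1.5))
  fit <- fit_dirichlet_mle(d)
  m <- colMeans(d); v <- apply(d, 2, var)
  s0 <- median(m * (1 - m) / v - 1)
  expect_gte(attr(fit, "loglik"), dirichlet_loglik(m * s0, d))
})

test_that("degenerate or undersized draw sets are rejected", {
  same <- matrix(rep(c(0.6, 0.3, 0.1), each = 50), 50, 3)
  expect_error(fit_dirichlet_mle(same), "degenerate")
  expect_error(fit_dirichlet_mle(rdirichlet(3, c(1, 1, 1))), "draws")
})
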
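diet_spec_fixture <- function(seed = 1, I = 20) {
  ds <- generate_isotope_dataset(toy_scenario(I = I, seed = seed,
                                              tdf = tdf_set(c(1.5, 3.0),
                                                            c(0.2, 0.1))))
  simm_spec(toy_sources(), ds$consumers, mode = "diet",
            tdf = tdf_set(c(1.5, 3.0), c(0.2, 0.1)),
            prior = dirichlet_spec(c(A = 1, B = 1, C = 1)))
}

tdf_spec_fixture <- function(seed = 2, I = 20) {
  ds <- generate_isotope_dataset(toy_scenario(I = I, seed = seed))
  simm_spec(toy_sources(), ds$consumers, mode = "tdf",
            diet = dirichlet_spec(c(A = 50, B = 30, C = 20)))
}

test_that("log posterior matches an independent density evaluator", {
  for (s in 1:10) {
    spec <- diet_spec_fixture(seed = s)
    st <- random_state(spec, seed = 100 + s)
    expect_equal(simm_log_posterior(spec, st), oracle_log_posterior(spec, st),
                 tolerance = 1e-10)
  }
  for (s in 1:10) {
    spec <- tdf_spec_fixture(seed = s)
    st <- random_state(spec, seed = 200 + s)
    expect_equal(simm_log_posterior(spec, st), oracle_log_posterior(spec, st),
                 tolerance = 1e-10)
  }
})

test_that("states outside the support have log density -Inf", {
  spec <- tdf_spec_fixture()
  ok <- random_state(spec, 1)
  bad_p <- ok; bad_p$p <- c(0.7, 0.2, 0.2)
  expect_identical(simm_log_posterior(spec, bad_p), -Inf)
  bad_c <- ok; bad_c$c <- c(11, 3)
  expect_identical(simm_log_posterior(spec, bad_c), -Inf)
  bad_s <- ok; bad_s$sigma <- c(-0.1, 0.5)
  expect_identical(simm_log_posterior(spec, bad_s), -Inf)
})

test_that("at a simplex vertex the mixture mean reduces to mu_j1 + c_j", {
  spec <- tdf_spec_fixture()
  pc <- tdfmix:::simm_precompute(spec)
  cvec <- c(1.2, 2.4); sigma <- c(0.5, 0.5)
  ll <- tdfmix:::simm_loglik(pc, c(1, 0, 0), cvec, sigma)
  X <- unclass(spec$consumers)
  direct <- 0
  for (j in 1:2) {
    m <- spec$mu[j, 1] + cvec[j]
    v <- spec$omega[j, 1]^2 + sigma[j]^2
    direct <- direct + sum(dnorm(X[, j], m, sqrt(v), log = TRUE))
  }
  expect_equal(ll, direct, tolerance = 1e-12)
})

test_that("Gelman-Rubin diagnostic follows the between/within formula", {
  set.seed(5)
  ch <- rnorm(400)
  expect_lte(gelman_rubin(list(ch, ch, ch)), 1 + 1e-6)

  c1 <- rnorm(1000, 0, 1); c2 <- rnorm(1000, 5, 1)
  psrf <- gelman_rubin(list(c1, c2))
  n <- 1000
  W <- mean(c(var(c1), var(c2)))
  B_n <- var(c(mean(c1), mean(c2)))
  expect_equal(psrf, sqrt(((n - 1) / n * W + B_n) / W), tolerance = 1e-12)
  expect_gt(psrf, 1.1)
  expect_error(gelman_rubin(list(c1)), "2 chains")
})

test_that("sampling is deterministic under a fixed seed", {
  spec <- diet_spec_fixture()
  mc <- quick_mcmc(burn_in = 300, n_samples = 300, thin = 3, n_chains = 2)
  f1 <- simm(spec, mcmc = mc, seed = 77)
  f2 <- simm(spec, mcmc = mc, seed = 77)
  expect_identical(f1$draws, f2$draws)
  f3 <- simm(spec, mcmc = mc, seed = 78)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior draws respect the simplex and prior supports", {
  fit <- simm(tdf_spec_fixture(), mcmc = quick_mcmc(1000, 600, 2), seed = 3)
  expect_equal(rowSums(fit$draws$p), rep(1, nrow(fit$draws$p)),
               tolerance = 1e-12)
  expect_true(all(fit$draws$c > 0 & fit$draws$c < 10))
  expect_true(all(fit$draws$sigma > 0 & fit$draws$sigma < 10))
  expect_equal(nrow(fit$draws$p), 3 * 300) # n_samples / thin per chain
})

test_that("a point-mass diet with tight sources pins the TDF at xbar - mu", {
  src <- source_table(c("A", "B"),
                      mean = rbind(d13C = c(-24, -12), d15N = c(3, 11)),
                      sd = rbind(d13C = c(0, 0), d15N = c(0, 0)))
  set.seed(9)
  X <- cbind(d13C = rnorm(15, -24 + 2.0, 0.05),
             d15N = rnorm(15, 3 + 3.2, 0.05))
  fit <- simm(src, X, mode = "tdf",
              diet = dirichlet_spec(c(A = 1e6, B = 1)),
              mcmc = quick_mcmc(2000, 1000, 2), seed = 10)
  expect_equal(unname(coef(fit)),
               unname(colMeans(X) - c(-24, 3)), tolerance = 0.1)
})

test_that("diet-mode posterior means are equivariant to source relabeling", {
  ds <- generate_isotope_dataset(toy_scenario(I = 40, seed = 4))
  perm <- c(3, 1, 2)
  src <- toy_sources()
  src_perm <- source_table(c("C", "A", "B"),
                           mean = rbind(d13C = c(-12, -24, -18),
                                        d15N = c(4, 3, 9)),
                           sd = rbind(d13C = rep(0.8, 3),
                                      d15N = rep(0.6, 3)))
  tdf <- tdf_set(c(1.5, 3.0), c(0, 0))
  flat3 <- function(nm) dirichlet_spec(rep(1, 3), nm)
  mc <- quick_mcmc(4000, 3000, 3)
  f1 <- simm(src, ds$consumers, mode = "diet", tdf = tdf,
             prior = flat3(c("A", "B", "C")), mcmc = mc, seed = 5)
  f2 <- simm(src_perm, ds$consumers, mode = "diet", tdf = tdf,
             prior = flat3(c("C", "A", "B")), mcmc = mc, seed = 6)
  expect_equal(coef(f2)[c("A", "B", "C")], coef(f1), tolerance = 0.04)
})

test_that("diet-mode recovery: truth within 3 posterior SDs on synthetics", {
  ds <- generate_isotope_dataset(toy_scenario(I = 50, seed = 12))
  fit <- simm(toy_sources(), ds$consumers, mode = "diet",
              tdf = tdf_set(c(1.5, 3.0), c(0, 0)),
              prior = dirichlet_spec(c(A = 1, B = 1, C = 1)),
              mcmc = quick_mcmc(), seed = 13)
  post_sd <- apply(fit$draws$p, 2, sd)
  expect_true(all(abs(coef(fit) - c(A = 0.5, B = 0.3, C = 0.2)) <
                    3 * post_sd))
})

test_that("posterior SDs shrink as the consumer sample grows", {
  mean_sd <- function(I) {
    mean(sapply(1:3, function(s) {
      ds <- generate_isotope_dataset(toy_scenario(I = I, seed = 40 + s))
      fit <- simm(toy_sources(), ds$consumers, mode = "diet",
                  tdf = tdf_set(c(1.5, 3.0), c(0, 0)),
                  prior = dirichlet_spec(c(A = 1, B = 1, C = 1)),
                  mcmc = quick_mcmc(2000, 1200, 2), seed = s)
      mean(apply(fit$draws$p, 2, sd))
    }))
  }
  expect_gt(mean_sd(8), mean_sd(64))
})

test_that("an infeasible model errors at initialization", {
  src <- source_table("only", mean = rbind(d13C = -20, d15N = 5),
                      sd = rbind(d13C = 0, d15N = 0))
  X <- cbind(d13C = c(-18, -17), d15N = c(6, 7))
  expect_error(
    simm(src, X, mode = "tdf", diet = dirichlet_spec(c(only = 1)),
         residual = FALSE, mcmc = quick_mcmc(100, 100, 1), seed = 1),
    "initialization")
})

test_that("model methods expose fitted values, residuals, and simulation", {
  spec <- diet_spec_fixture(I = 25)
  fit <- simm(spec, mcmc = quick_mcmc(800, 600, 2), seed = 21)
  s <- summary(fit)
  expect_s3_class(s, "summary.simm")
  expect_true(all(c("p[A]", "sigma[d13C]") %in% s$parameter))
  expect_equal(dim(fitted(fit)), dim(unclass(spec$consumers)))
  expect_equal(residuals(fit), unclass(spec$consumers) - fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(dim(sims[[1]]), c(25, 2))
  expect_equal(unname(coef(fit)), unname(colMeans(posterior_draws(fit, "p"))))
})
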
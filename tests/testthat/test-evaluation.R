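test_that("identical posterior and reference draw sets give zero bias", {
  set.seed(1)
  d <- rdirichlet(1000, c(deer = 10, beaver = 3, goose = 2))
  ev <- evaluate_posterior(d, d, n = 1000, seed = 2)
  expect_equal(unname(ev$bias), rep(0, 3), tolerance = 1e-12)
  expect_equal(ev$mse, ev$variance, tolerance = 1e-12)
  expect_true(all(ev$overlaps_zero))
})

test_that("a degenerate posterior against a fixed point has zero variance", {
  post <- matrix(rep(c(0.6, 0.3, 0.1), each = 1200), 1200, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  ref <- matrix(rep(c(0.9, 0.05, 0.05), each = 1200), 1200, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  ev <- evaluate_posterior(post, ref, n = 1000, seed = 3)
  expect_equal(unname(ev$variance), rep(0, 3))
  expect_equal(ev$mse, ev$bias^2)
  expect_equal(unname(ev$bias), c(-0.3, 0.25, 0.05), tolerance = 1e-12)
})

test_that("MSE decomposes exactly into variance plus squared bias", {
  set.seed(4)
  post <- rdirichlet(3000, c(x = 4, y = 2, z = 1))
  ref <- dirichlet_spec(c(x = 40, y = 20, z = 10))
  ev <- evaluate_posterior(post, ref, n = 1000, seed = 5)
  expect_equal(ev$mse, ev$variance + ev$bias^2, tolerance = 1e-12)
  expect_true(all(ev$variance >= 0))
})

test_that("metrics are equivariant to source reordering", {
  set.seed(6)
  post <- rdirichlet(2000, c(a = 6, b = 3, c = 1))
  refa <- c(a = 120, b = 60, c = 20)
  perm <- c("c", "a", "b")
  ev1 <- evaluate_posterior(post, dirichlet_spec(refa), n = 1000, seed = 7)
  ev2 <- evaluate_posterior(post[, perm], dirichlet_spec(refa[perm]),
                            n = 1000, seed = 7)
  rownames(ev1) <- ev1$source; rownames(ev2) <- ev2$source
  for (col in c("bias", "variance", "mse"))
    expect_equal(ev2[perm, col], ev1[perm, col], tolerance = 0.02)
})

test_that("requesting more pairs than draws is an error", {
  post <- rdirichlet(500, c(a = 2, b = 2))
  expect_error(evaluate_posterior(post, dirichlet_spec(c(a = 2, b = 2)),
                                  n = 1000), "only")
  expect_error(evaluate_posterior(rdirichlet(1500, c(a = 2, b = 2)),
                                  post, n = 1000), "fewer")
})

test_that("bias vanishes as the prior concentrates at the truth", {
  # along an increasingly informative schedule the posterior tracks the
  # reference, so |bias| against the reference shrinks
  ds <- generate_isotope_dataset(toy_scenario(p = c(0.70, 0.18, 0.12),
                                              I = 30, seed = 9))
  ref_alpha <- c(A = 700, B = 180, C = 120)
  bias_at <- function(alpha) {
    fit <- simm(toy_sources(), ds$consumers, mode = "diet",
                tdf = tdf_set(c(1.5, 3.0), c(0, 0)),
                prior = dirichlet_spec(alpha, c("A", "B", "C")),
                mcmc = quick_mcmc(2000, 1200, 2), seed = 10)
    max(abs(evaluate_posterior(fit, dirichlet_spec(ref_alpha),
                               n = 1000, seed = 11)$bias))
  }
  expect_lt(bias_at(c(350, 90, 60)), bias_at(c(1, 1, 1)))
})

test_that("comparing a baseline to itself gives null differences", {
  set.seed(12)
  base <- rdirichlet(1500, c(a = 5, b = 3, c = 2))
  tab <- compare_models(list(self = base), base, n = 1500, seed = 13)
  expect_equal(unname(tab$bias), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(tab$variance_diff), rep(0, 3), tolerance = 1e-12)
  expect_true(all(tab$overlaps_zero))
})

test_that("compare_models rejects mismatched source sets", {
  base <- rdirichlet(1200, c(a = 5, b = 3, c = 2))
  other <- rdirichlet(1200, c(x = 5, y = 3, z = 2))
  expect_error(compare_models(list(m = other), base, n = 1000),
               "different sources")
})
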
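test_that("candidate schedule caps phase 1 at the rounded top/second ratio", {
  sched <- candidate_schedule(c(deer = 0.941, beaver = 0.020, goose = 0.039),
                              n_scale = 3)
  phases <- vapply(sched, attr, 0L, "phase")
  phase1 <- sched[phases == 1L]
  expect_equal(length(phase1), 24L) # rounded 0.941 / 0.039
  expect_equal(as.numeric(phase1[[24]]), c(24, 1, 1))
  expect_true(all(vapply(phase1, function(a) all(a[c(2, 3)] == 1), TRUE)))
  # precision increases along the schedule
  conc <- vapply(sched, sum, 0)
  expect_true(all(diff(conc) >= 0))
})

test_that("a symmetric two-source diet goes straight to proportional scaling", {
  sched <- candidate_schedule(c(a = 0.5, b = 0.5), n_scale = 3)
  expect_equal(as.numeric(sched[[1]]), c(1, 1))
  expect_equal(vapply(sched, attr, 0L, "phase"), c(1L, 3L, 3L, 3L))
  expect_equal(as.numeric(sched[[2]]), c(2, 2))
  expect_identical(sched, candidate_schedule(c(a = 0.5, b = 0.5),
                                             n_scale = 3))
  expect_error(candidate_schedule(c(a = 1)), "2 sources")
})

test_that("equivalence test passes on self-comparison and separates
           disjoint distributions", {
  alpha <- c(deer = 582.1, beaver = 12.4, goose = 24.3)
  set.seed(1)
  post <- rdirichlet(2000, alpha)
  res <- equivalence_test(post, dirichlet_spec(alpha), seed = 2)
  expect_true(res$pass)
  expect_true(all(res$ci[1, ] <= 0 & res$ci[2, ] >= 0))

  far <- rdirichlet(2000, c(deer = 500, beaver = 1, goose = 1))
  res2 <- equivalence_test(far, dirichlet_spec(c(deer = 333, beaver = 333,
                                                 goose = 333)), seed = 3)
  expect_false(res2$pass)
  expect_false(any(res2$per_source))
})

test_that("equivalence test validates names and draw counts", {
  post <- rdirichlet(1500, c(a = 2, b = 2))
  expect_error(equivalence_test(post, dirichlet_spec(c(x = 2, y = 2))),
               "names differ")
  expect_error(equivalence_test(post[1:100, ], dirichlet_spec(c(a = 2, b = 2))),
               "fewer")
})

test_that("self-comparison pass rate is at least 95% across seeds", {
  alpha <- c(a = 582.1, b = 12.4, c = 24.3)
  ref <- dirichlet_spec(alpha)
  passes <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    equivalence_test(rdirichlet(1000, alpha), ref, seed = s)$pass
  }, TRUE)
  expect_gte(mean(passes), 0.95)
})

test_that("search returns the non-informative prior when it already passes", {
  ds <- generate_isotope_dataset(toy_scenario(I = 40, seed = 6))
  spec <- simm_spec(toy_sources(), ds$consumers, mode = "diet",
                    tdf = tdf_set(c(1.5, 3.0), c(0, 0)),
                    prior = dirichlet_spec(c(A = 1, B = 1, C = 1)))
  # a deliberately diffuse reference: wide difference CIs overlap zero at once
  tr <- minimum_informative_prior(spec,
                                  dirichlet_spec(c(A = 2, B = 1.5, C = 1)),
                                  mcmc = quick_mcmc(1500, 1000, 1, 2),
                                  seed = 4)
  expect_equal(unname(tr$selected), c(1, 1, 1))
  expect_equal(nrow(tr$trace), 1L)
  expect_true(tr$trace$pass[1])
  expect_s3_class(tr$fit, "simm")
})

test_that("the selected prior is minimal within the schedule", {
  # reference concentrated away from the likelihood so early candidates fail
  ds <- generate_isotope_dataset(toy_scenario(p = c(0.70, 0.18, 0.12),
                                              I = 25, seed = 8))
  spec <- simm_spec(toy_sources(), ds$consumers, mode = "diet",
                    tdf = tdf_set(c(1.5, 3.0), c(0, 0)),
                    prior = dirichlet_spec(c(A = 1, B = 1, C = 1)))
  ref <- dirichlet_spec(c(A = 3500, B = 900, C = 600))
  tr <- tryCatch(
    minimum_informative_prior(spec, ref, mcmc = quick_mcmc(1500, 1000, 1, 2),
                              seed = 5),
    error = function(e) e)
  if (inherits(tr, "prior_search_trace")) {
    n <- nrow(tr$trace)
    expect_true(tr$trace$pass[n])
    if (n > 1) expect_false(any(tr$trace$pass[-n]))
  } else {
    # no candidate passed: the error must carry the full audit trace
    expect_s3_class(tr$trace, "data.frame")
    expect_false(any(tr$trace$pass))
  }
})
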
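test_that("generation is a pure function of the seed", {
  a <- generate_instance(synth_config(seed = 99))
  b <- generate_instance(synth_config(seed = 99))
  expect_identical(a, b)
  c <- generate_instance(synth_config(seed = 100))
  expect_false(identical(a, c))
  # generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_instance(synth_config(seed = 1)))
  expect_identical(rnorm(1), before)
})

test_that("every generated instance is valid; single-type mix is degenerate", {
  for (s in 1:100) {
    inst <- generate_instance(synth_config(seed = s,
                                           n_types = 1L + s %% 3L,
                                           horizon = 1L + s %% 5L))
    expect_length(validate_instance(inst), 0)
  }
  one <- generate_instance(synth_config(seed = 7, n_types = 1L))
  expect_equal(one$patient_types[[1]]$mix_lower, 0)
  expect_equal(one$patient_types[[1]]$mix_upper, 1)
})

test_that("brute force refuses oversized spaces and solves the n=0 case", {
  big <- base_instance()
  expect_error(brute_force_optimum(big), "exceeds")
  inst <- modify_instance(tiny_instance(11), admission_cap = 0)
  bf <- brute_force_optimum(inst)
  expect_true(all(bf$x == 0))
  idle <- sum(vapply(inst$resources, function(r)
    r$cost_neg * sum(rep(r$target, length.out = inst$horizon)), 0))
  expect_equal(bf$objective, -idle, tolerance = 1e-9)
})

test_that("deterministic LOS makes simulated census exact with zero variance", {
  x <- matrix(c(3, 0, 2, 1, 4, 0), 2, 3, byrow = TRUE)
  pmfs <- list(los_pmf(c(1, 0, 0)), los_pmf(c(1, 0, 0)))
  sim <- simulate_census(x, pmfs, reps = 50, seed = 4)
  expect_equal(sim$mean, x, ignore_attr = TRUE)
  expect_true(all(sim$se == 0))
})

test_that("simulated census matches the binomial expectation", {
  # 2 admissions on day 1, P(stay > 1) = 0.5: day-2 census ~ Binomial(2, .5)
  x <- matrix(c(2, 0, 0), 1)
  sim <- simulate_census(x, list(los_survival(c(1, 0.5, 0))),
                         reps = 4000, seed = 11)
  expect_equal(sim$mean[1, 1], 2)
  expect_lt(abs(sim$mean[1, 2] - 1), 3 * sim$se[1, 2])
  expect_equal(sim$mean[1, 3], 0)
})

test_that("Monte-Carlo error shrinks like one over the square root of reps", {
  x <- matrix(c(5, 3, 0, 2), 1)
  surv <- los_survival(c(1, 0.8, 0.5, 0.2))
  lo <- simulate_census(x, list(surv), reps = 200, seed = 2)
  hi <- simulate_census(x, list(surv), reps = 3200, seed = 2)
  ratio <- mean(lo$se[lo$se > 0] / hi$se[hi$se > 0])
  expect_gt(ratio, 2.5)  # sqrt(16) = 4 in expectation
  expect_lt(ratio, 6)
})
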
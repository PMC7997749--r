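test_that("pmf/survival conversions match hand computations and invert", {
  expect_equal(unclass(survival_from_pmf(c(0.5, 0.5))), c(1, 0.5))
  expect_equal(unclass(pmf_from_survival(c(1, 0.5))), c(0.5, 0.5))
  # all mass on day 1: survival collapses after day 0
  expect_equal(unclass(survival_from_pmf(c(1, 0, 0))), c(1, 0, 0))
  # truncated mass: final pmf entry absorbs stays beyond the horizon
  expect_equal(unclass(pmf_from_survival(c(1, 0.6, 0.3))), c(0.4, 0.3, 0.3))

  for (seed in 1:25) {
    inst <- tiny_instance(seed, n_types = 2L, horizon = 4L)
    for (p in inst$patient_types) {
      surv <- p$survival
      expect_equal(unclass(survival_from_pmf(pmf_from_survival(surv))),
                   unclass(surv), tolerance = 1e-12)
    }
  }
})

test_that("conversion round-trips the packaged survival columns exactly", {
  inst <- base_instance()
  for (p in inst$patient_types) {
    back <- survival_from_pmf(pmf_from_survival(p$survival))
    expect_equal(unclass(back), unclass(p$survival))
  }
  # spot value from the type III column: P(LOS = 5) = 0.93 - 0.90
  p3 <- pmf_from_survival(inst$patient_types[[3]]$survival)
  expect_equal(unclass(p3)[5], 0.03, tolerance = 1e-12)
})

test_that("invalid curves are rejected", {
  expect_error(los_survival(c(1, 0.5, 0.7)), "nonincreasing")
  expect_error(los_survival(c(0.9, 0.5)), "start at 1")
  expect_error(los_pmf(c(0.7, 0.6)), "more than 1")
  expect_error(los_pmf(c(-0.1, 0.5)), "negative")
})

test_that("expected LOS uses the tail-sum identity", {
  expect_equal(expected_los(c(1, rep(0, 27))), 1)
  expect_equal(expected_los(rep(1, 28)), 28)
  inst <- base_instance()
  expect_equal(expected_los(inst$patient_types[[1]]$survival), 12.06)
})

test_that("census matrix is the admission-cohort convolution", {
  s <- los_survival(c(1, 0.5, 0))
  expect_equal(as.vector(census_matrix(matrix(c(2, 0, 0), 1), list(s))),
               c(2, 1, 0))
  # empty plan, empty hospital
  expect_equal(census_matrix(matrix(0, 2, 3),
                             list(s, los_survival(c(1, 1, 1)))),
               matrix(0, 2, 3))
  # day-1 census equals day-1 admissions
  x <- matrix(c(3, 1, 4, 0, 2, 5), 2, byrow = TRUE)
  M <- census_matrix(x, list(s, los_survival(c(1, 0.9, 0.8))))
  expect_equal(M[, 1], x[, 1])
})

test_that("census is linear and conserves patient-days", {
  set.seed(7)
  inst <- base_instance()
  surv <- lapply(inst$patient_types, function(p) p$survival)
  tau <- inst$horizon
  x <- matrix(rpois(3 * tau, 5), 3, tau)
  y <- matrix(rpois(3 * tau, 3), 3, tau)
  expect_equal(census_matrix(2 * x + 3 * y, surv),
               2 * census_matrix(x, surv) + 3 * census_matrix(y, surv))
  # cohort total patient-days = cohort size x horizon-truncated mean stay
  M <- census_matrix(x, surv)
  for (i in 1:3) {
    s <- unclass(surv[[i]])
    trunc_mean <- vapply(seq_len(tau), function(u) sum(s[1:(tau - u + 1)]), 0)
    expect_equal(sum(M[i, ]), sum(x[i, ] * trunc_mean))
    expect_lte(sum(M[i, ]), sum(x[i, ]) * expected_los(s) + 1e-9)
  }
  # single-day cohort: census is the shifted survival curve
  x1 <- matrix(0, 3, tau); x1[2, 5] <- 7
  M1 <- census_matrix(x1, surv)
  expect_equal(M1[2, 5:tau], 7 * unclass(surv[[2]])[1:(tau - 4)],
               ignore_attr = TRUE)
  expect_equal(M1[2, 1:4], rep(0, 4), ignore_attr = TRUE)
})
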
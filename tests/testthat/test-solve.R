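test_that("zero admission cap yields the empty plan and pure idle cost", {
  inst <- modify_instance(tiny_instance(11), admission_cap = 0)
  plan <- solve_model(build_model(inst), solver_options(mip_rel_gap = 0))
  expect_equal(plan$status, "optimal")
  expect_true(all(plan$x == 0))
  idle <- sum(vapply(inst$resources, function(r)
    r$cost_neg * sum(rep(r$target, length.out = inst$horizon)), 0))
  expect_equal(plan$objective, -idle, tolerance = 1e-9)
  kpi <- compute_kpis(plan)
  expect_equal(kpi$total_revenue, 0)
  expect_true(is.na(kpi$average_priority))
  expect_true(all(is.na(kpi$proportions)))
  expect_equal(sum(kpi$deviation_cost_neg), idle, tolerance = 1e-9)
})

test_that("solver optimum equals brute-force enumeration on seeded tiny instances", {
  seeds <- 1:40
  insts <- lapply(seeds, function(s)
    tiny_instance(s, n_types = 1L + s %% 2L, horizon = 2L + s %% 3L))
  plans <- solve_models(lapply(insts, build_model),
                        solver_options(mip_rel_gap = 0))
  for (k in seq_along(seeds)) {
    bf <- brute_force_optimum(insts[[k]])
    expect_equal(plans[[k]]$objective, bf$objective, tolerance = 1e-9,
                 info = paste("seed", seeds[k]))
    expect_equal(plans[[k]]$status, "optimal")
    expect_length(check_plan(plans[[k]]), 0)
  }
})

test_that("objective decomposes exactly and linearized deviations are complementary", {
  for (s in c(2, 9, 21)) {
    inst <- tiny_instance(s)
    plan <- solve_model(build_model(inst), solver_options(mip_rel_gap = 0))
    kpi <- compute_kpis(plan)
    expect_equal(kpi$objective,
                 kpi$total_revenue - sum(kpi$deviation_cost_pos) -
                   sum(kpi$deviation_cost_neg), tolerance = 1e-12)
    # recomputed positive-part deviations reproduce the solver objective:
    # only possible if the solver's deviation pair was complementary
    expect_equal(plan$objective, plan$solver_objective, tolerance = 1e-6)
    expect_true(all(pmin(plan$dev_pos, plan$dev_neg) == 0))
  }
})

test_that("KPIs are recomputed from x and respect mix/priority bounds", {
  inst <- tiny_instance(13)
  plan <- solve_model(build_model(inst), solver_options(mip_rel_gap = 0))
  kpi <- compute_kpis(plan)
  N <- kpi$total_admissions
  if (N > 0) {
    expect_equal(sum(kpi$proportions), 1, tolerance = 1e-12)
    beta <- inst_par(inst, "mix_upper"); alpha <- inst_par(inst, "mix_lower")
    expect_true(all(kpi$per_type_admissions <= beta * N + 1e-9))
    expect_true(all(kpi$per_type_admissions >= alpha * N - 1e-9))
  }
  # tampering with the plan objective is caught by the feasibility checker
  bad <- plan; bad$objective <- bad$objective + 1
  expect_match(paste(check_plan(bad), collapse = " "), "disagrees")
})

test_that("capacity relaxation never lowers the optimum", {
  for (s in c(4, 17)) {
    inst <- tiny_instance(s)
    plan <- solve_model(build_model(inst), solver_options(mip_rel_gap = 0))
    bigger <- inst
    bigger$resources$bed$available <- inst$resources$bed$available + 1
    plan2 <- solve_model(build_model(bigger), solver_options(mip_rel_gap = 0))
    expect_gte(plan2$objective, plan$objective - 1e-9)
  }
})
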
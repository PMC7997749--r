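test_that("a no-op sweep reproduces a direct solve", {
  inst <- tiny_instance(8)
  direct <- solve_model(build_model(inst), solver_options(mip_rel_gap = 0))
  sweep <- run_sweep(list(scenario_spec("base", inst)),
                     solver_options(mip_rel_gap = 0))
  expect_equal(nrow(sweep), 1L)
  expect_equal(sweep$objective, direct$objective, tolerance = 1e-9)
  expect_equal(sweep$admissions, sum(direct$x))
})

test_that("invalid scenario is reported, not fatal, and order is kept", {
  inst <- tiny_instance(8)
  bad <- inst
  bad$patient_types[[1]]$mix_lower <- 2  # invalid on purpose
  sweep <- run_sweep(list(scenario_spec("a", inst),
                          scenario_spec("b", bad),
                          scenario_spec("c", inst)),
                     solver_options(mip_rel_gap = 0))
  expect_equal(sweep$label, c("a", "b", "c"))
  expect_equal(sweep$status[2], "invalid")
  expect_true(all(sweep$status[c(1, 3)] == "optimal"))
})

test_that("model II relaxation and wider mix bounds never lower the optimum", {
  for (s in c(3, 14, 26)) {
    inst <- tiny_instance(s, n_types = 2L, horizon = 3L)
    opt <- solver_options(mip_rel_gap = 0)
    z1 <- solve_model(build_model(inst, model_variant("model_I")), opt)$objective
    z2 <- solve_model(build_model(inst, model_variant("model_II")), opt)$objective
    expect_gte(z2, z1 - 1e-9)
    wider <- modify_instance(inst,
                             mix_upper = pmin(inst_par(inst, "mix_upper") + 0.1, 1))
    z3 <- solve_model(build_model(wider), opt)$objective
    expect_gte(z3, z1 - 1e-9)
  }
})

test_that("priority floor steers the mix and tightening it never helps", {
  inst <- tiny_instance(6, n_types = 2L, horizon = 3L)
  scores <- inst_par(inst, "priority_score")
  floors <- c(0, mean(scores), max(scores))
  sweep <- priority_floor_sweep(inst, floors, solver_options(mip_rel_gap = 0))
  expect_equal(nrow(sweep), 3L)
  obj <- sweep$objective
  expect_true(all(diff(obj) <= 1e-9))
  # at the maximal floor only the top-score type can be admitted
  top <- which.max(scores)
  adm <- as.matrix(sweep[3, grep("^adm_", names(sweep))])
  if (sweep$admissions[3] > 0)
    expect_equal(sum(adm[-top]), 0)
  # floor 0 equals the unconstrained relaxation
  z_free <- solve_model(build_model(inst, model_variant("model_II")),
                        solver_options(mip_rel_gap = 0))$objective
  expect_equal(sweep$objective[1], z_free, tolerance = 1e-9)
})

test_that("packaged scenario grids carry the intended parameter patterns", {
  base <- base_instance()
  nh <- nursing_hours_scenarios(base)
  expect_length(nh, 9L)
  expect_equal(inst_par(nh[[4]]$instance, "nursing_hours"), c(1.5, 1.25, 0.5))
  expect_equal(inst_par(nh[[2]]$instance, "nursing_hours"),
               inst_par(base, "nursing_hours"))
  mx <- mix_bound_scenarios(base)
  expect_equal(vapply(mx, function(s) s$label, ""),
               c("1", "2", "3", "5", "6", "7", "8", "9", "10"))
  expect_equal(inst_par(mx[[1]]$instance, "mix_upper"), c(0.9, 0.2, 0.1))
  tc <- target_capacity_scenarios(base)
  expect_equal(vapply(tc, function(s)
    unique(inst_capacity(s$instance, "bed", "target")), 0),
    seq(183, 195, by = 2))
  # only the bed target moves in the target sweep
  expect_equal(unique(inst_capacity(tc[[7]]$instance, "exam", "target")), 181)
  cmp <- comparison_mix_scenarios()
  expect_length(cmp, 3L)
  expect_equal(cmp[[1]]$upper, c(0.9, 0.2, 0.1))
})
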
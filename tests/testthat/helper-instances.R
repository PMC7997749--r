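# Shared fixtures, built in code.

# Single-type toy: 2-day cycle, everyone stays exactly 1 day, one bed,
# free deviations. The optimum admits one patient per day.
toy_single_type <- function() {
  suppressWarnings(planning_instance(
    list(patient_type("only", 10, 0, 0, 1, 0, 1, c(1, 0))),
    list(resource_spec("bed", 1, 1, 0, 0, horizon = 2),
         resource_spec("exam", 10, 0, 0, 0, horizon = 2),
         resource_spec("nursing", 10, 0, 0, 0, horizon = 2)),
    horizon = 2, admission_cap = 10))
}

tiny_instance <- function(seed, n_types = 2L, horizon = 3L) {
  generate_instance(synth_config(seed = seed, n_types = n_types,
                                 horizon = horizon))
}

# Case-study solves are expensive; solve each configuration once per
# test run and share the plan across test files.
.plan_cache <- new.env(parent = emptyenv())
cached_plan <- function(key, builder, options = solver_options()) {
  if (is.null(.plan_cache[[key]]))
    .plan_cache[[key]] <- solve_model(builder(), options)
  .plan_cache[[key]]
}

base_case_plan <- function() {
  cached_plan("base", function() build_model(base_instance()))
}

# internal accessors used in expectations
inst_par <- admitplan:::inst_par
inst_capacity <- admitplan:::inst_capacity
inst_survival_matrix <- admitplan:::inst_survival_matrix

withr_local_tempfile <- function(ext, env = parent.frame()) {
  f <- tempfile(fileext = ext)
  withr::defer(unlink(c(f, paste0(f, ".csv"))), envir = env)
  f
}

expect_instances_equal <- function(a, b) {
  expect_equal(a$horizon, b$horizon)
  expect_equal(a$admission_cap, b$admission_cap)
  expect_equal(a$priority_floor, b$priority_floor)
  expect_equal(length(a$patient_types), length(b$patient_types))
  for (i in seq_along(a$patient_types)) {
    pa <- a$patient_types[[i]]; pb <- b$patient_types[[i]]
    for (f in c("id", "revenue", "exam_hours", "nursing_hours",
                "priority_score", "mix_lower", "mix_upper"))
      expect_equal(pa[[f]], pb[[f]], info = paste("field", f))
    expect_equal(unclass(pa$survival), unclass(pb$survival))
  }
  for (r in c("bed", "exam", "nursing")) {
    ra <- a$resources[[r]]; rb <- b$resources[[r]]
    expect_equal(rep(ra$available, length.out = a$horizon),
                 rep(rb$available, length.out = b$horizon))
    expect_equal(rep(ra$target, length.out = a$horizon),
                 rep(rb$target, length.out = b$horizon))
    expect_equal(ra$cost_pos, rb$cost_pos)
    expect_equal(ra$cost_neg, rb$cost_neg)
  }
}

`%||%` <- admitplan:::`%||%`
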
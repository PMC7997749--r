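test_that("packaged case-study instance carries the published parameters", {
  inst <- base_instance()
  expect_length(validate_instance(inst), 0)
  expect_equal(inst$horizon, 28L)
  expect_equal(inst_par(inst, "revenue"), c(170, 160, 150))
  expect_equal(inst_par(inst, "exam_hours"), c(1.5, 1, 1.5))
  expect_equal(inst_par(inst, "nursing_hours"), c(1.5, 1, 0.5))
  expect_equal(inst_par(inst, "priority_score"), c(9, 6.5, 3))
  expect_equal(inst_par(inst, "mix_upper"), c(0.7, 0.2, 0.1))
  expect_equal(inst_par(inst, "mix_lower"), c(0.5, 0.1, 0))
  expect_equal(unique(inst_capacity(inst, "bed", "available")), 203)
  expect_equal(unique(inst_capacity(inst, "bed", "target")), 183)
  expect_equal(unique(inst_capacity(inst, "exam", "available")), 201.6)
  expect_equal(unique(inst_capacity(inst, "exam", "target")), 181)
  expect_equal(unique(inst_capacity(inst, "nursing", "available")), 561)
  expect_equal(unique(inst_capacity(inst, "nursing", "target")), 512)
  for (r in inst$resources) {
    expect_equal(r$cost_pos, 20)
    expect_equal(r$cost_neg, 30)
  }
  # survival spot checks, s = 7 row and curve edges
  sv <- inst_survival_matrix(inst)
  expect_equal(sv[, 8], c(0.77, 0.79, 0.72), ignore_attr = TRUE)
  expect_equal(sv[, 1], c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(sv[, 28], c(0.02, 0.02, 0.03), ignore_attr = TRUE)
})

test_that("validation reports each violated invariant without raising", {
  inst <- base_instance()
  broken <- inst
  broken$patient_types[[1]]$survival <- c(1, 0.5, 0.7,
                                          rep(0.1, inst$horizon - 3))
  expect_match(paste(validate_instance(broken), collapse = " "),
               "nonincreasing")
  broken2 <- inst
  broken2$patient_types[[1]]$mix_lower <- 0.6
  broken2$patient_types[[2]]$mix_lower <- 0.5
  expect_match(paste(validate_instance(broken2), collapse = " "),
               "lower bounds sum > 1")
  broken3 <- inst
  broken3$resources$bed$target <- rep(500, 28) # target above available
  expect_match(paste(validate_instance(broken3), collapse = " "),
               "target capacity")
})

test_that("instances round-trip through YAML (inline and CSV survival)", {
  inst <- base_instance()
  f <- withr_local_tempfile(".yaml")
  write_instance(inst, f)
  back <- read_instance(f)
  expect_instances_equal(back, inst)

  f2 <- withr_local_tempfile(".yaml")
  write_instance(inst, f2, los_csv = paste0(basename(f2), ".csv"))
  back2 <- read_instance(f2)
  expect_instances_equal(back2, inst)

  syn <- tiny_instance(3, n_types = 2L, horizon = 4L)
  f3 <- withr_local_tempfile(".yaml")
  write_instance(syn, f3)
  expect_instances_equal(read_instance(f3), syn)
})
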
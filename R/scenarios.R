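# Scenario engine: parameter sweeps (nursing hours, mix bounds, priority
# floor, target capacity) and the model I vs model II comparison, with
# the packaged case-study scenario grids.

#' Derive a modified copy of a planning instance
#'
#' Convenience layer for scenario sweeps; every argument left `NULL`
#' keeps the base value. The modified instance is re-validated.
#'
#' @param inst Base [planning_instance()].
#' @param nursing_hours,exam_hours,revenue Per-type numeric vectors.
#' @param mix_upper,mix_lower Per-type proportion bounds.
#' @param priority_floor,admission_cap Scalars.
#' @param bed_target Scalar daily bed target capacity.
#' @param targets Named list (`bed`, `exam`, `nursing`) of scalar daily
#'   target capacities.
#' @return A new [planning_instance()].
#' @export
modify_instance <- function(inst, nursing_hours = NULL, exam_hours = NULL,
                            revenue = NULL, mix_upper = NULL,
                            mix_lower = NULL, priority_floor = NULL,
                            admission_cap = NULL, bed_target = NULL,
                            targets = NULL) {
  pts <- inst$patient_types
  set_field <- function(pts, field, values) {
    if (is.null(values)) return(pts)
    stopifnot(length(values) == length(pts))
    for (i in seq_along(pts)) pts[[i]][[field]] <- as.numeric(values[i])
    pts
  }
  pts <- set_field(pts, "nursing_hours", nursing_hours)
  pts <- set_field(pts, "exam_hours", exam_hours)
  pts <- set_field(pts, "revenue", revenue)
  pts <- set_field(pts, "mix_upper", mix_upper)
  pts <- set_field(pts, "mix_lower", mix_lower)
  res <- inst$resources
  if (!is.null(bed_target)) targets <- c(list(bed = bed_target), targets)
  for (rid in names(targets)) {
    stopifnot(rid %in% names(res))
    res[[rid]]$target <- rep(as.numeric(targets[[rid]]),
                             length.out = length(res[[rid]]$target))
  }
  planning_instance(pts, res, inst$horizon,
                    admission_cap = admission_cap %||% inst$admission_cap,
                    priority_floor = priority_floor %||% inst$priority_floor)
}

#' A labelled scenario: instance plus model variant
#'
#' @param label Scenario label (kept verbatim in result tables).
#' @param instance A [planning_instance()].
#' @param variant A [model_variant()].
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(label, instance,
                          variant = model_variant("model_I")) {
  structure(list(label = as.character(label), instance = instance,
                 variant = variant), class = "scenario_spec")
}

#' Run an ordered set of scenarios
#'
#' Solves every scenario in one batched solver invocation and returns one
#' KPI row per scenario, in input order. Scenarios whose instance fails
#' validation or whose model is infeasible are recorded with their status
#' rather than aborting the sweep.
#'
#' @param specs List of [scenario_spec()] objects.
#' @param options [solver_options()].
#' @return A data.frame with label, status, objective, revenue, deviation
#'   costs, admissions (total and per type), proportions and average
#'   priority; the solved plans are attached as attribute `"plans"`.
#' @export
run_sweep <- function(specs, options = solver_options()) {
  stopifnot(length(specs) >= 1L)
  models <- vector("list", length(specs))
  pre_bad <- character(length(specs))
  for (k in seq_along(specs)) {
    bad <- validate_instance(specs[[k]]$instance)
    if (length(bad)) pre_bad[k] <- paste(bad, collapse = "; ")
    else models[[k]] <- build_model(specs[[k]]$instance, specs[[k]]$variant)
  }
  todo <- which(pre_bad == "")
  plans <- vector("list", length(specs))
  if (length(todo))
    plans[todo] <- solve_models(models[todo], options)
  rows <- lapply(seq_along(specs), function(k) {
    lbl <- specs[[k]]$label
    if (pre_bad[k] != "")
      return(data.frame(label = lbl, status = "invalid", objective = NA,
                        revenue = NA, dev_cost_pos = NA, dev_cost_neg = NA,
                        admissions = NA, stringsAsFactors = FALSE))
    plan <- plans[[k]]
    if (is.null(plan$x))
      return(data.frame(label = lbl, status = plan$status, objective = NA,
                        revenue = NA, dev_cost_pos = NA, dev_cost_neg = NA,
                        admissions = NA, stringsAsFactors = FALSE))
    kpi <- compute_kpis(plan)
    out <- data.frame(label = lbl, status = plan$status,
                      objective = kpi$objective,
                      revenue = kpi$total_revenue,
                      dev_cost_pos = sum(kpi$deviation_cost_pos),
                      dev_cost_neg = sum(kpi$deviation_cost_neg),
                      admissions = kpi$total_admissions,
                      stringsAsFactors = FALSE)
    for (j in seq_along(kpi$per_type_admissions)) {
      id <- names(kpi$per_type_admissions)[j]
      out[[paste0("adm_", id)]] <- kpi$per_type_admissions[j]
      out[[paste0("prop_", id)]] <- kpi$proportions[j]
    }
    out$average_priority <- kpi$average_priority
    out
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  res <- do.call(rbind, rows)
  attr(res, "plans") <- plans
  res
}

#' Sweep of the average-priority floor with mix bounds removed
#'
#' Reproduces the priority-score analysis: the per-type proportion
#' constraints are dropped and only the average-priority floor varies, so
#' the induced mix shows how the floor steers admissions toward
#' high-priority types.
#'
#' @param inst Base [planning_instance()].
#' @param floors Numeric vector of floor values.
#' @param options [solver_options()].
#' @return A [run_sweep()] data.frame, one row per floor.
#' @export
priority_floor_sweep <- function(inst, floors, options = solver_options()) {
  specs <- lapply(floors, function(L)
    scenario_spec(paste0("Lp=", L),
                  modify_instance(inst, priority_floor = L),
                  model_variant("model_II", use_priority_floor = TRUE)))
  run_sweep(specs, options)
}

#' Compare model I under several mix-bound settings with model II
#'
#' Solves model I for each `(upper, lower)` proportion-bound scenario and
#' model II (no proportion constraints, no priority floor) once on the
#' unmodified instance, all in one batch.
#'
#' @param inst Base [planning_instance()].
#' @param mix_scenarios List of lists with elements `upper` and `lower`
#'   (per-type vectors) and optionally `label`.
#' @param options [solver_options()].
#' @return A [run_sweep()] data.frame; the last row is model II.
#' @export
compare_models <- function(inst, mix_scenarios, options = solver_options()) {
  specs <- lapply(seq_along(mix_scenarios), function(k) {
    sc <- mix_scenarios[[k]]
    scenario_spec(sc$label %||% paste0("model_I_scenario_", k),
                  modify_instance(
                    inst,
                    mix_upper = unlist(sc$upper %||% sc$mix_upper),
                    mix_lower = unlist(sc$lower %||% sc$mix_lower)),
                  model_variant("model_I"))
  })
  specs <- c(specs, list(scenario_spec("model_II", inst,
                                       model_variant("model_II"))))
  run_sweep(specs, options)
}

# ---- packaged case-study scenario grids ------------------------------

#' Case-study scenario grids
#'
#' `nursing_hours_scenarios()` varies one type's per-patient-day nursing
#' hours at a time around the base setting (nine scenarios; 2, 5 and 8
#' are the unmodified benchmark). `mix_bound_scenarios()` varies the
#' proportion bounds (labels follow the original study numbering, which
#' skips 4). `target_capacity_scenarios()` raises the daily bed target
#' from 183 to 195 in steps of 2 (the target-utilization levels 90-96% of
#' the 203 available beds). `comparison_mix_scenarios()` gives the three
#' mix-bound settings used in the model I vs model II comparison.
#'
#' @param inst Base instance (defaults to [base_instance()]).
#' @return A list of [scenario_spec()] (or, for
#'   `comparison_mix_scenarios`, the mix-scenario list consumed by
#'   [compare_models()]).
#' @name case_study_scenarios
NULL

#' @rdname case_study_scenarios
#' @export
nursing_hours_scenarios <- function(inst = base_instance()) {
  grid <- list(c(1.75, 1, 0.5), c(1.5, 1, 0.5), c(1.25, 1, 0.5),
               c(1.5, 1.25, 0.5), c(1.5, 1, 0.5), c(1.5, 0.75, 0.5),
               c(1.5, 1, 0.75), c(1.5, 1, 0.5), c(1.5, 1, 0.25))
  lapply(seq_along(grid), function(k)
    scenario_spec(as.character(k),
                  modify_instance(inst, nursing_hours = grid[[k]])))
}

#' @rdname case_study_scenarios
#' @export
mix_bound_scenarios <- function(inst = base_instance()) {
  # (upper, lower) per type; labels skip 4 as in the source table
  grid <- list(
    `1` = list(u = c(0.9, 0.2, 0.1), l = c(0.5, 0.1, 0)),
    `2` = list(u = c(0.8, 0.2, 0.1), l = c(0.5, 0.1, 0)),
    `3` = list(u = c(0.7, 0.2, 0.1), l = c(0.5, 0.1, 0)),
    `5` = list(u = c(0.7, 0.2, 0.1), l = c(0.6, 0.1, 0)),
    `6` = list(u = c(0.7, 0.2, 0.1), l = c(0.4, 0.1, 0)),
    `7` = list(u = c(0.7, 0.4, 0.1), l = c(0.5, 0.1, 0)),
    `8` = list(u = c(0.7, 0.3, 0.1), l = c(0.5, 0.1, 0)),
    `9` = list(u = c(0.7, 0.2, 0.2), l = c(0.5, 0.1, 0)),
    `10` = list(u = c(0.7, 0.3, 0.1), l = c(0.5, 0.1, 0.05)))
  lapply(names(grid), function(k)
    scenario_spec(k, modify_instance(inst, mix_upper = grid[[k]]$u,
                                     mix_lower = grid[[k]]$l)))
}

#' @rdname case_study_scenarios
#' @export
target_capacity_scenarios <- function(inst = base_instance()) {
  tc <- seq(183, 195, by = 2)
  lapply(seq_along(tc), function(k)
    scenario_spec(as.character(k), modify_instance(inst, bed_target = tc[k])))
}

#' @rdname case_study_scenarios
#' @export
comparison_mix_scenarios <- function() {
  list(list(label = "1", upper = c(0.9, 0.2, 0.1), lower = c(0.5, 0.1, 0)),
       list(label = "2", upper = c(0.7, 0.3, 0.1), lower = c(0.5, 0.1, 0)),
       list(label = "3", upper = c(0.7, 0.3, 0.1), lower = c(0.5, 0.1, 0.05)))
}

#' Read a sweep configuration file
#'
#' A sweep config is a YAML document with a `scenarios` list; each entry
#' has a `label` plus any [modify_instance()] argument
#' (`nursing_hours`, `exam_hours`, `revenue`, `mix_upper`, `mix_lower`,
#' `priority_floor`, `admission_cap`, `bed_target`). The configs shipped
#' under `inst/configs/` reproduce the case-study sweep grids.
#'
#' @param path YAML config path (or the name of a packaged config such
#'   as `"nursing_hours"`).
#' @param inst Base instance the overrides apply to.
#' @param variant A [model_variant()] used for every scenario.
#' @return A list of [scenario_spec()] for [run_sweep()].
#' @export
read_sweep_config <- function(path, inst = base_instance(),
                              variant = model_variant("model_I")) {
  if (!file.exists(path)) {
    packaged <- system.file("configs", paste0(path, ".yaml"),
                            package = "admitplan")
    if (nzchar(packaged)) path <- packaged
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$scenarios)) stop("config has no 'scenarios' list")
  lapply(doc$scenarios, function(sc) {
    label <- sc$label %||% "scenario"
    sc$label <- NULL
    args <- lapply(sc, function(v) if (is.list(v)) unlist(v) else v)
    scenario_spec(label, do.call(modify_instance, c(list(inst), args)),
                  variant)
  })
}
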
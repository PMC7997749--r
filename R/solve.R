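# Driving a MILP solver on built models and extracting admission plans.
#
# The numerical workhorse is the HiGHS branch-and-bound solver, reached
# through a small JSON bridge script (inst/python/solve_milp.py) running
# in the scientific Python environment that ships alongside R here. The
# package builds every matrix itself; the bridge only relays them.

#' Solver settings
#'
#' Stopping is governed by the relative MIP gap and a node limit rather
#' than wall-clock time, so results are reproducible across machines of
#' different speeds. If the node limit triggers first the returned status
#' is `"limit"` and the incumbent (best feasible) plan is returned with
#' its proven gap attached.
#'
#' @param mip_rel_gap Relative optimality gap at which to stop.
#' @param node_limit Maximum branch-and-bound nodes (deterministic).
#' @param time_limit Optional wall-clock safety limit in seconds;
#'   overrunning it also yields status `"limit"`.
#' @param python Python interpreter carrying scipy (found on `PATH` by
#'   default; override via `options(admitplan.python = ...)`).
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(mip_rel_gap = 1e-3, node_limit = 20000L,
                           time_limit = NULL,
                           python = getOption("admitplan.python", "python")) {
  structure(list(mip_rel_gap = mip_rel_gap, node_limit = as.integer(node_limit),
                 time_limit = time_limit, python = python),
            class = "solver_options")
}

#' Solve a built admission-planning model
#'
#' Runs branch and bound on the integer program and returns the admission
#' plan. The plan's census, deviations and objective are recomputed in R
#' from the integer admissions alone (positive-part deviations), so the
#' reported figures never depend on the solver's auxiliary variables.
#'
#' @param model A [build_model()] result.
#' @param options A [solver_options()] list.
#' @return An object of class `admission_plan` with elements `x`
#'   (type-by-day integer matrix), `census`, `dev_pos`/`dev_neg`
#'   (resource-by-day), `objective`, `status` (`"optimal"`, `"limit"`,
#'   `"infeasible"`, `"unbounded"` or `"error"`), `mip_gap`, `node_count`
#'   and diagnostic messages.
#' @export
#' @examples
#' \dontrun{
#' plan <- solve_model(build_model(base_instance()))
#' plan$objective
#' }
solve_model <- function(model, options = solver_options()) {
  solve_models(list(model), options)[[1L]]
}

#' Solve several built models in one solver invocation
#'
#' Batching amortizes interpreter start-up across a scenario sweep.
#'
#' @param models List of [build_model()] results.
#' @param options A [solver_options()] list.
#' @return List of `admission_plan` objects, in input order.
#' @export
solve_models <- function(models, options = solver_options()) {
  stopifnot(length(models) >= 1L)
  payload <- list(
    options = Filter(Negate(is.null),
                     list(mip_rel_gap = options$mip_rel_gap,
                          node_limit = options$node_limit,
                          time_limit = options$time_limit)),
    problems = lapply(unname(models), function(m) tighten_model(m)$problem))
  res <- run_bridge(payload, options$python)
  Map(function(m, r) extract_plan(m, r), models, res$results)
}

# Equivalent tightened formulation handed to the solver: per-type cycle
# totals and the grand total become integer variables of their own, and
# the cap / mix / priority rows act on them. This leaves the feasible x
# set and the optimum unchanged but lets branch and bound close the
# integrality gap far faster on proportion-constrained instances.
tighten_model <- function(model) {
  inst <- model$instance
  variant <- model$variant
  nI <- model$n_types; tau <- model$horizon; nx <- model$n_x
  nv0 <- length(model$obj)
  keep <- !grepl("^(total_cap|mix_upper|mix_lower|priority_floor)",
                 rownames(model$A))
  nadd <- nI + 1L
  iy <- function(i) nv0 + i
  iN <- nv0 + nI + 1L
  rows_i <- integer(); rows_j <- integer(); rows_v <- numeric()
  lb <- numeric(); ub <- numeric(); nr <- 0L
  add_row <- function(j, v, lo, hi) {
    nr <<- nr + 1L
    rows_i <<- c(rows_i, rep(nr, length(j)))
    rows_j <<- c(rows_j, j); rows_v <<- c(rows_v, v)
    lb <<- c(lb, lo); ub <<- c(ub, hi)
  }
  A0 <- model$A[keep, , drop = FALSE]
  nz <- which(A0 != 0, arr.ind = TRUE)
  rows_i <- nz[, 1]; rows_j <- nz[, 2]; rows_v <- A0[nz]
  lb <- model$row_lb[keep]; ub <- model$row_ub[keep]
  nr <- nrow(A0)
  for (i in seq_len(nI))
    add_row(c((i - 1L) * tau + seq_len(tau), iy(i)), c(rep(1, tau), -1), 0, 0)
  add_row(c(nv0 + seq_len(nI), iN), c(rep(1, nI), -1), 0, 0)
  add_row(iN, 1, -Inf, inst$admission_cap)
  if (variant$use_mix_bounds) {
    beta <- inst_par(inst, "mix_upper"); alpha <- inst_par(inst, "mix_lower")
    for (i in seq_len(nI)) {
      add_row(c(iy(i), iN), c(1, -beta[i]), -Inf, 0)
      add_row(c(iy(i), iN), c(-1, alpha[i]), -Inf, 0)
    }
  }
  if (variant$use_priority_floor) {
    score <- inst_par(inst, "priority_score")
    add_row(c(nv0 + seq_len(nI), iN), c(-score, inst$priority_floor), -Inf, 0)
  }
  cap <- as.numeric(inst$admission_cap)
  problem <- list(
    ncol = nv0 + nadd,
    obj = c(model$obj, rep(0, nadd)),
    A = list(i = as.integer(rows_i) - 1L, j = as.integer(rows_j) - 1L,
             v = as.numeric(rows_v)),
    nrow = nr,
    row_lb = as.list(ifelse(is.finite(lb), lb, NA)),
    row_ub = as.list(ifelse(is.finite(ub), ub, NA)),
    var_lb = as.list(c(model$var_lb, rep(0, nadd))),
    var_ub = as.list(ifelse(is.finite(c(model$var_ub, rep(cap, nadd))),
                            c(model$var_ub, rep(cap, nadd)), NA)),
    integrality = as.integer(c(model$integrality, rep(TRUE, nadd))))
  list(problem = problem)
}

run_bridge <- function(payload, python = "python") {
  script <- system.file("python", "solve_milp.py", package = "admitplan",
                        mustWork = TRUE)
  infile <- tempfile("milp_in_", fileext = ".json")
  outfile <- tempfile("milp_out_", fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  status <- suppressWarnings(
    system2(python, c(shQuote(script), shQuote(infile), shQuote(outfile)),
            stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if ((!is.null(code) && code != 0) || !file.exists(outfile))
    stop("MILP bridge failed (", python, "): ",
         paste(status, collapse = "\n"))
  jsonlite::read_json(outfile, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

extract_plan <- function(model, r) {
  inst <- model$instance
  nI <- model$n_types; tau <- model$horizon
  type_ids <- vapply(inst$patient_types, function(p) p$id, "")
  status <- r$status
  if (is.null(r$x) || status %in% c("infeasible", "unbounded", "error")) {
    return(structure(list(x = NULL, census = NULL, dev_pos = NULL,
                          dev_neg = NULL, objective = NA_real_,
                          solver_objective = r$objective, status = status,
                          message = r$status_message %||% "",
                          mip_gap = r$mip_gap, node_count = r$mip_node_count,
                          variant = model$variant, instance = inst),
                     class = "admission_plan"))
  }
  x <- matrix(round(unlist(r$x)[seq_len(model$n_x)]), nrow = nI, byrow = TRUE,
              dimnames = list(type = type_ids, day = seq_len(tau)))
  pieces <- plan_pieces(x, inst)
  structure(list(x = x, census = pieces$census, dev_pos = pieces$dev_pos,
                 dev_neg = pieces$dev_neg, objective = pieces$objective,
                 solver_objective = r$objective, status = status,
                 message = r$status_message %||% "",
                 mip_gap = r$mip_gap, node_count = r$mip_node_count,
                 variant = model$variant, instance = inst),
            class = "admission_plan")
}

# loads, deviations (direct positive parts) and objective implied by x
plan_pieces <- function(x, inst) {
  tau <- inst$horizon
  surv <- lapply(inst$patient_types, function(p) p$survival)
  census <- census_matrix(x, surv)
  loads <- resource_loads(x, census, inst)
  TC <- t(vapply(c("bed", "exam", "nursing"),
                 function(r) inst_capacity(inst, r, "target"), numeric(tau)))
  dev_pos <- pmax(loads - TC, 0)
  dev_neg <- pmax(TC - loads, 0)
  cpos <- vapply(inst$resources, function(r) r$cost_pos, 0)[rownames(loads)]
  cneg <- vapply(inst$resources, function(r) r$cost_neg, 0)[rownames(loads)]
  revenue <- sum(inst_par(inst, "revenue") * rowSums(x))
  objective <- revenue - sum(cpos * rowSums(dev_pos)) -
    sum(cneg * rowSums(dev_neg))
  list(census = census, dev_pos = dev_pos, dev_neg = dev_neg,
       objective = objective, revenue = revenue, loads = loads)
}

# daily loads per resource: bed census, exam hours on admission day,
# nursing hours over the census
resource_loads <- function(x, census, inst) {
  exam <- inst_par(inst, "exam_hours")
  nurs <- inst_par(inst, "nursing_hours")
  loads <- rbind(bed = colSums(census),
                 exam = as.vector(exam %*% x),
                 nursing = as.vector(nurs %*% census))
  loads
}

#' @export
print.admission_plan <- function(x, ...) {
  cat("admission_plan [", x$status, "]", sep = "")
  if (!is.null(x$x))
    cat(": objective ", format(x$objective, big.mark = ","), ", ",
        sum(x$x), " admissions over ", ncol(x$x), " days", sep = "")
  if (!is.null(x$mip_gap) && is.finite(as.numeric(x$mip_gap %||% NA)))
    cat(sprintf(" (gap %.2g)", as.numeric(x$mip_gap)))
  cat("\n")
  invisible(x)
}

#' Recheck a plan against every model constraint by direct arithmetic
#'
#' Independent of the solver: recomputes census, loads and deviations
#' from the integer admissions and tests the admission cap, mix bounds,
#' priority floor and capacity limits.
#'
#' @param plan An `admission_plan` with status `"optimal"` or `"limit"`.
#' @param tol Feasibility tolerance.
#' @return Character vector of violated constraints (empty iff feasible).
#' @export
check_plan <- function(plan, tol = 1e-6) {
  inst <- plan$instance
  variant <- plan$variant
  out <- character()
  x <- plan$x
  if (is.null(x)) return("plan has no admissions matrix")
  if (any(x < 0) || any(abs(x - round(x)) > tol))
    out <- c(out, "admissions not nonnegative integers")
  N <- sum(x)
  if (N > inst$admission_cap + tol) out <- c(out, "total admission cap exceeded")
  if (variant$use_mix_bounds && N > 0) {
    beta <- inst_par(inst, "mix_upper"); alpha <- inst_par(inst, "mix_lower")
    tot <- rowSums(x)
    if (any(tot > beta * N + tol)) out <- c(out, "mix upper bound violated")
    if (any(tot < alpha * N - tol)) out <- c(out, "mix lower bound violated")
  }
  if (variant$use_priority_floor && N > 0) {
    sc <- sum(inst_par(inst, "priority_score") * rowSums(x)) / N
    if (sc < inst$priority_floor - tol) out <- c(out, "priority floor violated")
  }
  pieces <- plan_pieces(x, inst)
  tau <- inst$horizon
  AC <- t(vapply(c("bed", "exam", "nursing"),
                 function(r) inst_capacity(inst, r, "available"), numeric(tau)))
  over <- pieces$loads > AC + tol
  if (any(over))
    out <- c(out, paste0("available capacity exceeded: ",
                         paste(rownames(AC)[which(over, arr.ind = TRUE)[, 1]],
                               collapse = ", ")))
  if (abs(pieces$objective - plan$objective) > 1e-6 * max(1, abs(plan$objective)))
    out <- c(out, "stored objective disagrees with recomputation")
  out
}

#' Compute every reported KPI from a solved plan
#'
#' All indicators are recomputed from the integer admissions matrix as
#' the single source of truth; census and deviations stored on the plan
#' are treated as caches.
#'
#' @param plan An `admission_plan` with a feasible `x`.
#' @param inst Planning instance; defaults to the one stored on the plan.
#' @return A list of class `kpi_record`: `objective`, `total_revenue`,
#'   `deviation_cost_pos`/`neg` (named by resource), `total_admissions`,
#'   `per_type_admissions`, `proportions`, `average_priority` and
#'   `mean_utilization` (load / available, averaged over days). With zero
#'   admissions, proportions and average priority are `NA`.
#' @export
compute_kpis <- function(plan, inst = plan$instance) {
  x <- plan$x
  if (is.null(x)) stop("plan has no solution (status ", plan$status, ")")
  pieces <- plan_pieces(x, inst)
  cpos <- vapply(inst$resources, function(r) r$cost_pos, 0)
  cneg <- vapply(inst$resources, function(r) r$cost_neg, 0)
  dev_cost_pos <- cpos[rownames(pieces$dev_pos)] * rowSums(pieces$dev_pos)
  dev_cost_neg <- cneg[rownames(pieces$dev_neg)] * rowSums(pieces$dev_neg)
  N <- sum(x)
  tot <- rowSums(x)
  tau <- inst$horizon
  AC <- t(vapply(c("bed", "exam", "nursing"),
                 function(r) inst_capacity(inst, r, "available"), numeric(tau)))
  util <- rowMeans(pieces$loads / AC)
  structure(list(
    objective = pieces$objective,
    total_revenue = pieces$revenue,
    deviation_cost_pos = dev_cost_pos,
    deviation_cost_neg = dev_cost_neg,
    total_admissions = N,
    per_type_admissions = tot,
    proportions = if (N > 0) tot / N else rep(NA_real_, length(tot)),
    average_priority = if (N > 0)
      sum(inst_par(inst, "priority_score") * tot) / N else NA_real_,
    mean_utilization = util,
    status = plan$status, mip_gap = plan$mip_gap), class = "kpi_record")
}

#' @export
print.kpi_record <- function(x, ...) {
  cat(sprintf("objective %.2f = revenue %.2f - overuse %.2f - idle %.2f\n",
              x$objective, x$total_revenue, sum(x$deviation_cost_pos),
              sum(x$deviation_cost_neg)))
  cat("admissions", x$total_admissions, "(",
      paste(sprintf("%s %d [%s]", names(x$per_type_admissions),
                    x$per_type_admissions,
                    ifelse(is.na(x$proportions), "NA",
                           sprintf("%.2f%%", 100 * x$proportions))),
            collapse = ", "), ")\n")
  cat(sprintf("average priority %.2f | mean utilization %s\n",
              x$average_priority,
              paste(sprintf("%s %.1f%%", names(x$mean_utilization),
                            100 * x$mean_utilization), collapse = ", ")))
  invisible(x)
}

#' Export an admission plan as a type-by-day CSV
#'
#' @param plan An `admission_plan`.
#' @param path Output CSV path.
#' @param what `"admissions"` or `"census"`.
#' @return `path`, invisibly.
#' @export
write_plan_csv <- function(plan, path, what = c("admissions", "census")) {
  what <- match.arg(what)
  m <- if (what == "admissions") plan$x else plan$census
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
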
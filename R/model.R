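# Integer-program construction: decision variables, objective and the
# full constraint system for the priority-constrained admission model
# (model I) and its relaxation without proportion constraints (model II).

#' Choose the model variant
#'
#' Model I is the full formulation: proportion (mix) bounds per patient
#' type and the average-priority floor. Model II drops the per-type
#' proportion constraints (and, by default, the priority floor as well),
#' treating patients as homogeneous.
#'
#' @param name `"model_I"` or `"model_II"`.
#' @param use_priority_floor Override for the priority-floor constraint;
#'   defaults to `TRUE` for model I and `FALSE` for model II.
#' @return An object of class `model_variant` with flags `use_mix_bounds`
#'   and `use_priority_floor`.
#' @export
model_variant <- function(name = c("model_I", "model_II"),
                          use_priority_floor = NULL) {
  name <- match.arg(name)
  mix <- name == "model_I"
  if (is.null(use_priority_floor)) use_priority_floor <- mix
  if (mix && !use_priority_floor)
    stop("model I always carries the priority floor; use model_II or a custom floor of 0")
  structure(list(name = name, use_mix_bounds = mix,
                 use_priority_floor = use_priority_floor),
            class = "model_variant")
}

#' Build the admission-planning integer program
#'
#' Decision variables are integer admissions `x[i, t]` (one per patient
#' type and day) followed by continuous deviation variables `Cpos[r, t]`
#' and `Cneg[r, t]` per resource-day. The objective maximizes revenue
#' minus deviation costs
#' `sum_i sum_t r_i x_it - sum_r sum_t (c_r^+ Cpos_rt + c_r^- Cneg_rt)`.
#'
#' Constraints: the cycle-total admission cap; per-type mix bounds on
#' cycle totals (model I); the average-priority floor; hard availability
#' caps on the expected bed census, daily exam hours and nursing hours;
#' and goal-programming linkage `load_rt - target_rt = Cpos_rt - Cneg_rt`
#' per resource-day. The direct positive-part definitions of the
#' deviations are recovered at any optimum because both unit costs are
#' positive; if a cost is zero or negative the builder warns and results
#' carry the usual goal-programming caveat. Deviation variables get the
#' valid bounds `Cpos <= available - target` and `Cneg <= target`, which
#' tighten the search without excluding any optimum.
#'
#' @param inst A [planning_instance()].
#' @param variant A [model_variant()] (default model I).
#' @return An object of class `built_model`: list with `obj`, constraint
#'   matrix `A` (dense, rows named by constraint family), row bounds
#'   `row_lb`/`row_ub`, variable bounds `var_lb`/`var_ub`, `integrality`,
#'   `var_names`, dimensions, and the originating instance and variant.
#' @export
build_model <- function(inst, variant = model_variant("model_I")) {
  bad <- validate_instance(inst)
  if (length(bad)) stop("invalid instance: ", paste(bad, collapse = "; "))
  if (!inherits(variant, "model_variant")) stop("unknown variant")
  nI <- length(inst$patient_types)
  tau <- inst$horizon
  nx <- nI * tau
  nv <- nx + 6L * tau
  surv <- inst_survival_matrix(inst)
  rev <- inst_par(inst, "revenue")
  exam <- inst_par(inst, "exam_hours")
  nurs <- inst_par(inst, "nursing_hours")
  score <- inst_par(inst, "priority_score")
  alpha <- inst_par(inst, "mix_lower")
  beta <- inst_par(inst, "mix_upper")
  rids <- c("bed", "exam", "nursing")
  AC <- vapply(rids, function(r) inst_capacity(inst, r, "available"),
               numeric(tau))            # tau x 3
  TC <- vapply(rids, function(r) inst_capacity(inst, r, "target"),
               numeric(tau))
  cpos <- vapply(rids, function(r) inst$resources[[r]]$cost_pos, 0)
  cneg <- vapply(rids, function(r) inst$resources[[r]]$cost_neg, 0)
  if (any(cpos <= 0) || any(cneg <= 0))
    warning("non-positive deviation cost: positive-part deviations are not ",
            "guaranteed at optimality")

  xi <- function(i, t) (i - 1L) * tau + t
  ip <- function(r, t) nx + (r - 1L) * tau + t            # Cpos index
  im <- function(r, t) nx + 3L * tau + (r - 1L) * tau + t # Cneg index
  var_names <- c(
    as.vector(t(outer(seq_len(nI), seq_len(tau),
                      function(i, t) sprintf("x[%d,%d]", i, t)))),
    as.vector(t(outer(1:3, seq_len(tau),
                      function(r, t) sprintf("Cpos[%s,%d]", rids[r], t)))),
    as.vector(t(outer(1:3, seq_len(tau),
                      function(r, t) sprintf("Cneg[%s,%d]", rids[r], t)))))

  obj <- numeric(nv)
  for (i in seq_len(nI)) obj[xi(i, seq_len(tau))] <- rev[i]
  for (r in 1:3) {
    obj[ip(r, seq_len(tau))] <- -cpos[r]
    obj[im(r, seq_len(tau))] <- -cneg[r]
  }

  # resource load coefficient rows over x: bed = census, exam = admissions
  # that day, nursing = nursing-weighted census
  load_row <- function(r, t) {
    row <- numeric(nv)
    if (r == 2L) {
      for (i in seq_len(nI)) row[xi(i, t)] <- exam[i]
    } else {
      w <- if (r == 1L) rep(1, nI) else nurs
      for (i in seq_len(nI)) {
        u <- seq_len(t)
        row[xi(i, u)] <- w[i] * surv[i, t - u + 1L]
      }
    }
    row
  }

  rows <- list(); lb <- numeric(); ub <- numeric(); rnames <- character()
  add <- function(row, lo, hi, nm) {
    rows[[length(rows) + 1L]] <<- row
    lb[length(lb) + 1L] <<- lo; ub[length(ub) + 1L] <<- hi
    rnames[length(rnames) + 1L] <<- nm
  }

  r0 <- numeric(nv); r0[seq_len(nx)] <- 1
  add(r0, -Inf, inst$admission_cap, "total_cap")
  if (variant$use_mix_bounds) {
    for (i in seq_len(nI)) {
      row <- numeric(nv); row[seq_len(nx)] <- -beta[i]
      row[xi(i, seq_len(tau))] <- row[xi(i, seq_len(tau))] + 1
      add(row, -Inf, 0, sprintf("mix_upper[%d]", i))
      row <- numeric(nv); row[seq_len(nx)] <- alpha[i]
      row[xi(i, seq_len(tau))] <- row[xi(i, seq_len(tau))] - 1
      add(row, -Inf, 0, sprintf("mix_lower[%d]", i))
    }
  }
  if (variant$use_priority_floor) {
    row <- numeric(nv)
    for (i in seq_len(nI))
      row[xi(i, seq_len(tau))] <- inst$priority_floor - score[i]
    add(row, -Inf, 0, "priority_floor")
  }
  for (r in 1:3) {
    for (t in seq_len(tau)) {
      lrow <- load_row(r, t)
      add(lrow, -Inf, AC[t, r], sprintf("cap[%s,%d]", rids[r], t))
      drow <- lrow; drow[ip(r, t)] <- -1; drow[im(r, t)] <- 1
      add(drow, TC[t, r], TC[t, r], sprintf("dev[%s,%d]", rids[r], t))
    }
  }

  A <- do.call(rbind, rows)
  rownames(A) <- rnames
  colnames(A) <- var_names
  var_ub <- c(rep(as.numeric(inst$admission_cap), nx),
              as.vector(vapply(1:3, function(r) pmax(AC[, r] - TC[, r], 0),
                               numeric(tau))),
              as.vector(TC))
  structure(list(obj = obj, A = A, row_lb = lb, row_ub = ub,
                 var_lb = rep(0, nv), var_ub = var_ub,
                 integrality = c(rep(TRUE, nx), rep(FALSE, 6L * tau)),
                 var_names = var_names, sense = "max",
                 n_types = nI, horizon = tau, n_x = nx,
                 instance = inst, variant = variant),
            class = "built_model")
}

#' @export
print.built_model <- function(x, ...) {
  cat("built_model (", x$variant$name, "): ", x$n_x, " integer + ",
      length(x$obj) - x$n_x, " continuous variables, ", nrow(x$A),
      " constraints\n", sep = "")
  invisible(x)
}

#' Export a built model in LP file format
#'
#' Writes the CPLEX-style LP text format readable by any standard MILP
#' solver, for inspection and debugging.
#'
#' @param model A [build_model()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  nv <- length(model$obj)
  term <- function(coef, vars) {
    keep <- which(abs(coef) > 1e-12)
    if (!length(keep)) return("0")
    paste(sprintf("%+.12g %s", coef[keep], vars[keep]), collapse = " ")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("Maximize", paste(" obj:", term(model$obj, model$var_names)),
               "Subject To"), con)
  for (k in seq_len(nrow(model$A))) {
    lhs <- term(model$A[k, ], model$var_names)
    nm <- gsub("[^A-Za-z0-9_]", "_", rownames(model$A)[k])
    if (is.finite(model$row_lb[k]) && model$row_lb[k] == model$row_ub[k]) {
      writeLines(sprintf(" %s: %s = %.12g", nm, lhs, model$row_ub[k]), con)
    } else {
      if (is.finite(model$row_ub[k]))
        writeLines(sprintf(" %s: %s <= %.12g", nm, lhs, model$row_ub[k]), con)
      if (is.finite(model$row_lb[k]))
        writeLines(sprintf(" %s_lo: %s >= %.12g", nm, lhs, model$row_lb[k]), con)
    }
  }
  writeLines("Bounds", con)
  for (j in seq_len(nv))
    writeLines(sprintf(" %.12g <= %s <= %.12g", model$var_lb[j],
                       model$var_names[j], model$var_ub[j]), con)
  writeLines("General", con)
  writeLines(paste("", paste(model$var_names[model$integrality],
                             collapse = " ")), con)
  writeLines("End", con)
  invisible(path)
}
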
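# Domain types for the planning problem: patient types, resources, full
# instances; validation; YAML/CSV readers and writers; the packaged
# case-study instance.

#' Define an elective patient type
#'
#' @param id Character label, e.g. `"type_I"`.
#' @param revenue Revenue per admitted patient (money units). Positive.
#' @param exam_hours Medical-examination hours consumed once, on the
#'   admission day.
#' @param nursing_hours Nursing hours consumed per in-hospital patient-day.
#' @param priority_score Dimensionless admission-priority score; higher
#'   means more urgent for a tertiary-care setting.
#' @param mix_lower,mix_upper Lower and upper bounds on this type's share
#'   of total cycle admissions, in `[0, 1]` with `mix_lower <= mix_upper`.
#' @param survival A [los_survival()] curve (or numeric vector) for the
#'   type's length of stay.
#' @return An object of class `patient_type`.
#' @export
patient_type <- function(id, revenue, exam_hours, nursing_hours,
                         priority_score, mix_lower, mix_upper, survival) {
  pt <- structure(
    list(id = as.character(id), revenue = as.numeric(revenue),
         exam_hours = as.numeric(exam_hours),
         nursing_hours = as.numeric(nursing_hours),
         priority_score = as.numeric(priority_score),
         mix_lower = as.numeric(mix_lower), mix_upper = as.numeric(mix_upper),
         survival = los_survival(unclass(survival))),
    class = "patient_type")
  bad <- patient_type_violations(pt)
  if (length(bad)) stop("invalid patient type '", id, "': ",
                        paste(bad, collapse = "; "))
  pt
}

patient_type_violations <- function(pt) {
  out <- character()
  if (!isTRUE(pt$revenue > 0)) out <- c(out, "revenue must be positive")
  if (!isTRUE(pt$exam_hours >= 0)) out <- c(out, "exam hours must be nonnegative")
  if (!isTRUE(pt$nursing_hours >= 0)) out <- c(out, "nursing hours must be nonnegative")
  if (!isTRUE(pt$priority_score >= 0)) out <- c(out, "priority score must be nonnegative")
  if (!isTRUE(pt$mix_lower >= 0 && pt$mix_upper <= 1 &&
              pt$mix_lower <= pt$mix_upper))
    out <- c(out, "mix bounds must satisfy 0 <= lower <= upper <= 1")
  c(out, survival_violations(unclass(pt$survival)))
}

#' Define a resource (bed, exam or nursing capacity)
#'
#' Capacities are stored per day even when constant, so day-varying
#' profiles and target sweeps need no schema change. Bed capacity is in
#' beds; examination and nursing capacity in hours per day.
#'
#' @param id One of `"bed"`, `"exam"`, `"nursing"`.
#' @param available Daily available (hard) capacity; scalar or vector.
#' @param target Daily target capacity, `0 <= target <= available`;
#'   utilization below the target incurs the idle cost `cost_neg` per
#'   unit, above it the overuse cost `cost_pos` per unit.
#' @param cost_pos,cost_neg Nonnegative unit deviation costs (money per
#'   bed-day or per hour).
#' @param horizon Cycle length used to recycle scalar capacities.
#' @return An object of class `resource_spec`.
#' @export
resource_spec <- function(id, available, target, cost_pos, cost_neg,
                          horizon = NULL) {
  id <- match.arg(id, c("bed", "exam", "nursing"))
  if (!is.null(horizon)) {
    if (length(available) == 1L) available <- rep(available, horizon)
    if (length(target) == 1L) target <- rep(target, horizon)
  }
  rs <- structure(
    list(id = id, available = as.numeric(available),
         target = as.numeric(target),
         cost_pos = as.numeric(cost_pos), cost_neg = as.numeric(cost_neg)),
    class = "resource_spec")
  bad <- resource_violations(rs)
  if (length(bad)) stop("invalid resource '", id, "': ",
                        paste(bad, collapse = "; "))
  rs
}

resource_violations <- function(rs) {
  out <- character()
  if (length(rs$available) != length(rs$target))
    return("available and target capacity must have the same length")
  if (any(rs$target < 0) || any(rs$target > rs$available + 1e-9))
    out <- c(out, paste0(rs$id, ": target capacity must lie in [0, available]"))
  if (rs$cost_pos < 0 || rs$cost_neg < 0)
    out <- c(out, paste0(rs$id, ": deviation costs must be nonnegative"))
  out
}

#' Assemble a planning instance
#'
#' @param patient_types List of [patient_type()] objects.
#' @param resources List of three [resource_spec()] objects (bed, exam,
#'   nursing, in any order; accessed by id).
#' @param horizon Planning-cycle length in days.
#' @param admission_cap Upper bound on total admissions over the cycle
#'   (the demand estimate); use a large value when non-binding.
#' @param priority_floor Lower bound on the admission-weighted average
#'   priority score; 0 disables it.
#' @return An object of class `planning_instance`.
#' @export
planning_instance <- function(patient_types, resources, horizon,
                              admission_cap, priority_floor = 0) {
  ids <- vapply(resources, function(r) r$id, "")
  names(resources) <- ids
  inst <- structure(
    list(patient_types = patient_types,
         resources = resources[c("bed", "exam", "nursing")],
         horizon = as.integer(horizon),
         admission_cap = as.integer(admission_cap),
         priority_floor = as.numeric(priority_floor)),
    class = "planning_instance")
  bad <- validate_instance(inst)
  if (length(bad)) stop("invalid instance: ", paste(bad, collapse = "; "))
  inst
}

#' Validate a planning instance
#'
#' Checks every structural invariant and returns one message per
#' violation; an empty character vector means the instance is valid.
#' Unlike the constructors, this never raises, so it can be used to
#' triage instances read from files.
#'
#' @param inst A `planning_instance` (possibly hand-assembled).
#' @return Character vector of violation messages (empty iff valid).
#' @export
validate_instance <- function(inst) {
  out <- character()
  if (!is.list(inst$patient_types) || length(inst$patient_types) < 1L)
    out <- c(out, "instance needs at least one patient type")
  if (length(inst$resources) != 3L || !setequal(names(inst$resources),
                                                c("bed", "exam", "nursing")))
    out <- c(out, "instance needs bed, exam and nursing resources")
  if (!isTRUE(inst$horizon >= 1L)) out <- c(out, "horizon must be at least 1")
  if (!isTRUE(inst$admission_cap >= 0L))
    out <- c(out, "admission cap must be nonnegative")
  for (pt in inst$patient_types) {
    bad <- patient_type_violations(pt)
    if (length(bad)) out <- c(out, paste0(pt$id, ": ", bad))
    if (length(unclass(pt$survival)) < inst$horizon)
      out <- c(out, paste0(pt$id, ": survival curve shorter than horizon"))
  }
  for (rs in inst$resources) {
    bad <- resource_violations(rs)
    if (length(bad)) out <- c(out, bad)
    if (!is.null(rs$available) && length(rs$available) != inst$horizon &&
        length(rs$available) != 1L)
      out <- c(out, paste0(rs$id, ": capacity length differs from horizon"))
  }
  alphas <- vapply(inst$patient_types, function(p) p$mix_lower, 0)
  if (sum(alphas) > 1 + 1e-9)
    out <- c(out, "mix lower bounds sum > 1 (proportion constraints infeasible)")
  out
}

#' @export
print.planning_instance <- function(x, ...) {
  cat("planning_instance:", length(x$patient_types), "patient types,",
      x$horizon, "day cycle\n")
  for (pt in x$patient_types)
    cat(sprintf("  %-8s revenue %g, exam %g h, nursing %g h/day, score %g, mix [%g, %g], E[LOS] %.2f d\n",
                pt$id, pt$revenue, pt$exam_hours, pt$nursing_hours,
                pt$priority_score, pt$mix_lower, pt$mix_upper,
                expected_los(pt$survival)))
  for (rs in x$resources)
    cat(sprintf("  %-8s available %g, target %g, c+ %g, c- %g\n", rs$id,
                rs$available[1], rs$target[1], rs$cost_pos, rs$cost_neg))
  cat("  admission cap", x$admission_cap, "| priority floor",
      x$priority_floor, "\n")
  invisible(x)
}

# internal accessors used throughout the package
inst_survival_matrix <- function(inst) {
  t(vapply(inst$patient_types,
           function(p) unclass(p$survival)[seq_len(inst$horizon)],
           numeric(inst$horizon)))
}
inst_par <- function(inst, field) {
  vapply(inst$patient_types, function(p) p[[field]], 0)
}
inst_capacity <- function(inst, rid, field) {
  v <- inst$resources[[rid]][[field]]
  if (length(v) == 1L) rep(v, inst$horizon) else v[seq_len(inst$horizon)]
}

#' The packaged respiratory-department case-study instance
#'
#' Three elective patient types (I, II, III, ordered by priority) over a
#' 28-day cycle, with empirical LOS survival curves, and bed, examination
#' and nursing resources. Bed capacity is the 70% elective share of a
#' 290-bed department (30% is reserved for emergency arrivals). The
#' admission cap defaults to a non-binding `horizon * bed availability`
#' and the priority floor to 0, both configurable after loading.
#'
#' @return A [planning_instance()].
#' @export
#' @examples
#' inst <- base_instance()
#' validate_instance(inst)
base_instance <- function() {
  read_instance(system.file("extdata", "base_instance.yaml",
                            package = "admitplan", mustWork = TRUE))
}

#' Read a planning instance from a YAML file
#'
#' The file holds `horizon`, `admission_cap`, `priority_floor`, a
#' `patient_types` list and a `resources` list. LOS survival curves are
#' either inline (`survival:` sequences) or referenced through `los_csv`,
#' a CSV with column `s` and one column per patient-type id, as produced
#' by [write_instance()].
#'
#' @param path Path to the YAML document.
#' @return A [planning_instance()].
#' @export
read_instance <- function(path) {
  doc <- yaml::read_yaml(path)
  los <- NULL
  if (!is.null(doc$los_csv)) {
    csv <- doc$los_csv
    if (!file.exists(csv)) csv <- file.path(dirname(path), doc$los_csv)
    los <- utils::read.csv(csv, check.names = FALSE)
  }
  pts <- lapply(doc$patient_types, function(p) {
    surv <- p$survival
    if (is.null(surv)) {
      if (is.null(los)) stop("no survival curve for ", p$id,
                             " and no los_csv reference")
      surv <- los[[p$id]]
    }
    patient_type(p$id, p$revenue, p$exam_hours, p$nursing_hours,
                 p$priority_score, p$mix_lower, p$mix_upper,
                 as.numeric(unlist(surv)))
  })
  res <- lapply(doc$resources, function(r)
    resource_spec(r$id, as.numeric(unlist(r$available)),
                  as.numeric(unlist(r$target)), r$cost_pos, r$cost_neg,
                  horizon = doc$horizon))
  planning_instance(pts, res, doc$horizon,
                    admission_cap = doc$admission_cap,
                    priority_floor = doc$priority_floor %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a planning instance to a YAML file
#'
#' Emits the same schema [read_instance()] consumes, with probabilities at
#' full precision. Survival curves go inline unless `los_csv` names a CSV
#' file to hold them in the tabular `s` + one-column-per-type layout.
#'
#' @param inst A [planning_instance()].
#' @param path Output YAML path.
#' @param los_csv Optional file name (relative to `path`) for the survival
#'   table.
#' @return `path`, invisibly.
#' @export
write_instance <- function(inst, path, los_csv = NULL) {
  compact <- function(v) if (length(unique(v)) == 1L) v[1] else v
  doc <- list(
    horizon = inst$horizon,
    admission_cap = inst$admission_cap,
    priority_floor = inst$priority_floor,
    patient_types = lapply(inst$patient_types, function(p) {
      out <- list(id = p$id, revenue = p$revenue, exam_hours = p$exam_hours,
                  nursing_hours = p$nursing_hours,
                  priority_score = p$priority_score,
                  mix_lower = p$mix_lower, mix_upper = p$mix_upper)
      if (is.null(los_csv)) out$survival <- as.numeric(unclass(p$survival))
      out
    }),
    resources = lapply(inst$resources, function(r)
      list(id = r$id, available = compact(r$available),
           target = compact(r$target),
           cost_pos = r$cost_pos, cost_neg = r$cost_neg)))
  names(doc$resources) <- NULL
  if (!is.null(los_csv)) {
    doc$los_csv <- los_csv
    tab <- data.frame(s = seq_len(inst$horizon) - 1L)
    for (p in inst$patient_types)
      tab[[p$id]] <- as.numeric(unclass(p$survival))[seq_len(inst$horizon)]
    utils::write.csv(tab, file.path(dirname(path), los_csv),
                     row.names = FALSE)
  }
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}
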
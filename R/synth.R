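# Synthetic instance generation for property testing, plus two
# independent oracles: exhaustive enumeration for tiny integer programs
# and Monte-Carlo discharge simulation for the census expectation.

#' Configuration for the synthetic instance generator
#'
#' Oracle-sized configurations keep the enumeration space of
#' [brute_force_optimum()] tractable (small horizons, small per-day
#' admission caps); non-oracle configurations may span the full 28-day
#' cycle for structural tests.
#'
#' @param seed Integer seed; generation is a pure function of it.
#' @param n_types Number of patient types (1-3).
#' @param horizon Cycle length in days (1-6 when `oracle_sized`, up to 28
#'   otherwise).
#' @param oracle_sized Keep capacities and the admission cap small enough
#'   for exhaustive enumeration.
#' @param revenue_range,cost_range Uniform ranges for per-patient revenue
#'   and for the deviation unit costs.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed, n_types = 2L, horizon = 3L,
                         oracle_sized = TRUE,
                         revenue_range = c(50, 200),
                         cost_range = c(1, 40)) {
  stopifnot(n_types >= 1L, n_types <= 3L, horizon >= 1L,
            horizon <= if (oracle_sized) 6L else 28L)
  structure(list(seed = as.integer(seed), n_types = as.integer(n_types),
                 horizon = as.integer(horizon), oracle_sized = oracle_sized,
                 revenue_range = revenue_range, cost_range = cost_range),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a random valid planning instance
#'
#' LOS curves are truncated geometric-like survival curves; mix bounds
#' are drawn so that the lower bounds sum below 1 and each upper bound
#' dominates its lower bound, which makes every generated instance pass
#' [validate_instance()] by construction (the zero plan is always
#' feasible, so generated models always admit an optimum).
#'
#' @param cfg A [synth_config()].
#' @return A [planning_instance()].
#' @export
#' @examples
#' inst <- generate_instance(synth_config(seed = 1))
#' validate_instance(inst)
generate_instance <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    nI <- cfg$n_types; tau <- cfg$horizon
    pts <- vector("list", nI)
    if (nI == 1L) {
      beta <- 1; alpha <- 0
    } else {
      beta <- round(stats::runif(nI, 1 / nI, 1), 2)
      alpha <- round(stats::runif(nI, 0, 0.8 / nI), 2)
      alpha <- pmin(alpha, beta)
    }
    for (i in seq_len(nI)) {
      p_dis <- stats::runif(1, 0.3, 0.8)   # daily discharge probability
      surv <- cumprod(c(1, rep(1 - p_dis, tau - 1L)))
      pts[[i]] <- patient_type(
        id = paste0("syn_", i),
        revenue = round(stats::runif(1, cfg$revenue_range[1],
                                     cfg$revenue_range[2]), 1),
        exam_hours = round(stats::runif(1, 0.5, 2), 2),
        nursing_hours = round(stats::runif(1, 0.25, 2), 2),
        priority_score = round(stats::runif(1, 1, 10), 1),
        mix_lower = alpha[i], mix_upper = beta[i],
        survival = surv)
    }
    if (cfg$oracle_sized) {
      bed_ac <- sample(2:3, 1)
      n_cap <- sample(2:5, 1)
    } else {
      bed_ac <- sample(50:250, 1)
      n_cap <- bed_ac * tau
    }
    emax <- max(vapply(pts, function(p) p$exam_hours, 0))
    nmax <- max(vapply(pts, function(p) p$nursing_hours, 0))
    mk <- function(id, ac) {
      tc <- round(stats::runif(1, 0.5, 1) * ac, 2)
      resource_spec(id, ac, tc,
                    cost_pos = round(stats::runif(1, cfg$cost_range[1],
                                                  cfg$cost_range[2]), 2),
                    cost_neg = round(stats::runif(1, cfg$cost_range[1],
                                                  cfg$cost_range[2]), 2),
                    horizon = tau)
    }
    res <- list(mk("bed", bed_ac),
                mk("exam", round(emax * bed_ac * stats::runif(1, 0.8, 1.5), 2)),
                mk("nursing", round(nmax * bed_ac * stats::runif(1, 1, 2), 2)))
    planning_instance(pts, res, tau, admission_cap = n_cap,
                      priority_floor = 0)
  })
}

#' Exhaustive enumeration oracle for tiny instances
#'
#' Enumerates every integer admission matrix within the per-variable caps
#' implied by the hard capacities, checks all constraints by direct
#' arithmetic, and evaluates the objective with deviations computed
#' directly as positive parts `[load - target]+` / `[target - load]+` --
#' deliberately not reusing the goal-programming linearization, so that
#' agreement with [solve_model()] validates the linearized model.
#'
#' @param inst A [planning_instance()]; the search space (product of
#'   per-variable caps + 1) must not exceed `max_space`.
#' @param variant A [model_variant()].
#' @param max_space Enumeration-size guard.
#' @return List with `objective`, the maximizing `x`, and `n_evaluated`.
#' @export
brute_force_optimum <- function(inst, variant = model_variant("model_I"),
                                max_space = 1e6) {
  nI <- length(inst$patient_types); tau <- inst$horizon
  exam <- inst_par(inst, "exam_hours"); nurs <- inst_par(inst, "nursing_hours")
  AC <- t(vapply(c("bed", "exam", "nursing"),
                 function(r) inst_capacity(inst, r, "available"), numeric(tau)))
  caps <- matrix(0L, nI, tau)
  for (i in seq_len(nI)) for (t in seq_len(tau)) {
    cap <- min(inst$admission_cap, floor(AC["bed", t] + 1e-9),
               if (exam[i] > 0) floor(AC["exam", t] / exam[i] + 1e-9) else Inf,
               if (nurs[i] > 0) floor(AC["nursing", t] / nurs[i] + 1e-9) else Inf)
    caps[i, t] <- as.integer(max(cap, 0))
  }
  space <- prod(caps + 1)
  if (space > max_space)
    stop("enumeration space ", format(space, big.mark = ","),
         " exceeds max_space = ", format(max_space, big.mark = ","))
  grid <- as.matrix(expand.grid(lapply(as.vector(t(caps)),
                                       function(k) 0:k)))  # K x (nI*tau)
  K <- nrow(grid)
  # feasibility by direct arithmetic, vectorized over candidates
  N <- rowSums(grid)
  ok <- N <= inst$admission_cap
  tot <- matrix(vapply(seq_len(nI),
                       function(i) rowSums(grid[, (i - 1L) * tau + seq_len(tau),
                                                drop = FALSE]),
                       numeric(K)), nrow = K)
  if (variant$use_mix_bounds) {
    beta <- inst_par(inst, "mix_upper"); alpha <- inst_par(inst, "mix_lower")
    for (i in seq_len(nI)) {
      ok <- ok & tot[, i] <= beta[i] * N + 1e-9
      ok <- ok & tot[, i] >= alpha[i] * N - 1e-9
    }
  }
  if (variant$use_priority_floor) {
    score <- inst_par(inst, "priority_score")
    ok <- ok & (as.vector(tot %*% score) >= inst$priority_floor * N - 1e-9)
  }
  surv <- inst_survival_matrix(inst)
  census_cols <- vector("list", tau)   # K x nI census per day
  for (t in seq_len(tau)) {
    M <- matrix(0, K, nI)
    for (i in seq_len(nI)) for (u in seq_len(t))
      M[, i] <- M[, i] + surv[i, t - u + 1L] * grid[, (i - 1L) * tau + u]
    census_cols[[t]] <- M
  }
  TCm <- t(vapply(c("bed", "exam", "nursing"),
                  function(r) inst_capacity(inst, r, "target"), numeric(tau)))
  cpos <- vapply(inst$resources, function(r) r$cost_pos, 0)
  cneg <- vapply(inst$resources, function(r) r$cost_neg, 0)
  rev <- inst_par(inst, "revenue")
  objective <- as.vector(tot %*% rev)
  for (t in seq_len(tau)) {
    M <- census_cols[[t]]
    loads <- cbind(bed = rowSums(M),
                   exam = as.vector(grid[, (seq_len(nI) - 1L) * tau + t,
                                         drop = FALSE] %*% exam),
                   nursing = as.vector(M %*% nurs))
    for (r in 1:3) {
      ok <- ok & loads[, r] <= AC[r, t] + 1e-9
      dev <- loads[, r] - TCm[r, t]
      objective <- objective - cpos[r] * pmax(dev, 0) - cneg[r] * pmax(-dev, 0)
    }
  }
  objective[!ok] <- -Inf
  best <- which.max(objective)
  x <- matrix(as.integer(grid[best, ]), nrow = nI, byrow = TRUE,
              dimnames = list(type = vapply(inst$patient_types,
                                            function(p) p$id, ""),
                              day = seq_len(tau)))
  list(objective = unname(objective[best]), x = x, n_evaluated = K,
       n_feasible = sum(ok))
}

#' Monte-Carlo discharge simulation of the in-hospital census
#'
#' Every admitted patient draws a length of stay from the type's pmf and
#' occupies a bed from the admission day through discharge, truncated at
#' the horizon. Residual pmf mass beyond the horizon corresponds to
#' staying through the whole remaining cycle. Returns per-day, per-type
#' empirical mean censuses with standard errors over replications, the
#' stochastic counterpart of [census_matrix()].
#'
#' @param x Type-by-day admission matrix.
#' @param pmfs List of [los_pmf()] (or survival curves, converted) per type.
#' @param reps Number of independent replications of the whole plan.
#' @param seed RNG seed.
#' @return List with matrices `mean` and `se` (types x days), vectors
#'   `total_mean` and `total_se` (all-type census per day) and `reps`.
#' @export
simulate_census <- function(x, pmfs, reps = 200L, seed = 1L) {
  x <- as.matrix(x)
  nI <- nrow(x); tau <- ncol(x)
  stopifnot(reps >= 1L, length(pmfs) == nI)
  with_seed(seed, {
    mean_m <- matrix(0, nI, tau, dimnames = dimnames(x))
    se_m <- mean_m
    tot_occ <- matrix(0, reps, tau)
    for (i in seq_len(nI)) {
      pmf <- if (inherits(pmfs[[i]], "los_survival"))
        unclass(pmf_from_survival(pmfs[[i]])) else unclass(pmfs[[i]])
      pmf <- pmf[seq_len(min(length(pmf), tau))]
      resid <- max(0, 1 - sum(pmf))
      prob <- c(pmf, resid)          # LOS = tau+1 means "beyond horizon"
      occ <- matrix(0, reps, tau)    # per-rep census of this type
      for (u in seq_len(tau)) {
        k <- x[i, u]
        if (k == 0) next
        los <- sample.int(tau + 1L, size = reps * k, replace = TRUE,
                          prob = prob)
        los <- matrix(los, reps, k)
        # patient occupies days u .. min(u + los - 1, tau)
        lastday <- pmin(u + los - 1L, tau)
        for (t in u:tau)
          occ[, t] <- occ[, t] + rowSums(lastday >= t)
      }
      mean_m[i, ] <- colMeans(occ)
      se_m[i, ] <- apply(occ, 2, stats::sd) / sqrt(reps)
      tot_occ <- tot_occ + occ
    }
    list(mean = mean_m, se = se_m,
         total_mean = colMeans(tot_occ),
         total_se = apply(tot_occ, 2, stats::sd) / sqrt(reps),
         reps = reps)
  })
}
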
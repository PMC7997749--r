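# Length-of-stay probability machinery: survival curves, pmfs, expected
# stay and the expected-census operator linking admissions to occupancy.

#' Survival curve of length of stay
#'
#' A discrete LOS survival curve stores `P(LOS > s)` for `s = 0, ...,
#' horizon - 1`. By convention `P(LOS > 0) = 1` (every admitted patient is
#' in hospital on the admission day) and stays longer than the planning
#' horizon are truncated: the curve is treated as 0 from `s = horizon` on.
#'
#' @param values Numeric vector of exceedance probabilities, starting at
#'   `s = 0`. Must begin with 1, be nonincreasing, and lie in `[0, 1]`.
#' @return A numeric vector of class `los_survival`.
#' @seealso [pmf_from_survival()], [survival_from_pmf()], [expected_los()]
#' @export
#' @examples
#' los_survival(c(1, 0.5, 0.25))
los_survival <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("survival curve needs at least one value")
  bad <- survival_violations(values)
  if (length(bad)) stop("invalid survival curve: ", paste(bad, collapse = "; "))
  structure(values, class = "los_survival")
}

# internal: report (not raise) survival-curve invariant violations
survival_violations <- function(values, tol = 1e-9) {
  out <- character()
  if (anyNA(values)) return("survival contains NA")
  if (abs(values[1] - 1) > tol) out <- c(out, "survival must start at 1 (P(LOS > 0) = 1)")
  if (any(values < -tol) || any(values > 1 + tol))
    out <- c(out, "survival values outside [0, 1]")
  if (length(values) > 1L && any(diff(values) > tol))
    out <- c(out, "survival not nonincreasing")
  out
}

#' Length-of-stay probability mass function
#'
#' `values[t]` is the probability that a patient stays exactly `t` days,
#' for `t = 1, ..., horizon`. Mass may sum to less than 1 when the
#' distribution is truncated at the horizon; the residual mass corresponds
#' to patients still in hospital at the end of the cycle.
#'
#' @param values Nonnegative numeric vector with `sum(values) <= 1`.
#' @return A numeric vector of class `los_pmf`.
#' @export
los_pmf <- function(values) {
  values <- as.numeric(values)
  tol <- 1e-9
  if (length(values) < 1L) stop("pmf needs at least one value")
  if (anyNA(values)) stop("pmf contains NA")
  if (any(values < -tol)) stop("pmf has negative mass")
  if (sum(values) > 1 + 1e-8) stop("pmf mass sums to more than 1")
  structure(pmax(values, 0), class = "los_pmf")
}

#' Convert an LOS pmf to its survival curve
#'
#' The survival value at `s` is `P(LOS > s) = 1 - sum(P(LOS = t), t <= s)`.
#' The result has the same length as the pmf (indices `s = 0 ...
#' horizon - 1`).
#'
#' @param pmf A [los_pmf()] or a plain numeric vector interpreted as one.
#' @return A [los_survival()] vector.
#' @export
#' @examples
#' survival_from_pmf(c(0.5, 0.5)) # (1, 0.5)
survival_from_pmf <- function(pmf) {
  pmf <- los_pmf(unclass(pmf))
  tau <- length(pmf)
  surv <- 1 - cumsum(c(0, pmf))[seq_len(tau)]
  # clamp tiny negative round-off
  los_survival(pmin(pmax(surv, 0), 1))
}

#' Convert an LOS survival curve to its pmf
#'
#' Exact inverse of [survival_from_pmf()]: `P(LOS = t) = P(LOS > t - 1) -
#' P(LOS > t)` with the survival curve taken as 0 at the horizon, so the
#' final mass absorbs every stay that would outlast the cycle.
#'
#' @param surv A [los_survival()] or a plain numeric vector interpreted as
#'   one.
#' @return A [los_pmf()] vector of the same length.
#' @export
#' @examples
#' pmf_from_survival(c(1, 0.5)) # (0.5, 0.5)
pmf_from_survival <- function(surv) {
  surv <- los_survival(unclass(surv))
  los_pmf(-diff(c(unclass(surv), 0)))
}

#' Expected length of stay
#'
#' Uses the tail-sum identity `E[LOS] = sum_s P(LOS > s)` over the stored
#' horizon, i.e. the expected number of in-hospital days within the cycle.
#'
#' @param surv A [los_survival()] or plain numeric vector.
#' @return Mean stay in days.
#' @export
expected_los <- function(surv) {
  surv <- los_survival(unclass(surv))
  sum(unclass(surv))
}

#' Expected in-hospital census implied by an admission plan
#'
#' The expected number of type-`i` patients in hospital on day `t` is the
#' convolution of admission cohorts with the type's survival curve:
#' `M[i, t] = sum_{u <= t} P(LOS_i > t - u) * x[i, u]`. Patients count
#' toward the census of their admission day (`P(LOS > 0) = 1`), and the
#' hospital starts the cycle empty.
#'
#' @param x Integer (or numeric) matrix of admissions, types in rows, days
#'   in columns.
#' @param survivals List of survival curves, one per row of `x`; each must
#'   cover at least `ncol(x)` days.
#' @return Numeric matrix of the same shape as `x` with expected censuses.
#' @export
#' @examples
#' census_matrix(matrix(c(2, 0, 0), 1), list(los_survival(c(1, 0.5, 0))))
census_matrix <- function(x, survivals) {
  x <- as.matrix(x)
  if (!is.list(survivals)) survivals <- list(survivals)
  if (nrow(x) != length(survivals))
    stop("need one survival curve per admission row (", nrow(x), " rows, ",
         length(survivals), " curves)")
  if (any(x < 0)) stop("admissions must be nonnegative")
  tau <- ncol(x)
  M <- matrix(0, nrow(x), tau, dimnames = dimnames(x))
  for (i in seq_len(nrow(x))) {
    s <- unclass(survivals[[i]])
    if (length(s) < tau)
      stop("survival curve ", i, " shorter than planning horizon")
    for (t in seq_len(tau)) {
      u <- seq_len(t)
      M[i, t] <- sum(s[t - u + 1L] * x[i, u])
    }
  }
  M
}
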
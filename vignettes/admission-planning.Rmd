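---
title: "Admission planning by patient-mix optimization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admission planning by patient-mix optimization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

Large referral hospitals routinely run inpatient wards near or above
nominal capacity while still facing long elective waiting lists. A
tactical admission plan decides, for each day `t` of a planning cycle of
`tau` days, how many elective patients of each type `i` to admit
(`x[i, t]`, a nonnegative integer). Types differ in revenue `r_i`,
one-off medical-examination time `e_i` (hours, consumed on the admission
day), per-patient-day nursing workload `n_i` (hours), a priority score
`s_i` reflecting how well the case matches the hospital's tertiary-care
mandate, and a stochastic length of stay (LOS).

Three resources constrain the plan: beds, examination capacity and
nursing capacity. Each resource `r` has a daily hard availability
`AC[r, t]` and a softer daily target `TC[r, t] <= AC[r, t]`. Utilization
above the target costs `c_r^+` per unit (overuse), utilization below it
costs `c_r^-` per unit (idle capacity) -- the goal-programming element
of the objective.

## Length of stay and the expected census

LOS is discrete, truncated at the cycle length: the survival value
`P(LOS_i > s)` is stored for `s = 0 .. tau - 1`, with `P(LOS_i > 0) = 1`
and 0 beyond the horizon. The pmf and the survival curve are exact
transforms of each other (`pmf_from_survival()`, `survival_from_pmf()`),
and `E[LOS]` is the tail sum of the survival curve.

The expected number of type-`i` patients in hospital on day `t` is the
admission-cohort convolution

    M[i, t] = sum_{u = 1}^{t} P(LOS_i > t - u) * x[i, u],

implemented in `census_matrix()`. Two modelling conventions are baked
in:

* **Cohort convolution, not a per-day product.** A day-`t` census that
  multiplied the whole cumulative survival sum by the *same day's*
  admissions would let day-1 census exceed day-1 admissions, which
  contradicts both the verbal definition of the census and an empty
  starting ward. We therefore convolve each admission cohort with the
  survival curve; `simulate_census()` (a patient-level Monte-Carlo
  discharge simulation) is tested against this operator and agrees
  within sampling error, which is the strongest internal evidence for
  the convolution reading.
* **Truncation at the horizon.** Patients whose residual stay would
  outlast the cycle are censored at day `tau`; occupancy beyond the
  horizon does not enter the objective. Patients admitted on day `t`
  count toward day `t`'s bed and nursing load.

The census is an expectation and therefore real-valued even though
admissions are integers; no rounding happens inside the model.

## The integer program

`build_model()` assembles, for a `planning_instance`:

* objective: maximize
  `sum_i sum_t r_i x[i,t] - sum_r sum_t (c_r^+ Cpos[r,t] + c_r^- Cneg[r,t])`;
* a cycle-total admission cap `sum x <= n` (the demand estimate);
* per-type mix bounds on cycle totals,
  `alpha_i * N <= sum_t x[i,t] <= beta_i * N` with `N` the total
  admissions (model I only). The bounds act on cycle totals; per-day
  copies would be redundant because the sums already run over the whole
  cycle;
* the average-priority floor
  `sum_i s_i sum_t x[i,t] >= L_p * N` (model I; switchable);
* hard caps: bed census `sum_i M[i,t] <= AC[bed,t]`, admission-day exam
  hours `sum_i e_i x[i,t] <= AC[exam,t]`, nursing hours
  `sum_i n_i M[i,t] <= AC[nursing,t]`;
* goal-programming linkage per resource-day:
  `load[r,t] - TC[r,t] = Cpos[r,t] - Cneg[r,t]`, `Cpos, Cneg >= 0`.

The deviation variables are the standard linearization of the
positive-part definitions `Cpos = [load - TC]+`, `Cneg = [TC - load]+`;
the two coincide at any optimum because both unit costs are strictly
positive (the builder warns when they are not). Deviations get the
valid bounds `Cpos <= AC - TC` and `Cneg <= TC`, which cannot exclude
an optimum but help the solver. `model_variant("model_II")` drops the
mix bounds and (by default) the priority floor, the homogeneous-patient
relaxation; the floor flag is independently switchable because the two
halves of the source material disagree on whether the relaxation keeps
it.

Emergency demand is not modelled explicitly: the case-study bed
availability is already the 70% elective share of the physical ward
(30% reserved), and the same convention is expected of user instances.

## Solving

No exact MILP solver is available as an R library in this stack, so
`solve_model()` drives the HiGHS branch-and-bound solver through a small
JSON bridge (`inst/python/solve_milp.py`, scipy's `milp`) in the
scientific Python environment installed alongside R. The package builds
all matrices itself; the bridge only relays them. Three details matter:

* **Equivalent tightening.** Before handing the model over, the solver
  layer introduces integer per-type cycle totals `y_i` and the grand
  total `N` as explicit variables and rewrites cap, mix and priority
  rows over them. The feasible set of `x` and the optimal value are
  unchanged, but branching on the aggregates closes the integrality gap
  far faster on proportion-constrained instances.
* **Deterministic stopping.** Termination is by relative MIP gap
  (default `1e-3`) and a branch-and-bound node limit (default 20,000),
  never by wall-clock time, so repeated runs -- also on machines of
  different speeds -- reproduce identical plans. When the node limit
  fires first the plan is returned with status `"limit"` and its proven
  gap attached, never silently. Proving optimality to gap 0 is cheap on
  small instances (and the oracle tests do exactly that) but the
  case-study instance has a wide plateau of near-optimal plans that
  differ by one admission shifted between days; closing the last
  fraction of a percent takes orders of magnitude longer than finding
  the incumbent, which is why the defaults accept a 0.1% certificate.
* **Single source of truth.** Census, deviations and the objective of a
  returned plan are recomputed in R from the integer `x` alone, with
  deviations as direct positive parts; the solver's auxiliary variables
  are never trusted. `check_plan()` re-verifies every constraint by
  direct arithmetic. Alternate optima may differ in `x` at identical
  objective; downstream checks therefore compare objectives, totals and
  mixes, not the full admission matrix.

The independent correctness anchor is `brute_force_optimum()`:
exhaustive enumeration over all integer plans of oracle-sized instances
(search spaces up to 10^6), with deviations computed directly as
positive parts -- deliberately not reusing the linearization. The test
suite checks exact agreement between enumeration and the solver on 100
generated instances.

## The case-study instance and what it reproduces

`base_instance()` ships the respiratory-department case study: three
patient types over a 28-day cycle; revenues 170/160/150, exam hours
1.5/1/1.5, nursing hours 1.5/1/0.5, priority scores 9/6.5/3; mix bounds
upper (0.7, 0.2, 0.1) and lower (0.5, 0.1, 0); bed 203/183, exam
201.6/181 h, nursing 561/512 h daily available/target capacity, all
with `c+ = 20`, `c- = 30`. Two fields the source tables do not print
are defaulted to non-binding values and are configurable: the admission
cap (`28 * 203 = 5684`) and the priority floor (0; with the upper mix
bounds summing to 1 the base-case average score is forced to 7.9
regardless). In the printed parameter table the first bracket entry is
the larger one; it is read as the upper bound, the only reading
consistent with feasibility of the proportion constraints.

Two reproduction notes, stated here because they shape the acceptance
suite:

* **The published mix and admission structure reproduces; the published
  objective values do not.** The optimal plan of the faithful model
  hits the forced 70/20/10 mix exactly, fills the ward (bed utilization
  near 99%), and without mix bounds a priority floor of 9 admits only
  type-I patients -- all as published. The published *objective values*
  (thousands, positive), however, are arithmetically unreachable from
  the published parameters under any census reading: the daily nursing
  load can never exceed `1.5 h * 203 beds = 304.5 h`, far below its
  512 h target, and a 28-day plan of several hundred admissions
  consumes well under 1,000 exam hours against a 5,068 h cycle target,
  so idle-capacity costs of roughly 300,000 money units are unavoidable
  and every feasible objective is deeply negative. The package reports
  what the model actually yields (base-case objective about -239,000 =
  revenue 96,280 minus deviation costs); the acceptance tests assert
  the reproducible structure (mix, invariants) and state the published
  objective values verbatim where they are checked, leaving them red
  rather than rescaling any parameter to force agreement.
* **The target-capacity sweep moves the bed target only.** The sweep's
  printed utilization column equals bed target / 203 for every row, so
  the packaged `bed_targets` config raises the bed target 183..195 and
  leaves exam and nursing targets untouched.

## The synthetic generator

`generate_instance()` draws instances for property tests: truncated
geometric-like survival curves (constant daily discharge probability),
uniform revenues, exam/nursing hours, priority scores, mix bounds with
`sum(alpha) < 1 <= max(beta)` granted by construction, and (in
oracle-sized mode) capacities and admission caps small enough that the
enumeration oracle stays under a million candidates. Generation is a
pure function of the seed and restores the caller's RNG state. It
emulates the *structure* of real instances, not their content: real LOS
curves are not geometric, real wards have weekday patterns and
non-stationary demand, and real deviation costs are asymmetric across
resources. Passing the property suite therefore certifies the algebra
and the solver contract, not the realism of any particular parameter
set.

`simulate_census()` complements it as the stochastic oracle: every
admitted patient samples an LOS from the type pmf (residual mass beyond
the horizon means staying through the cycle) and occupies a bed from
admission to discharge, truncated at `tau`. Mean occupancies converge
to `census_matrix()` at the usual `1/sqrt(reps)` rate, which the tests
check at two replication levels.

## Numerical choices and degenerate inputs

* Feasibility and identity tolerances are `1e-6` (objective agreement
  `1e-6` relative); probability invariants use `1e-9`.
* A zero admission cap is legitimate: the empty plan is returned with
  the pure idle-capacity objective `-sum_r c_r^- sum_t TC[r, t]`.
* Zero admissions make proportions and the average priority undefined;
  KPIs report `NA`, never a division error.
* Instances with `sum(alpha) > 1` are rejected at validation (the
  proportion constraints would forbid any nonzero plan); scenario
  sweeps record an invalid or infeasible scenario and continue.
* Sweep tables keep scenario labels verbatim (including source
  numbering gaps) and full precision; rounding is left to reporting.
* Monte-Carlo census validation checks daily census totals at three
  standard errors per day; the roughly 900 per-type day-cells checked
  across all validation plans use a familywise (Šidák-adjusted)
  threshold instead, because ~900 simultaneous three-sigma checks are
  expected to produce a handful of false alarms even when the census
  operator is exactly right.

## Limitations

The model is deterministic in expectation: no sample-path census inside
the optimizer, no recourse, no rolling horizon, no emergency arrival
process beyond the capacity reservation, and no per-day mix quotas.
Upstream patient classification (how types are assigned before
admission) is out of scope; types are inputs. The solver certificate is
a relative gap, not always proof of exact optimality on the full-size
instance; all structural acceptance checks are robust to the default
0.1% gap.
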
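# admitplan

Tactical admission planning for elective patients in capacity-constrained
hospital departments, by patient-mix optimization.

Hospital managers planning a 4-week admission cycle face a joint decision:
how many elective patients to admit in total, in what mix across patient
types of different priority, and on which days — under hard daily limits on
beds, medical-examination time and nursing time, and soft daily utilization
targets for each of those resources. `admitplan` builds and solves the
integer program behind that decision and ships the surrounding machinery a
planner or researcher needs: instance files, scenario sweeps, a model
comparison, a synthetic instance generator and two independent validation
oracles.

## The model

For patient types `i` and days `t = 1..τ`, choose integer admissions
`x_it` to maximize

```
Z = Σ_i Σ_t r_i x_it − Σ_r Σ_t (c_r⁺ C⁺_rt + c_r⁻ C⁻_rt)
```

subject to

- `Σ_i Σ_t x_it ≤ n` — cycle demand estimate;
- `α_i N ≤ Σ_t x_it ≤ β_i N` — per-type share of total admissions `N`
  (model I; model II drops these);
- `Σ_i s_i Σ_t x_it ≥ L_p N` — average-priority floor;
- `M_it = Σ_{u≤t} P(LOS_i > t−u) x_iu` — expected census as the
  convolution of admission cohorts with the type's LOS survival curve;
- hard caps: bed census `Σ_i M_it ≤ AC_bed`, exam hours
  `Σ_i e_i x_it ≤ AC_exam`, nursing hours `Σ_i n_i M_it ≤ AC_nursing`;
- goal-programming deviations per resource-day:
  `load_rt − TC_rt = C⁺_rt − C⁻_rt`, `C± ≥ 0`.

Lengths of stay are stochastic and enter only through their survival
curves; the census is an expectation. The MILP is solved by HiGHS through
a thin bridge into the co-installed scientific Python stack, with
deterministic gap/node-limit stopping; every returned plan is re-verified
in R by direct arithmetic, and exhaustive enumeration on small instances
serves as an independent oracle.

## Worked example

```r
library(admitplan)
inst <- base_instance()          # packaged respiratory-department case study
plan <- solve_model(build_model(inst))
compute_kpis(plan)
```

```
objective -239348.85 = revenue 96280.00 - overuse 10930.00 - idle 324698.85
admissions 580 ( type_I 406 [70.00%], type_II 116 [20.00%], type_III 58 [10.00%] )
average priority 7.90 | mean utilization bed 98.6%, exam 14.4%, nursing 49.9%
```

The optimum admits 580 patients at exactly the 70/20/10 type mix (forced
because the upper share bounds sum to 1), fills the 203 elective beds to
98.6% mean utilization, and carries large idle-capacity costs on the exam
and nursing targets, which are far above any load a 203-bed ward can
generate — see the methods vignette (`vignettes/admission-planning.Rmd`)
for why the objective is negative here and how that relates to the
published case-study figures.

Scenario analysis and the model comparison:

```r
tab <- run_sweep(read_sweep_config("nursing_hours"))   # packaged sweep grid
cmp <- compare_models(inst, comparison_mix_scenarios())
sweep9 <- priority_floor_sweep(inst, c(0, 3, 6, 9))    # mix bounds off
```

A thin command-line front end covers the same ground
(`exec/admitplan solve|sweep|compare|generate`).

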
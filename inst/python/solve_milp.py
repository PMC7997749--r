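#!/usr/bin/env python
"""Thin MILP bridge: read problems as JSON, solve with scipy's HiGHS
backend, write solutions as JSON.

Input schema: {"options": {...}, "problems": [{"ncol": int,
  "obj": [...maximize...], "A": {"i": [...], "j": [...], "v": [...]}  (0-based),
  "nrow": int, "row_lb": [...], "row_ub": [...],
  "var_lb": [...], "var_ub": [...], "integrality": [0/1, ...]}, ...]}
Output: {"results": [{"status": str, "objective": float or None,
  "x": [...], "mip_gap": float, "mip_node_count": int}, ...]}

Deterministic: single-threaded HiGHS with gap/node stopping rules only.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "error"}


def solve_one(p, options):
    ncol = int(p["ncol"])
    obj = np.asarray(p["obj"], dtype=float)
    A = sparse.csc_matrix(
        (np.asarray(p["A"]["v"], dtype=float),
         (np.asarray(p["A"]["i"], dtype=int), np.asarray(p["A"]["j"], dtype=int))),
        shape=(int(p["nrow"]), ncol))
    lb = np.array([-np.inf if v is None else float(v) for v in p["row_lb"]])
    ub = np.array([np.inf if v is None else float(v) for v in p["row_ub"]])
    vlb = np.array([-np.inf if v is None else float(v) for v in p["var_lb"]])
    vub = np.array([np.inf if v is None else float(v) for v in p["var_ub"]])
    integ = np.asarray(p["integrality"], dtype=int)
    opts = {k: options[k] for k in ("mip_rel_gap", "time_limit", "node_limit",
                                    "presolve", "disp") if k in options}
    res = milp(-obj, constraints=LinearConstraint(A, lb, ub),
               integrality=integ, bounds=Bounds(vlb, vub), options=opts)
    status = STATUS.get(res.status, "error")
    if res.status != 0 and res.x is not None:
        status = "limit"  # stopped early but carries a feasible incumbent
    out = {"status": status,
           "status_message": getattr(res, "message", ""),
           "objective": None, "x": None,
           "mip_gap": getattr(res, "mip_gap", None),
           "mip_node_count": getattr(res, "mip_node_count", None)}
    if res.x is not None:
        out["objective"] = -float(res.fun)
        out["x"] = [float(v) for v in res.x]
    return out


def main(argv):
    infile, outfile = argv[1], argv[2]
    with open(infile) as fh:
        spec = json.load(fh)
    options = spec.get("options") or {}
    results = [solve_one(p, options) for p in spec["problems"]]
    with open(outfile, "w") as fh:
        json.dump({"results": results}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
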
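"""Batch MILP/LP solver backend.

Reads a JSON problem batch from argv[1], solves each problem with
scipy.optimize.milp (HiGHS), and writes a JSON solution batch to argv[2].

Problem format (per entry in "problems"):
  c            objective coefficients
  integrality  0 (continuous) / 1 (integer) per variable
  lb, ub       variable bounds (use +/-1e30 for infinite)
  rows         {"i": [...], "j": [...], "x": [...]}  1-based triplets
  row_lb, row_ub  per-row bounds
  time_limit   seconds (optional)
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e30


def solve_one(p):
    c = np.asarray(p["c"], dtype=float)
    nvar = c.size
    lb = np.asarray(p["lb"], dtype=float)
    ub = np.asarray(p["ub"], dtype=float)
    lb[lb <= -INF] = -np.inf
    ub[ub >= INF] = np.inf
    integrality = np.asarray(p["integrality"], dtype=int)
    nrow = len(p["row_lb"])
    if nrow:
        A = sparse.csr_matrix(
            (
                np.asarray(p["rows"]["x"], dtype=float),
                (
                    np.asarray(p["rows"]["i"], dtype=int) - 1,
                    np.asarray(p["rows"]["j"], dtype=int) - 1,
                ),
            ),
            shape=(nrow, nvar),
        )
        rlb = np.asarray(p["row_lb"], dtype=float)
        rub = np.asarray(p["row_ub"], dtype=float)
        rlb[rlb <= -INF] = -np.inf
        rub[rub >= INF] = np.inf
        constraints = LinearConstraint(A, rlb, rub)
    else:
        constraints = ()
    options = {}
    if p.get("time_limit") is not None:
        options["time_limit"] = float(p["time_limit"])
    res = milp(
        c,
        constraints=constraints,
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options=options,
    )
    out = {"status": int(res.status), "success": bool(res.success)}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["fun"] = float(res.fun)
    return out


def main():
    with open(sys.argv[1]) as fh:
        batch = json.load(fh)
    solutions = [solve_one(p) for p in batch["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"solutions": solutions}, fh)


if __name__ == "__main__":
    main()
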
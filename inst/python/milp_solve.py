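"""Batch MILP solving through scipy.optimize.milp (HiGHS).

Reads a JSON file {"time_limit": s, "models": [...]} where each model has
objective coefficients, variable bounds and integrality flags, and sparse
constraint triplets with per-row sense/rhs. Writes a JSON list with one
{"status", "objective", "bound", "x"} object per model.
"""
import json
import sys

import numpy as np
from scipy.optimize import LinearConstraint, Bounds, milp
from scipy.sparse import csr_matrix


def solve_one(m, time_limit):
    c = np.asarray(m["obj"], dtype=float)
    n = c.size
    lb = np.asarray(m["lb"], dtype=float)
    ub = np.asarray(m["ub"], dtype=float)
    integrality = np.asarray(m["integer"], dtype=int)
    row = np.asarray(m.get("con_row", []), dtype=int)
    col = np.asarray(m.get("con_col", []), dtype=int)
    coef = np.asarray(m.get("con_coef", []), dtype=float)
    sense = m.get("row_sense", [])
    rhs = np.asarray(m.get("row_rhs", []), dtype=float)
    n_rows = len(sense)
    constraints = []
    if n_rows:
        A = csr_matrix((coef, (row, col)), shape=(n_rows, n))
        row_lb = np.where(np.isin(sense, ["=", ">="]), rhs, -np.inf)
        row_ub = np.where(np.isin(sense, ["=", "<="]), rhs, np.inf)
        constraints = [LinearConstraint(A, row_lb, row_ub)]
    res = milp(c, constraints=constraints, bounds=Bounds(lb, ub),
               integrality=integrality,
               options={"time_limit": float(time_limit)})
    if res.x is None:
        return {"status": "failed", "objective": None, "bound": None, "x": []}
    status = "optimal" if res.status == 0 else "feasible"
    bound = getattr(res, "mip_dual_bound", None)
    return {
        "status": status,
        "objective": float(res.fun),
        "bound": float(bound) if bound is not None else float(res.fun),
        "x": [float(v) for v in res.x],
    }


def main(fin, fout):
    with open(fin) as fh:
        payload = json.load(fh)
    time_limit = payload.get("time_limit", 60)
    out = [solve_one(m, time_limit) for m in payload["models"]]
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
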
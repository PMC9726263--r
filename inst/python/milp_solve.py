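"""Batch MILP bridge: read a JSON list of models, solve each with the HiGHS
solver via scipy.optimize.milp, write a JSON list of results.

Model fields: obj, lb, ub, integer (0/1), ri/rj/rv (1-based sparse rows),
rlb, rub, options {time_limit, mip_rel_gap}. Null bounds mean +/-infinity.
"""
import json
import sys
import time

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import coo_matrix


def _arr(v, fill):
    return np.array([fill if x is None else float(x) for x in v])


def solve_one(m):
    c = np.asarray(m["obj"], dtype=float)
    n = c.size
    lb = _arr(m["lb"], -np.inf)
    ub = _arr(m["ub"], np.inf)
    integrality = np.asarray(m["integer"], dtype=float)
    constraints = []
    if m.get("rlb"):
        ri = np.asarray(m["ri"], dtype=int) - 1
        rj = np.asarray(m["rj"], dtype=int) - 1
        rv = np.asarray(m["rv"], dtype=float)
        nrow = len(m["rlb"])
        A = coo_matrix((rv, (ri, rj)), shape=(nrow, n)).tocsr()
        constraints.append(
            LinearConstraint(A, _arr(m["rlb"], -np.inf), _arr(m["rub"], np.inf))
        )
    opts = m.get("options", {}) or {}
    t0 = time.perf_counter()
    res = milp(
        c,
        constraints=constraints,
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options={
            "time_limit": float(opts.get("time_limit", 60)),
            "mip_rel_gap": float(opts.get("mip_rel_gap", 1e-6)),
            "disp": False,
        },
    )
    wall = time.perf_counter() - t0
    out = {"status": int(res.status), "wall_seconds": wall}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = float(res.fun)
        out["bound"] = float(getattr(res, "mip_dual_bound", res.fun) or res.fun)
        gap = getattr(res, "mip_gap", None)
        out["gap"] = float(gap) if gap is not None else 0.0
    else:
        out["x"] = None
    return out


def main():
    fin, fout = sys.argv[1], sys.argv[2]
    with open(fin) as fh:
        models = json.load(fh)
    results = [solve_one(m) for m in models]
    with open(fout, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
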
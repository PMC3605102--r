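"""Batch LP/MILP solving helper.

Reads a JSON file holding a list of linear/mixed-integer programs, solves each
with scipy's HiGHS interface, and writes a JSON list of results.  Bounds with
magnitude >= 1e29 are treated as infinite.  Called by the R package; not a
public interface.

Usage: python milp_batch.py IN.json OUT.json
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29


def _definitize(a, sign):
    a = np.asarray(a, dtype=float)
    a[np.isnan(a)] = sign * np.inf
    a[sign * a >= BIG] = sign * np.inf
    return a


def solve_one(p):
    c = np.asarray(p["obj"], dtype=float)
    n = c.size
    sense = -1.0 if p.get("maximize", False) else 1.0
    lb = _definitize(p["lb"], -1)
    ub = _definitize(p["ub"], +1)
    integrality = np.asarray(p.get("integrality", [0] * n), dtype=int)
    constraints = []
    if p.get("A") is not None and len(p["A"]) > 0:
        A = np.asarray(p["A"], dtype=float).reshape(-1, n)
        clb = _definitize(p["con_lb"], -1)
        cub = _definitize(p["con_ub"], +1)
        constraints.append(LinearConstraint(A, clb, cub))
    if np.any(lb > ub):
        return {"status": 2, "success": False, "x": None, "objective": None,
                "message": "trivially infeasible: lb > ub"}
    res = milp(
        c=sense * c,
        constraints=constraints,
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options={"mip_rel_gap": 0.0, "presolve": True},
    )
    out = {
        "status": int(res.status),
        "success": bool(res.success),
        "message": str(res.message),
    }
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = float(sense * res.fun)
    else:
        out["x"] = None
        out["objective"] = None
    return out


def main(argv):
    with open(argv[1]) as fh:
        problems = json.load(fh)
    results = [solve_one(p) for p in problems]
    with open(argv[2], "w") as fh:
        json.dump(results, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
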
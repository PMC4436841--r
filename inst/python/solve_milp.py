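"""Solve a batch of 0-1 assignment models with HiGHS (scipy.optimize.milp).

Usage: python solve_milp.py IN.json OUT.json

IN.json is a list of problems, each:
  {"n": <vars>, "obj": [...],
   "aub": {"i": [...], "j": [...], "v": [...]}, "bub": [...],
   "aeq": {"i": [...], "j": [...], "v": [...]}, "beq": [...],
   "mip_rel_gap": float, "time_limit": float}
Row/column indices are 1-based.  All variables are binary.

OUT.json is a list of {"success": bool, "status": int, "message": str,
"objective": float|null, "x": [...]} in input order.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def triplet_matrix(tr, nrow, ncol):
    if nrow == 0:
        return None
    i = np.asarray(tr.get("i", []), dtype=int) - 1
    j = np.asarray(tr.get("j", []), dtype=int) - 1
    v = np.asarray(tr.get("v", []), dtype=float)
    return sparse.coo_matrix((v, (i, j)), shape=(nrow, ncol)).tocsc()


def as_vec(x):
    if x is None:
        return np.zeros(0)
    return np.atleast_1d(np.asarray(x, dtype=float))


def solve_one(p):
    n = int(p["n"])
    c = as_vec(p.get("obj"))
    bub = as_vec(p.get("bub"))
    beq = as_vec(p.get("beq"))
    constraints = []
    a_ub = triplet_matrix(p.get("aub", {}), len(bub), n)
    if a_ub is not None:
        constraints.append(LinearConstraint(a_ub, -np.inf, bub))
    a_eq = triplet_matrix(p.get("aeq", {}), len(beq), n)
    if a_eq is not None:
        constraints.append(LinearConstraint(a_eq, beq, beq))
    res = milp(
        c=c,
        constraints=constraints,
        integrality=np.ones(n, dtype=int),
        bounds=Bounds(np.zeros(n), np.ones(n)),
        options={
            "mip_rel_gap": float(p.get("mip_rel_gap", 1e-6)),
            "time_limit": float(p.get("time_limit", 60.0)),
        },
    )
    x = None
    if res.x is not None:
        x = [int(round(v)) for v in np.atleast_1d(res.x)]
    return {
        "success": bool(res.success),
        "status": int(res.status),
        "message": str(res.message),
        "objective": None if res.fun is None else float(res.fun),
        "x": x,
    }


def main(argv):
    with open(argv[1]) as fh:
        problems = json.load(fh)
    if isinstance(problems, dict):
        problems = [problems]
    out = [solve_one(p) for p in problems]
    with open(argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv)
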
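"""Solve a binary linear program with scipy's HiGHS MILP interface.

Usage: python solve_milp.py MODEL.json  (writes a JSON object to stdout)

Input: {"n_vars": int, "obj": [...], "rows": [...], "cols": [...],
        "vals": [...], "lb": [...], "ub": [...], "time_limit": seconds}
(0-based sparse constraint triplets; -1 time limit = none). All variables
are binary. Output: {"status": "optimal"|"infeasible"|"time_limit",
"objective": number, "x": [...]}.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, milp


def main():
    with open(sys.argv[1]) as fh:
        m = json.load(fh)
    n = int(m["n_vars"])
    nrow = int(max(m["rows"])) + 1 if m["rows"] else 0
    A = sparse.csr_matrix(
        (m["vals"], (m["rows"], m["cols"])), shape=(nrow, n))
    lb = np.array(m["lb"], dtype=float)
    ub = np.array(m["ub"], dtype=float)
    options = {}
    if m.get("time_limit", -1) and m["time_limit"] > 0:
        options["time_limit"] = float(m["time_limit"])
    res = milp(
        c=np.asarray(m["obj"], dtype=float),
        constraints=LinearConstraint(A, lb, ub) if nrow else (),
        integrality=np.ones(n),
        bounds=(0, 1),
        options=options,
    )
    if res.status == 0:
        out = {"status": "optimal", "objective": res.fun,
               "x": [float(v) for v in res.x]}
    elif res.status == 2:
        out = {"status": "infeasible", "objective": None, "x": None}
    else:
        out = {"status": "time_limit", "objective": None, "x": None}
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
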
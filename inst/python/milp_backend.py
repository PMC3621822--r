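"""MILP backend: solve a binary program exported as JSON with HiGHS.

Usage: python milp_backend.py model.json solution.json

The model file holds the objective vector, sparse constraint triplets
(1-based row/col), senses ("E" equality, "L" <=), right-hand sides and a
wall-clock time limit in seconds.  The solution file reports the scipy/HiGHS
status code (0 optimal, 1 time/iteration limit, 2 infeasible, 3 unbounded,
4 other), the 1-based indices of the variables set to one, and the objective
value.
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def scalar(x):
    return x[0] if isinstance(x, list) else x


def main(model_path, out_path):
    with open(model_path) as fh:
        spec = json.load(fh)
    obj = np.asarray(spec["obj"], dtype=np.float64)
    n = obj.size
    row = np.asarray(spec["row"], dtype=np.int64) - 1
    col = np.asarray(spec["col"], dtype=np.int64) - 1
    val = np.asarray(spec["val"], dtype=np.float64)
    m = int(scalar(spec["ncons"]))
    a_mat = sparse.csr_matrix((val, (row, col)), shape=(m, n))
    rhs = np.asarray(spec["rhs"], dtype=np.float64)
    sense = np.asarray(spec["sense"])
    lb = np.where(sense == "E", rhs, -np.inf)
    res = milp(
        c=obj,
        constraints=LinearConstraint(a_mat, lb, rhs),
        integrality=np.ones(n),
        bounds=Bounds(0, 1),
        options={"time_limit": float(scalar(spec["time_limit"]))},
    )
    out = {"status": int(res.status), "message": str(res.message)}
    if res.x is not None:
        chosen = np.flatnonzero(np.asarray(res.x) > 0.5)
        out["x"] = [int(i) + 1 for i in chosen]
        out["objective"] = float(res.fun)
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
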
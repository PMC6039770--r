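# Independent optimal-transport oracle: solves each balanced transport
# instance as a plain LP with scipy's HiGHS backend. Used from the R test
# suite only; shares no code with the package's solver.
#
# usage: python oracle_transport.py problems.json values.json
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(p):
    n, m = p["n"], p["m"]
    C = np.array(p["C"], dtype=float, ndmin=1).reshape(n, m)
    d1 = np.array(p["d1"], dtype=float, ndmin=1)
    d2 = np.array(p["d2"], dtype=float, ndmin=1)
    rows = []
    for i in range(n):
        r = np.zeros((n, m))
        r[i, :] = 1
        rows.append(r.ravel())
    for j in range(m):
        r = np.zeros((n, m))
        r[:, j] = 1
        rows.append(r.ravel())
    res = linprog(C.ravel(), A_eq=np.array(rows),
                  b_eq=np.concatenate([d1, d2]), method="highs")
    if not res.success:
        raise RuntimeError("oracle LP failed")
    return float(res.fun)


def main():
    problems = json.load(open(sys.argv[1]))
    json.dump([solve(p) for p in problems], open(sys.argv[2], "w"))


if __name__ == "__main__":
    main()
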
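"""Dense linear-program oracle for the earth mover's distance.

Reads a JSON list of problems ({"a": [...], "b": [...], "cost": [[...]]})
and writes the optimal transportation costs as a JSON list. Used only as an
independent cross-check of the package's transportation solver.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(a, b, cost):
    a = np.asarray(a, dtype=float)
    b = np.asarray(b, dtype=float)
    C = np.asarray(cost, dtype=float)
    m, n = C.shape
    # variables f_ij >= 0, row sums = a, col sums = b
    A_eq = []
    b_eq = []
    for i in range(m):
        row = np.zeros(m * n)
        row[i * n:(i + 1) * n] = 1.0
        A_eq.append(row)
        b_eq.append(a[i])
    for j in range(n):
        col = np.zeros(m * n)
        col[j::n] = 1.0
        A_eq.append(col)
        b_eq.append(b[j])
    res = linprog(C.ravel(), A_eq=np.array(A_eq), b_eq=np.array(b_eq),
                  bounds=(0, None), method="highs")
    if not res.success:
        raise RuntimeError(res.message)
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    out = [solve(p["a"], p["b"], p["cost"]) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
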
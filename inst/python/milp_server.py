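"""MILP solving service for the resinopt R package.

Solves mixed-integer linear programs with scipy.optimize.milp (HiGHS).
Two modes:

  milp_server.py --connect PORT   persistent worker: connects to a local
                                  socket opened by the R session and
                                  answers one JSON request per line
  milp_server.py --one-shot IN OUT   solve a single JSON request file

Request:  {"cmd": "solve", "ncol": n, "obj": [...], "maximize": true,
           "lb": [...], "ub": [...], "integer": [0/1 ...],
           "i": [...], "j": [...], "x": [...],   # 1-based triplets
           "rlb": [...], "rub": [...],
           "gap": 0.0, "time_limit": 60.0}
Response: {"status": "optimal"|"infeasible"|"limit"|"unbounded"|"error",
           "objective": float, "x": [...]}
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded"}


def arr(v, dtype=float):
    """1-D array from a JSON value that may be a scalar, list or None.

    jsonlite serializes R's Inf/-Inf as the strings "Inf"/"-Inf", which
    numpy's float cast understands, and unboxes length-1 vectors to
    scalars, which atleast_1d undoes."""
    if v is None:
        return np.zeros(0, dtype=dtype)
    return np.atleast_1d(np.asarray(v)).astype(dtype)


def solve(req):
    n = int(req["ncol"])
    obj = arr(req["obj"])
    sign = -1.0 if req.get("maximize", True) else 1.0
    lb = arr(req["lb"])
    ub = arr(req["ub"])
    integrality = arr(req["integer"], int)
    cons = []
    i = arr(req.get("i"), int)
    if i.size:
        rlb = arr(req["rlb"])
        A = sparse.coo_matrix(
            (arr(req["x"]), (i - 1, arr(req.get("j"), int) - 1)),
            shape=(rlb.size, n),
        ).tocsc()
        cons = [LinearConstraint(A, rlb, arr(req["rub"]))]
    options = {"mip_rel_gap": float(req.get("gap", 0.0))}
    if req.get("time_limit") is not None:
        options["time_limit"] = float(req["time_limit"])
    res = milp(c=sign * obj, constraints=cons,
               integrality=integrality, bounds=Bounds(lb, ub),
               options=options)
    out = {"status": STATUS.get(res.status, "error")}
    if res.x is not None:
        scale = float(req.get("obj_scale", 1.0))
        out["objective"] = float(sign * res.fun) / scale
        out["x"] = [float(v) for v in res.x]
    return out


def handle(line):
    try:
        req = json.loads(line)
        if req.get("cmd") == "quit":
            return None
        if req.get("cmd") == "ping":
            return {"status": "pong"}
        return solve(req)
    except Exception as exc:  # report, never crash the worker
        return {"status": "error", "message": f"{type(exc).__name__}: {exc}"}


def main(argv):
    if argv[0] == "--connect":
        import socket

        s = socket.create_connection(("127.0.0.1", int(argv[1])), timeout=60)
        f = s.makefile("rw", encoding="utf-8", newline="\n")
        f.write(json.dumps({"status": "ready"}) + "\n")
        f.flush()
        for line in f:
            out = handle(line)
            if out is None:
                break
            f.write(json.dumps(out) + "\n")
            f.flush()
    elif argv[0] == "--one-shot":
        with open(argv[1], encoding="utf-8") as fh:
            out = handle(fh.read())
        with open(argv[2], "w", encoding="utf-8") as fh:
            json.dump(out, fh)
    else:
        raise SystemExit("usage: milp_server.py --connect PORT | --one-shot IN OUT")


if __name__ == "__main__":
    main(sys.argv[1:])
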
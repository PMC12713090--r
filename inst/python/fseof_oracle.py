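"""Independent brute-force reimplementation of the enforced-objective scan.

Reads a job description (JSON) with the model in the package's JSON
dialect plus the scan configuration, recomputes the scan with dense
matrices and scipy's HiGHS linprog backend over a fine fraction grid, and
writes scores as JSON. Used only to cross-validate the R implementation on
small toy models.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def build(model):
    mets = [m["id"] for m in model["metabolites"] if not m.get("boundary", False)]
    midx = {m: i for i, m in enumerate(mets)}
    rids = [r["id"] for r in model["reactions"]]
    S = np.zeros((len(mets), len(rids)))
    lb = np.zeros(len(rids))
    ub = np.zeros(len(rids))
    for j, r in enumerate(model["reactions"]):
        for m, coef in r["mets"].items():
            if m in midx:
                S[midx[m], j] = coef
        lb[j] = r.get("lb", -1000.0)
        ub[j] = r.get("ub", 1000.0)
    return S, lb, ub, rids


def solve(S, lb, ub, c, maximize=False):
    obj = -np.asarray(c, float) if maximize else np.asarray(c, float)
    res = linprog(obj, A_eq=S, b_eq=np.zeros(S.shape[0]),
                  bounds=list(zip(lb, ub)), method="highs")
    if res.status != 0:
        return None
    return res.x


def min_total_flux(S, lb, ub):
    """min sum |v| via forward/backward splitting."""
    n = S.shape[1]
    cols, owner, sgn, slb, sub = [], [], [], [], []
    for k in range(n):
        if lb[k] >= 0:
            cols.append(S[:, k]); owner.append(k); sgn.append(1.0)
            slb.append(lb[k]); sub.append(ub[k])
        elif ub[k] <= 0:
            cols.append(-S[:, k]); owner.append(k); sgn.append(-1.0)
            slb.append(-ub[k]); sub.append(-lb[k])
        else:
            cols.append(S[:, k]); owner.append(k); sgn.append(1.0)
            slb.append(0.0); sub.append(ub[k])
            cols.append(-S[:, k]); owner.append(k); sgn.append(-1.0)
            slb.append(0.0); sub.append(-lb[k])
    Sp = np.column_stack(cols)
    x = solve(Sp, np.array(slb), np.array(sub), np.ones(Sp.shape[1]))
    if x is None:
        return None
    v = np.zeros(n)
    for j, k in enumerate(owner):
        v[k] += sgn[j] * x[j]
    return v


def pin(lb, ub, idx, val):
    tol = 1e-9 * max(1.0, abs(val))
    lo, hi = lb.copy(), ub.copy()
    lo[idx] = max(lo[idx], val - tol)
    hi[idx] = min(hi[idx], val + tol)
    return lo, hi


def main(job_path, out_path):
    with open(job_path) as fh:
        job = json.load(fh)
    S, lb, ub, rids = build(job["model"])
    bio = rids.index(job["biomass"])
    tgt = rids.index(job["target"])
    eps = job["activation_epsilon"]
    fractions = [float(f) for f in job["fractions"]]
    fine = job.get("fine_step", 0.01)

    e_bio = np.zeros(len(rids)); e_bio[bio] = 1.0
    e_tgt = np.zeros(len(rids)); e_tgt[tgt] = 1.0
    v = solve(S, lb, ub, e_bio, maximize=True)
    if v is None:
        raise SystemExit("oracle: model infeasible")
    mu_max = float(v[bio])

    if job.get("use_pfba_for_control", True):
        lo, hi = pin(lb, ub, bio, mu_max)
        control = min_total_flux(S, lo, hi)
    else:
        control = v
    if control is None:
        raise SystemExit("oracle: control infeasible")

    grid = sorted(set(np.round(np.arange(min(fractions), max(fractions) + fine / 2,
                                         fine), 10)) | set(fractions))
    envelope = []
    levels = {}
    for f in grid:
        lo, hi = pin(lb, ub, bio, f * mu_max)
        vt = solve(S, lo, hi, e_tgt, maximize=True)
        if vt is None:
            envelope.append([f, None])
            continue
        tmax = float(vt[tgt])
        envelope.append([f, tmax])
        if any(abs(f - fc) < 1e-12 for fc in fractions):
            lo2, hi2 = pin(lo, hi, tgt, tmax)
            dist = min_total_flux(S, lo2, hi2)
            if dist is not None:
                levels[f] = dist

    lev = np.column_stack([levels[f] for f in fractions if f in levels])
    pmean = lev.mean(axis=1)
    scores = []
    for i, rid in enumerate(rids):
        c0, pm = float(control[i]), float(pmean[i])
        score, activated = None, False
        if abs(c0) <= eps and abs(pm) <= eps:
            score = 0.0
        elif abs(c0) <= eps:
            activated = True
        elif abs(pm) <= eps:
            score = 0.0
        elif np.sign(pm) == np.sign(c0):
            if job.get("aggregation", "mean_flux") == "mean_flux":
                score = abs(pm) / abs(c0)
            else:
                score = float(np.mean(lev[i, :] / c0))
        scores.append({"reaction_id": rid, "score": score,
                       "activated": activated, "control_flux": c0,
                       "production_flux_mean": pm})
    with open(out_path, "w") as fh:
        json.dump({"mu_max": mu_max, "scores": scores,
                   "envelope": envelope}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
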
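# Independent projection oracle: each instance is solved as the generic
# convex program  min 0.5*||w - x||^2  s.t.  w in S  with scipy's SLSQP
# (the L1 ball via the smooth split w = u - v).  One batched python call
# keeps the suite fast.  Entirely independent of the closed forms in R/.

oracle_py <- '
import json, sys
import numpy as np
from scipy.optimize import minimize

def solve(inst):
    x = np.asarray(inst["x"], float)
    kind = inst["kind"]
    opts = {"maxiter": 2000, "ftol": 1e-14}
    if kind == "l1":
        g = float(inst["gamma"]); d = len(x)
        def obj(z):
            r = z[:d] - z[d:] - x
            return 0.5 * np.dot(r, r)
        def grad(z):
            r = z[:d] - z[d:] - x
            return np.concatenate([r, -r])
        cons = [{"type": "ineq",
                 "fun": lambda z: g - z.sum(),
                 "jac": lambda z: -np.ones(2 * d)}]
        z0 = np.concatenate([np.clip(x, 0, None), np.clip(-x, 0, None)])
        if z0.sum() > g:
            z0 *= g / z0.sum()
        res = minimize(obj, z0, jac=grad, method="SLSQP",
                       bounds=[(0, None)] * (2 * d), constraints=cons,
                       options=opts)
        return (res.x[:d] - res.x[d:]).tolist()
    def obj(w):
        r = w - x
        return 0.5 * np.dot(r, r)
    def grad(w):
        return w - x
    if kind == "halfspace":
        a = np.asarray(inst["a"], float); b = float(inst["b"])
        cons = [{"type": "ineq", "fun": lambda w: b - a @ w,
                 "jac": lambda w: -a}]
        w0 = x - max(a @ x - b, 0.0) * a / max(a @ a, 1e-300) * 0.5
    elif kind == "ball":
        c = np.asarray(inst["center"], float); r = float(inst["radius"])
        cons = [{"type": "ineq",
                 "fun": lambda w: r ** 2 - np.dot(w - c, w - c),
                 "jac": lambda w: -2.0 * (w - c)}]
        w0 = c + 0.5 * (x - c)
    elif kind == "relaxed":
        anchor = np.asarray(inst["anchor"], float)
        fval = float(inst["fval"])
        gsub = np.asarray(inst["subgrad"], float)
        kap = float(inst["curvature"])
        def mval(w):
            d = anchor - w
            return fval - gsub @ d + 0.5 * kap * np.dot(d, d)
        def mgrad(w):
            return gsub - kap * (anchor - w)
        cons = [{"type": "ineq", "fun": lambda w: -mval(w),
                 "jac": lambda w: -mgrad(w)}]
        w0 = anchor - gsub  # pushed toward the feasible side
    else:
        raise ValueError(kind)
    res = minimize(obj, x, jac=grad, method="SLSQP", constraints=cons,
                   options=opts)
    best = res
    res2 = minimize(obj, w0, jac=grad, method="SLSQP", constraints=cons,
                    options=opts)
    if res2.fun < best.fun or not best.success:
        best = res2
    return best.x.tolist()

with open(sys.argv[1]) as fh:
    instances = json.load(fh)
out = [solve(inst) for inst in instances]
with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
'

# instances: unnamed list of named lists (kind, x, params...)
# returns: list of numeric vectors (the oracle projections)
qp_project_oracle <- function(instances) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  fpy <- tempfile(fileext = ".py")
  on.exit(unlink(c(fin, fout, fpy)))
  writeLines(oracle_py, fpy)
  jsonlite::write_json(instances, fin, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(fpy, fin, fout), stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(fout))
    stop("projection oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(fout, simplifyVector = FALSE) |>
    lapply(function(v) as.numeric(unlist(v)))
}

# central finite-difference gradient
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
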
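# Shared fixtures and independent oracles.

toy <- toy_model()
toy_kin <- toy_kinetics()

toy_aerobic <- set_bounds(toy, "EX_o2_e", lower = -20)
toy_anaerobic <- set_bounds(toy, "EX_o2_e", lower = 0)

# ---- independent LP oracle (scipy HiGHS via python) ------------------------

has_scipy <- local({
  ok <- tryCatch({
    out <- suppressWarnings(system2("python", c("-c", shQuote("import scipy.optimize")),
                                    stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status")) || attr(out, "status") == 0
  }, error = function(e) FALSE)
  isTRUE(ok)
})

# Solves max/min obj'v s.t. S v = 0, bounds, via scipy.optimize.linprog.
# Independent of the package's simplex implementation.
lp_oracle <- function(model, objective, maximize = TRUE,
                      fix = NULL) {
  stopifnot(has_scipy)
  S <- stoich_matrix(model)
  lb <- pmax(model$reactions$lower_bound, -1000)
  ub <- pmin(model$reactions$upper_bound, 1000)
  if (!is.null(fix)) {
    i <- match(names(fix), model$reactions$id)
    lb[i] <- vapply(fix, `[`, numeric(1), 1)
    ub[i] <- vapply(fix, `[`, numeric(1), 2)
  }
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  utils::write.csv(S, file.path(dir, "S.csv"))
  utils::write.csv(data.frame(lb = lb, ub = ub),
                   file.path(dir, "bounds.csv"), row.names = FALSE)
  obj <- as.numeric(model$reactions$id == objective)
  writeLines(as.character(obj), file.path(dir, "obj.txt"))
  script <- sprintf('
import numpy as np, pandas as pd, json, sys
from scipy.optimize import linprog
d = %s
S = pd.read_csv(d + "/S.csv", index_col=0)
b = pd.read_csv(d + "/bounds.csv")
c = np.array([float(x) for x in open(d + "/obj.txt")])
sign = %s
res = linprog(sign * c, A_eq=S.values, b_eq=np.zeros(S.shape[0]),
              bounds=list(zip(b.lb, b.ub)), method="highs")
ok = res.status == 0
out = {"status": int(res.status),
       "objective": float(np.dot(c, res.x)) if ok else None,
       "flux": [float(x) for x in res.x] if ok else None}
print(json.dumps(out))
', deparse(dir), if (maximize) "-1" else "1")
  f <- file.path(dir, "solve.py")
  writeLines(script, f)
  out <- system2("python", f, stdout = TRUE)
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  if (res$status == 0) {
    res$flux <- stats::setNames(as.numeric(res$flux), model$reactions$id)
  }
  res
}

# reaction-row builder for micro models assembled inside tests
toy_rxn <- function(id, stoich, lb = 0, ub = 1000, gpr = "") {
  tibble::tibble(id = id, stoichiometry = list(stoich),
                 lower_bound = lb, upper_bound = ub, gpr = gpr)
}

# independent L1 flux minimisation at fixed growth: scipy linprog on the
# split formulation min sum(vp + vn), S(vp - vn) = 0, bounds
lp_oracle_l1 <- function(model, mu_star) {
  stopifnot(has_scipy)
  S <- stoich_matrix(model)
  lb <- pmax(model$reactions$lower_bound, -1000)
  ub <- pmin(model$reactions$upper_bound, 1000)
  bio <- match(model$objective, model$reactions$id)
  lb[bio] <- mu_star * (1 - 1e-6)
  ub[bio] <- max(mu_star, lb[bio])
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  utils::write.csv(S, file.path(dir, "S.csv"))
  utils::write.csv(data.frame(lb = lb, ub = ub),
                   file.path(dir, "bounds.csv"), row.names = FALSE)
  script <- sprintf('
import numpy as np, pandas as pd
from scipy.optimize import linprog
d = %s
S = pd.read_csv(d + "/S.csv", index_col=0).values
b = pd.read_csv(d + "/bounds.csv")
n = S.shape[1]
A = np.hstack([S, -S])
c = np.ones(2 * n)
bounds = [(0, max(u, 0)) for u in b.ub] + [(0, max(-l, 0)) for l in b.lb]
# direction-forcing rows for lb > 0 / ub < 0
Aub, bub = [], []
for i in range(n):
    if b.lb[i] > 0:
        row = np.zeros(2 * n); row[i] = -1; row[n + i] = 1
        Aub.append(row); bub.append(-b.lb[i])
    if b.ub[i] < 0:
        row = np.zeros(2 * n); row[i] = 1; row[n + i] = -1
        Aub.append(row); bub.append(b.ub[i])
res = linprog(c, A_eq=A, b_eq=np.zeros(S.shape[0]),
              A_ub=np.array(Aub) if Aub else None,
              b_ub=np.array(bub) if bub else None,
              bounds=bounds, method="highs")
print(res.fun if res.status == 0 else "NA")
', deparse(dir))
  f <- file.path(dir, "solve.py")
  writeLines(script, f)
  as.numeric(system2("python", f, stdout = TRUE))
}

# ---- ODE integration oracle (deSolve) --------------------------------------

# integrates the mRNA balance dm/dt = s_b + R s_a - (mu + gamma) m over
# dt_min minutes with an adaptive-step integrator
integrate_mrna <- function(m0, R, s_b, s_a, gamma, mu_min, dt_min,
                           T_d = NULL) {
  rhs <- function(t, y, parms) {
    act <- if (is.null(T_d)) R else as.numeric(t >= T_d)
    list(s_b + act * s_a - (mu_min + gamma) * y)
  }
  out <- deSolve::ode(y = m0, times = c(0, dt_min), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-11)
  unname(out[nrow(out), 2])
}

integrate_protein <- function(p0, m, s_P, mu, dt_h) {
  rhs <- function(t, y, parms) list(s_P * m - mu * y)
  out <- deSolve::ode(y = p0, times = c(0, dt_h), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-11)
  unname(out[nrow(out), 2])
}
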
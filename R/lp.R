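# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Written for the moderate problem sizes of this package (tens to a few
# hundred variables after flux splitting); no installed R package provides a
# reliable general LP solver. The tableau is kept in canonical form B^-1 A,
# reduced costs are recomputed from it each iteration, and Bland's smallest-
# index rule guarantees termination on degenerate flux polytopes.

# min cost'x  s.t.  A x = b, x >= 0.
# Returns list(x, value, status in {"optimal","infeasible","unbounded","maxiter"}).
simplex_core <- function(cost, A, b, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
  }
  run_phase <- function(Tab, basis, cost_vec) {
    nc <- length(cost_vec)
    rhs_col <- ncol(Tab)
    for (it in seq_len(max_iter)) {
      cB <- cost_vec[basis]
      z <- as.vector(cB %*% Tab[, seq_len(nc), drop = FALSE])
      red <- cost_vec - z
      enter <- which(red < -tol)
      if (length(enter) == 0L) {
        return(list(Tab = Tab, basis = basis, status = "optimal"))
      }
      j <- enter[1L]                              # Bland: smallest index
      col <- Tab[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(Tab = Tab, basis = basis, status = "unbounded"))
      }
      ratios <- Tab[pos, rhs_col] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      i <- cand[which.min(basis[cand])]           # Bland tie-break
      piv <- Tab[i, ] / Tab[i, j]
      Tab <- Tab - outer(Tab[, j], piv)
      Tab[i, ] <- piv
      Tab[, j] <- 0; Tab[i, j] <- 1
      Tab[, rhs_col] <- pmax(Tab[, rhs_col], 0)   # clip round-off negatives
      basis[i] <- j
    }
    list(Tab = Tab, basis = basis, status = "maxiter")
  }
  # phase 1: artificial identity basis
  Tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  ph1 <- run_phase(Tab, basis, c(rep(0, n), rep(1, m)))
  if (ph1$status != "optimal") return(list(x = NULL, value = NA_real_,
                                           status = ph1$status))
  Tab <- ph1$Tab; basis <- ph1$basis
  aux <- sum(Tab[basis > n, ncol(Tab)])
  if (aux > 1e-7) return(list(x = NULL, value = NA_real_,
                              status = "infeasible"))
  # drive leftover zero-valued artificials out of the basis; a row without a
  # usable original column is redundant and is dropped
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    cols <- which(abs(Tab[i, seq_len(n)]) > tol)
    if (length(cols) == 0L) {
      drop_rows <- c(drop_rows, i)
    } else {
      j <- cols[1L]
      piv <- Tab[i, ] / Tab[i, j]
      Tab <- Tab - outer(Tab[, j], piv)
      Tab[i, ] <- piv
      Tab[, j] <- 0; Tab[i, j] <- 1
      basis[i] <- j
    }
  }
  if (length(drop_rows) > 0L) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  Tab <- Tab[, c(seq_len(n), n + m + 1L), drop = FALSE]
  ph2 <- run_phase(Tab, basis, cost)
  if (ph2$status != "optimal") return(list(x = NULL, value = NA_real_,
                                           status = ph2$status))
  x <- numeric(n)
  x[ph2$basis] <- ph2$Tab[, ncol(ph2$Tab)]
  list(x = x, value = sum(cost * x), status = "optimal")
}

# General bounded LP over fluxes: optimise obj'v (or minimise sum|v| when
# l1_objective) subject to S v = 0 and lb <= v <= ub. Fluxes are split into
# non-negative forward/reverse parts; finite caps become slack rows; fixed
# directions (lb > 0 or ub < 0) add surplus rows.
solve_lp <- function(S, lb, ub, obj, maximize = TRUE, l1_objective = FALSE,
                     tol = 1e-9) {
  n <- ncol(S)
  lb <- pmax(lb, -LP_BOUND_CAP)
  ub <- pmin(ub, LP_BOUND_CAP)
  if (any(lb > ub)) {
    return(list(flux = NULL, objective = NA_real_, status = "infeasible"))
  }
  cap_p <- pmax(ub, 0)
  cap_n <- pmax(-lb, 0)
  # active split variables (zero-capacity parts are fixed at 0 and dropped)
  act_p <- which(cap_p > 0)
  act_n <- which(cap_n > 0)
  np <- length(act_p); nn <- length(act_n)
  nv <- np + nn
  cost <- if (l1_objective) rep(1, nv) else {
    sgn <- if (maximize) -1 else 1
    sgn * c(obj[act_p], -obj[act_n])
  }
  A_eq <- cbind(S[, act_p, drop = FALSE], -S[, act_n, drop = FALSE])
  b_eq <- rep(0, nrow(S))
  # cap rows: x_k + s_k = cap_k
  ncap <- nv
  A_cap <- cbind(diag(nv), diag(ncap))
  b_cap <- c(cap_p[act_p], cap_n[act_n])
  # direction-forcing rows: lb > 0 -> vp - vn - t = lb ; ub < 0 -> vn - vp - t = -ub
  extra_rows <- list(); extra_b <- numeric(0)
  add_dir <- function(i, sign) {
    row <- numeric(nv)
    ip <- match(i, act_p); iq <- match(i, act_n)
    if (!is.na(ip)) row[ip] <- sign
    if (!is.na(iq)) row[np + iq] <- -sign
    row
  }
  for (i in which(lb > 0)) {
    extra_rows[[length(extra_rows) + 1L]] <- add_dir(i, 1)
    extra_b <- c(extra_b, lb[i])
  }
  for (i in which(ub < 0)) {
    extra_rows[[length(extra_rows) + 1L]] <- add_dir(i, -1)
    extra_b <- c(extra_b, -ub[i])
  }
  n_extra <- length(extra_rows)
  n_slack <- ncap + n_extra
  A <- rbind(
    cbind(A_eq, matrix(0, nrow(A_eq), n_slack)),
    cbind(A_cap, matrix(0, ncap, n_extra)),
    if (n_extra > 0L) {
      cbind(do.call(rbind, extra_rows), matrix(0, n_extra, ncap),
            -diag(n_extra))
    })
  b <- c(b_eq, b_cap, extra_b)
  res <- simplex_core(c(cost, rep(0, n_slack)), A, b, tol = tol)
  if (res$status != "optimal") {
    return(list(flux = NULL, objective = NA_real_, status = res$status))
  }
  vp <- numeric(n); vn <- numeric(n)
  vp[act_p] <- res$x[seq_len(np)]
  vn[act_n] <- res$x[np + seq_len(nn)]
  v <- vp - vn
  names(v) <- colnames(S)
  list(flux = v,
       objective = if (l1_objective) sum(vp + vn) else sum(obj * v),
       total_split_flux = sum(vp + vn),
       status = "optimal")
}
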
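# Linear-programming core: growth FBA, parsimonious FBA, flux variability.

LP_BOUND_CAP <- 1000      # COBRA convention for "unbounded" reactions
GROWTH_FIX_TOL <- 1e-6    # relative slack when fixing growth at mu*

new_ddd_flux <- function(flux, growth_rate, objective_value, status,
                         norm = NA_character_) {
  structure(list(
    fluxes = tibble::tibble(reaction = names(flux), flux = unname(flux)),
    growth_rate = growth_rate, objective_value = objective_value,
    status = status, norm = norm), class = "ddd_flux")
}

#' @export
print.ddd_flux <- function(x, ...) {
  cat("<ddd_flux> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  growth rate mu = ", format(x$growth_rate, digits = 6), " 1/h\n",
        sep = "")
    cat("  objective      = ", format(x$objective_value, digits = 6), "\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy a flux solution
#'
#' @param x A `ddd_flux` from [fba()] or [pfba()].
#' @param ... Unused.
#' @return Tibble with columns `reaction`, `flux` (mmol h^-1 gDCW^-1).
#' @export
tidy.ddd_flux <- function(x, ...) x$fluxes

#' One-row summary of a flux solution
#'
#' @param x A `ddd_flux`.
#' @param ... Unused.
#' @return Tibble with `growth_rate`, `objective_value`, `total_flux`, `status`.
#' @export
glance.ddd_flux <- function(x, ...) {
  tibble::tibble(growth_rate = x$growth_rate,
                 objective_value = x$objective_value,
                 total_flux = sum(abs(x$fluxes$flux)),
                 status = x$status)
}

#' Growth-maximising flux balance analysis
#'
#' Maximises the biomass reaction subject to the steady-state constraint
#' S v = 0 on internal metabolites and the model's flux bounds. Bounds beyond
#' +-1000 mmol h^-1 gDCW^-1 are capped at that conventional value.
#'
#' @param model A `ddd_model`.
#' @return A `ddd_flux`; on infeasibility `status = "infeasible"` and no flux
#'   vector.
#' @export
fba <- function(model) {
  validate_model(model)
  S <- stoich_matrix(model)
  obj <- as.numeric(model$reactions$id == model$objective)
  sol <- solve_lp(S, model$reactions$lower_bound, model$reactions$upper_bound,
                  obj, maximize = TRUE)
  if (sol$status != "optimal") {
    return(new_ddd_flux(stats::setNames(numeric(0), character(0)),
                        NA_real_, NA_real_, sol$status))
  }
  mu <- sol$flux[[model$objective]]
  new_ddd_flux(sol$flux, mu, sol$objective, "optimal")
}

#' Parsimonious flux balance analysis
#'
#' Fixes growth at `mu_star` (within a relative slack of 1e-6 to avoid
#' numerical infeasibility) and minimises total flux: the L1 norm
#' `sum(|v|)` (default; linearised by splitting each flux into an
#' irreversible pair) or the squared L2 norm `sum(v^2)` (solved as a
#' quadratic program). The minimal-flux solution proxies minimal enzyme
#' usage within the growth optimum.
#'
#' @param model A `ddd_model`.
#' @param mu_star Growth rate to fix (h^-1); defaults to the [fba()] optimum.
#' @param norm `"l1"` or `"l2"`.
#' @return A `ddd_flux`; `objective_value` is the minimised flux norm and
#'   `growth_rate` the realised growth.
#' @export
pfba <- function(model, mu_star = NULL, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  validate_model(model)
  if (is.null(mu_star)) {
    g <- fba(model)
    if (g$status != "optimal") {
      stop("growth FBA is ", g$status, "; cannot run pFBA", call. = FALSE)
    }
    mu_star <- g$growth_rate
  }
  S <- stoich_matrix(model)
  lb <- pmax(model$reactions$lower_bound, -LP_BOUND_CAP)
  ub <- pmin(model$reactions$upper_bound, LP_BOUND_CAP)
  bio <- match(model$objective, model$reactions$id)
  lb[bio] <- mu_star * (1 - GROWTH_FIX_TOL)
  ub[bio] <- max(mu_star, lb[bio])
  if (norm == "l1") {
    sol <- solve_lp(S, lb, ub, obj = rep(0, ncol(S)), l1_objective = TRUE)
    if (sol$status != "optimal") {
      stop("L1 flux minimisation at mu* = ", format(mu_star),
           " is ", sol$status, call. = FALSE)
    }
    new_ddd_flux(sol$flux, sol$flux[[model$objective]], sol$objective,
                 "optimal", norm = "l1")
  } else {
    # L2: quadratic program over the constant-growth null space, anchored at
    # the (feasible) L1 solution; degenerate zero-variability coordinates are
    # eliminated, which keeps the active-set solver well conditioned
    anchor <- pfba(model, mu_star = mu_star, norm = "l1")
    v0 <- stats::setNames(anchor$fluxes$flux, anchor$fluxes$reaction)
    n <- ncol(S)
    bio_row <- as.numeric(seq_len(n) == bio)
    N <- MASS::Null(t(rbind(S, bio_row)))
    if (is.null(dim(N)) || ncol(N) == 0L) {
      return(new_ddd_flux(v0, v0[[model$objective]], sum(v0^2), "optimal",
                          norm = "l2"))
    }
    moving <- which(apply(abs(N), 1, max) > 1e-10)
    # coordinates with zero flux variability are only nominally free; pin
    # them at the anchor value so their (degenerate) bound rows drop out
    iv <- fva(model, mu_star = mu_star,
              reactions = model$reactions$id[moving])
    pinned <- moving[iv$max - iv$min < 1e-8]
    if (length(pinned) > 0L) {
      pin_rows <- diag(n)[pinned, , drop = FALSE]
      N <- MASS::Null(t(rbind(S, bio_row, pin_rows)))
      if (is.null(dim(N)) || ncol(N) == 0L) {
        return(new_ddd_flux(v0, v0[[model$objective]], sum(v0^2), "optimal",
                            norm = "l2"))
      }
      moving <- which(apply(abs(N), 1, max) > 1e-10)
    }
    Dmat <- 2 * crossprod(N)
    diag(Dmat) <- diag(Dmat) + 1e-12
    dvec <- -2 * as.vector(crossprod(N, v0))
    Amat <- t(rbind(N[moving, , drop = FALSE], -N[moving, , drop = FALSE]))
    bvec <- c(lb[moving] - v0[moving], -(ub[moving] - v0[moving]))
    q <- tryCatch(
      quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 0),
      error = function(e) stop("L2 flux minimisation failed at mu* = ",
                               format(mu_star), ": ", conditionMessage(e),
                               call. = FALSE))
    v <- v0 + as.vector(N %*% q$solution)
    names(v) <- colnames(S)
    v[abs(v) < 1e-12] <- 0
    new_ddd_flux(v, v[[model$objective]], sum(v^2), "optimal", norm = "l2")
  }
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its flux over the
#' growth-optimal solution space (growth fixed at `mu_star` within a 1e-6
#' relative slack). No parsimony constraint is applied: variability is
#' assessed directly within the growth optimum.
#'
#' @param model A `ddd_model`.
#' @param mu_star Growth rate to fix (h^-1); defaults to the [fba()] optimum.
#' @param reactions Reaction ids to analyse (default: all).
#' @return Tibble with columns `reaction`, `min`, `max` (mmol h^-1 gDCW^-1).
#' @export
fva <- function(model, mu_star = NULL, reactions = NULL) {
  validate_model(model)
  if (is.null(mu_star)) {
    g <- fba(model)
    if (g$status != "optimal") {
      stop("growth FBA is ", g$status, "; cannot run FVA", call. = FALSE)
    }
    mu_star <- g$growth_rate
  }
  if (is.null(reactions)) reactions <- model$reactions$id
  missing <- setdiff(reactions, model$reactions$id)
  if (length(missing) > 0L) {
    stop("unknown reaction(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  S <- stoich_matrix(model)
  lb <- pmax(model$reactions$lower_bound, -LP_BOUND_CAP)
  ub <- pmin(model$reactions$upper_bound, LP_BOUND_CAP)
  bio <- match(model$objective, model$reactions$id)
  lb[bio] <- mu_star * (1 - GROWTH_FIX_TOL)
  ub[bio] <- max(mu_star, lb[bio])
  one <- function(rid, maximize) {
    obj <- as.numeric(model$reactions$id == rid)
    sol <- solve_lp(S, lb, ub, obj, maximize = maximize)
    if (sol$status != "optimal") {
      stop("FVA ", if (maximize) "max" else "min", " for '", rid, "' is ",
           sol$status, call. = FALSE)
    }
    sol$flux[[rid]]
  }
  out <- tibble::tibble(
    reaction = reactions,
    min = vapply(reactions, one, numeric(1), maximize = FALSE,
                 USE.NAMES = FALSE),
    max = vapply(reactions, one, numeric(1), maximize = TRUE,
                 USE.NAMES = FALSE))
  # clip the occasional 1e-12 inversion from solver round-off
  swap <- out$min > out$max
  if (any(swap)) {
    m <- (out$min[swap] + out$max[swap]) / 2
    out$min[swap] <- m; out$max[swap] <- m
  }
  out
}
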
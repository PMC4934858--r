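# Demand-directed dynamic FBA: per time step (1) maximise growth, (2) minimise
# total flux, (3) integrate the culture, (4) recompute uptake and
# enzyme-capacity bounds from the advanced expression state.

#' Simulation scenario configuration
#'
#' Collects the tunable parameters of a demand-directed dFBA run. Defaults
#' describe an anaerobic batch culture that is aerated at `t_aer_min`.
#'
#' @param theta Regulatory threshold in (0, 1] (default 0.6).
#' @param tau Translation constant (bp mmol h^-1 RPKM^-1 gDCW^-1, default 0.6).
#' @param spacing_bp Interribosomal spacing (bp, default 72).
#' @param dt_min Time step (min, default 0.5).
#' @param horizon_min Simulation horizon (min, default 60).
#' @param t_aer_min Onset of aeration (min from simulation start, default 0).
#' @param mu_anaerobic Anaerobic growth rate used for the basal steady-state
#'   initial condition (1/h, default 0.26).
#' @param glc_exchange,o2_exchange Reaction ids of the glucose and oxygen
#'   exchanges.
#' @param glc_max,o2_max Maximal specific uptake rates (mmol h^-1 gDCW^-1).
#' @param uptake Glucose uptake kinetics: `"fixed"` (vmax while substrate
#'   remains) or `"michaelis-menten"`.
#' @param km Michaelis constant for `"michaelis-menten"` uptake (mmol/L).
#' @param biomass_0 Inoculum biomass (gDCW/L, default 0.1).
#' @param concentrations Named vector of initial external metabolite
#'   concentrations (mmol/L); metabolites of other exchanges start at 0.
#' @param parsimony pFBA norm, `"l1"` or `"l2"`.
#' @param fva_reactions Reaction ids to track with flux variability analysis
#'   each step (`NULL` to switch FVA off).
#' @param unit_factor Unit conversion applied inside [flux_bound()].
#' @param seed Random seed recorded with the scenario.
#' @return A list of class `ddd_config`.
#' @export
ddd_config <- function(theta = 0.6, tau = 0.6, spacing_bp = 72, dt_min = 0.5,
                       horizon_min = 60, t_aer_min = 0, mu_anaerobic = 0.26,
                       glc_exchange = "EX_glc_e", o2_exchange = "EX_o2_e",
                       glc_max = 10, o2_max = 20,
                       uptake = c("fixed", "michaelis-menten"), km = 0.5,
                       biomass_0 = 0.1, concentrations = c(glc_e = 25),
                       parsimony = c("l1", "l2"), fva_reactions = NULL,
                       unit_factor = 1, seed = 1L) {
  uptake <- match.arg(uptake)
  parsimony <- match.arg(parsimony)
  if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]", call. = FALSE)
  if (dt_min <= 0 || horizon_min <= 0) {
    stop("dt_min and horizon_min must be positive", call. = FALSE)
  }
  if (glc_max < 0 || o2_max < 0) stop("uptake maxima must be >= 0", call. = FALSE)
  if (km < 0) stop("km must be non-negative", call. = FALSE)
  structure(list(
    theta = theta, tau = tau, spacing_bp = spacing_bp, dt_min = dt_min,
    horizon_min = horizon_min, t_aer_min = t_aer_min,
    mu_anaerobic = mu_anaerobic, glc_exchange = glc_exchange,
    o2_exchange = o2_exchange, glc_max = glc_max, o2_max = o2_max,
    uptake = uptake, km = km, biomass_0 = biomass_0,
    concentrations = concentrations, parsimony = parsimony,
    fva_reactions = fva_reactions, unit_factor = unit_factor,
    seed = as.integer(seed)), class = "ddd_config")
}

#' Read a scenario configuration from YAML
#'
#' Keys mirror the arguments of [ddd_config()]; missing keys keep their
#' defaults, unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return A `ddd_config`.
#' @export
read_ddd_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(ddd_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$concentrations)) {
    vals$concentrations <- unlist(vals$concentrations)
  }
  do.call(ddd_config, vals)
}

#' Substrate-dependent uptake bound
#'
#' Stage-4 recalculation of an uptake bound from the external substrate
#' concentration: `"fixed"` kinetics allow `vmax` while any substrate remains
#' and 0 otherwise; `"michaelis-menten"` returns `vmax * C / (km + C)`.
#'
#' @param conc External concentration (mmol/L, >= 0).
#' @param vmax Maximal uptake rate (mmol h^-1 gDCW^-1, >= 0).
#' @param kinetics `"fixed"` or `"michaelis-menten"`.
#' @param km Michaelis constant (mmol/L).
#' @return Uptake bound magnitude (mmol h^-1 gDCW^-1).
#' @export
uptake_bound <- function(conc, vmax, kinetics = c("fixed", "michaelis-menten"),
                         km = 0.5) {
  kinetics <- match.arg(kinetics)
  if (any(conc < 0) || any(vmax < 0)) {
    stop("conc and vmax must be non-negative", call. = FALSE)
  }
  if (km < 0) stop("km must be non-negative", call. = FALSE)
  switch(kinetics,
         "fixed" = ifelse(conc > 0, vmax, 0),
         "michaelis-menten" = vmax * conc / (km + conc))
}

#' Culture state
#'
#' @param biomass Biomass concentration (gDCW/L, >= 0).
#' @param conc Named vector of external metabolite concentrations (mmol/L).
#' @param time_min Culture time (min).
#' @return A list of class `ddd_culture`.
#' @export
culture_state <- function(biomass, conc, time_min = 0) {
  if (biomass < 0 || any(conc < 0)) {
    stop("biomass and concentrations must be non-negative", call. = FALSE)
  }
  structure(list(biomass = biomass, conc = conc, time_min = time_min),
            class = "ddd_culture")
}

#' Integrate the culture over one step
#'
#' Exponential-growth closure of the batch balance: biomass
#' `X' = X exp(mu dt)` and, per exchanged metabolite with specific flux `v`
#' (positive = secretion), `C' = max(0, C + v X (exp(mu dt) - 1) / mu)`;
#' at `mu = 0` the linear limit `C' = max(0, C + v X dt)` applies.
#'
#' @param culture A `ddd_culture`.
#' @param exchange_flux Named vector of specific exchange fluxes, names being
#'   external metabolite ids present in `culture$conc`.
#' @param mu Growth rate over the step (1/h).
#' @param dt_h Step length (h, > 0).
#' @return Updated `ddd_culture`.
#' @export
update_culture <- function(culture, exchange_flux, mu, dt_h) {
  stopifnot(inherits(culture, "ddd_culture"), dt_h > 0)
  growth <- if (mu > 0) (exp(mu * dt_h) - 1) / mu else dt_h
  ids <- intersect(names(exchange_flux), names(culture$conc))
  conc <- culture$conc
  conc[ids] <- pmax(0, conc[ids] + exchange_flux[ids] * culture$biomass * growth)
  culture_state(biomass = culture$biomass * exp(mu * dt_h), conc = conc,
                time_min = culture$time_min + dt_h * 60)
}

# map exchange reaction id -> its single metabolite id
exchange_metabolites <- function(model) {
  ex <- exchange_reactions(model)
  stats::setNames(
    vapply(ex, function(r) {
      names(model$reactions$stoichiometry[[match(r, model$reactions$id)]])[1]
    }, character(1)), ex)
}

#' Initialise a demand-directed dFBA run
#'
#' Sets every balanced enzyme to its anaerobic basal steady state (regulatory
#' signal 0, growth `mu_anaerobic`), derives the initial capacity bounds from
#' the steady-state protein levels, and checks that the model grows
#' anaerobically (oxygen exchange closed) at all.
#'
#' @param model A `ddd_model`.
#' @param kinetics A `ddd_kinetics` tibble for the balanced reactions (may
#'   have zero rows, reducing the method to plain dynamic FBA).
#' @param config A `ddd_config`.
#' @return List with elements `expression` (tibble: reaction, mrna, protein,
#'   bound, signal), `culture` (a `ddd_culture`) and `base` (the model with
#'   scenario-independent bounds).
#' @export
ddd_initialize <- function(model, kinetics, config) {
  validate_model(model)
  missing <- setdiff(kinetics$reaction, model$reactions$id)
  if (length(missing) > 0L) {
    stop("kinetics reference unknown reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  anaerobic <- set_bounds(model, config$o2_exchange, lower = 0)
  anaerobic <- set_bounds(anaerobic, config$glc_exchange,
                          lower = -config$glc_max)
  g <- fba(anaerobic)
  if (g$status != "optimal" || g$growth_rate <= 1e-9) {
    stop("model is infeasible (or non-growing) anaerobically; cannot ",
         "initialise at the anaerobic steady state", call. = FALSE)
  }
  expr <- if (nrow(kinetics) > 0L) {
    ss <- steady_state_expression(kinetics, config$mu_anaerobic, R = 0)
    ss$bound <- flux_bound(kinetics$kcat, ss$protein, config$unit_factor)
    ss$signal <- 0L
    ss
  } else {
    tibble::tibble(reaction = character(), mrna = numeric(),
                   protein = numeric(), bound = numeric(), signal = integer())
  }
  ex_met <- exchange_metabolites(model)
  conc <- stats::setNames(rep(0, length(ex_met)), unname(ex_met))
  known <- intersect(names(config$concentrations), names(conc))
  conc[known] <- config$concentrations[known]
  list(expression = expr,
       culture = culture_state(config$biomass_0, conc, time_min = 0),
       base = model)
}

apply_dynamic_bounds <- function(model, expression, culture, config) {
  aerated <- culture$time_min >= config$t_aer_min
  ex_met <- exchange_metabolites(model)
  glc_met <- ex_met[[config$glc_exchange]]
  glc_b <- uptake_bound(culture$conc[[glc_met]], config$glc_max,
                        config$uptake, config$km)
  model <- set_bounds(model, config$glc_exchange, lower = -glc_b)
  model <- set_bounds(model, config$o2_exchange,
                      lower = if (aerated) -config$o2_max else 0)
  if (nrow(expression) > 0L) {
    idx <- match(expression$reaction, model$reactions$id)
    base_lb <- model$reactions$lower_bound[idx]
    base_ub <- model$reactions$upper_bound[idx]
    model$reactions$upper_bound[idx] <- pmin(base_ub, expression$bound)
    model$reactions$lower_bound[idx] <- pmax(base_lb, -expression$bound)
  }
  model
}

#' One demand-directed dFBA step
#'
#' Applies the current uptake and enzyme-capacity bounds, maximises growth,
#' minimises total flux at the growth optimum, evaluates the demand signal on
#' the parsimonious fluxes, advances the mRNA (regulatory signal held
#' constant) and protein (mRNA held constant) balances, integrates the
#' culture, and recomputes the capacity bounds from the new protein levels.
#' If the constrained model cannot grow (e.g. substrate exhausted), the step
#' returns a dormant state (`mu = 0`, zero fluxes) rather than failing.
#'
#' @param model The base `ddd_model` (scenario-independent bounds).
#' @param expression Expression tibble as produced by [ddd_initialize()].
#' @param culture A `ddd_culture`.
#' @param kinetics A `ddd_kinetics` tibble (rows matching `expression`).
#' @param config A `ddd_config`.
#' @return List with `solution` (`ddd_flux`), `expression`, `culture`,
#'   `fva` (tibble or `NULL`) and `dormant` (logical).
#' @export
ddd_step <- function(model, expression, culture, kinetics, config) {
  constrained <- apply_dynamic_bounds(model, expression, culture, config)
  g <- fba(constrained)
  dormant <- g$status != "optimal" || g$growth_rate <= 1e-9
  fva_tab <- NULL
  if (dormant) {
    mu <- 0
    flux <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
    sol <- new_ddd_flux(flux, 0, 0, "dormant")
  } else {
    mu <- g$growth_rate
    sol <- pfba(constrained, mu_star = mu, norm = config$parsimony)
    flux <- stats::setNames(sol$fluxes$flux, sol$fluxes$reaction)
    if (!is.null(config$fva_reactions)) {
      fva_tab <- fva(constrained, mu_star = mu,
                     reactions = config$fva_reactions)
    }
  }
  dt_h <- config$dt_min / 60
  if (nrow(expression) > 0L) {
    j <- abs(flux[expression$reaction])
    expression$signal <- regulatory_signal(j, expression$bound, config$theta)
    m_old <- expression$mrna
    expression$mrna <- mrna_step(m_old, expression$signal, kinetics$s_b,
                                 kinetics$s_a, kinetics$gamma, mu / 60,
                                 config$dt_min)
    expression$protein <- protein_step(expression$protein, m_old,
                                       kinetics$s_P, mu, dt_h)
    expression$bound <- flux_bound(kinetics$kcat, expression$protein,
                                   config$unit_factor)
  }
  ex_met <- exchange_metabolites(model)
  ex_flux <- stats::setNames(flux[names(ex_met)], unname(ex_met))
  culture <- update_culture(culture, ex_flux, mu, dt_h)
  list(solution = sol, expression = expression, culture = culture,
       fva = fva_tab, dormant = dormant)
}

#' Simulate a demand-directed dFBA scenario
#'
#' Runs [ddd_initialize()] and iterates [ddd_step()] over the configured
#' horizon. At each recorded time the stored fluxes, bounds and expression
#' state are those under which that step's linear programs were solved.
#'
#' @inheritParams ddd_initialize
#' @return A `ddd_trajectory`: list of tibbles `fluxes` (time_min, reaction,
#'   flux), `expression` (time_min, reaction, mrna, protein, bound, flux,
#'   signal), `culture` (time_min, biomass, growth_rate, status and one
#'   column per tracked metabolite), `fva` (time_min, reaction, min, max; or
#'   `NULL`), plus the `config`.
#' @export
ddd_simulate <- function(model, kinetics, config = ddd_config()) {
  state <- ddd_initialize(model, kinetics, config)
  expression <- state$expression
  culture <- state$culture
  n_steps <- ceiling(config$horizon_min / config$dt_min)
  times <- (seq_len(n_steps) - 1L) * config$dt_min
  flux_rec <- vector("list", n_steps)
  expr_rec <- vector("list", n_steps)
  cult_rec <- vector("list", n_steps)
  fva_rec <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    bounds_in <- expression$bound
    signal_in <- expression$signal
    mrna_in <- expression$mrna
    protein_in <- expression$protein
    step <- ddd_step(model, expression, culture, kinetics, config)
    flux <- stats::setNames(step$solution$fluxes$flux,
                            step$solution$fluxes$reaction)
    flux_rec[[k]] <- tibble::tibble(time_min = times[k],
                                    reaction = names(flux),
                                    flux = unname(flux))
    if (nrow(expression) > 0L) {
      expr_rec[[k]] <- tibble::tibble(
        time_min = times[k], reaction = expression$reaction,
        mrna = mrna_in, protein = protein_in, bound = bounds_in,
        flux = unname(flux[expression$reaction]),
        signal = step$expression$signal)
    }
    cult_rec[[k]] <- dplyr::bind_cols(
      tibble::tibble(time_min = times[k], biomass = culture$biomass,
                     growth_rate = step$solution$growth_rate,
                     status = step$solution$status),
      tibble::as_tibble_row(as.list(culture$conc)))
    if (!is.null(step$fva)) {
      fva_rec[[k]] <- dplyr::mutate(step$fva, time_min = times[k],
                                    .before = 1)
    }
    expression <- step$expression
    culture <- step$culture
  }
  structure(list(
    fluxes = dplyr::bind_rows(flux_rec),
    expression = dplyr::bind_rows(expr_rec),
    culture = dplyr::bind_rows(cult_rec),
    fva = if (is.null(config$fva_reactions)) NULL else dplyr::bind_rows(fva_rec),
    config = config), class = "ddd_trajectory")
}

#' @export
print.ddd_trajectory <- function(x, ...) {
  cat("<ddd_trajectory> ", length(unique(x$fluxes$time_min)), " steps of ",
      x$config$dt_min, " min; ", length(unique(x$expression$reaction)),
      " balanced reaction(s)\n", sep = "")
  invisible(x)
}

#' Expression-episode and bound-binding durations
#'
#' Summarises a trajectory per balanced reaction: total time with the
#' regulatory signal on (activated transcription episode) and total time the
#' parsimonious flux sits on the enzyme-capacity bound.
#'
#' @param trajectory A `ddd_trajectory`.
#' @param binding_tol Relative tolerance for calling a flux bound-binding.
#' @return Tibble with `reaction`, `expression_min`, `binding_min`.
#' @export
episode_summary <- function(trajectory, binding_tol = 1e-6) {
  dt <- trajectory$config$dt_min
  trajectory$expression |>
    dplyr::group_by(reaction) |>
    dplyr::summarise(
      expression_min = sum(signal == 1L) * dt,
      binding_min = sum(abs(flux) >= bound * (1 - binding_tol) - 1e-9 &
                          bound < LP_BOUND_CAP) * dt,
      .groups = "drop")
}

#' Parameter sweep over scenario configurations
#'
#' Re-runs [ddd_simulate()] over a grid of translation constants, regulatory
#' thresholds and/or turnover-number overrides, all other settings identical,
#' and attaches the per-reaction episode summary for each run.
#'
#' @param model A `ddd_model`.
#' @param kinetics A `ddd_kinetics` tibble.
#' @param config Base `ddd_config`.
#' @param grid Tibble of scenario overrides; recognised columns are `tau`,
#'   `theta` and `kcat_<reaction id>` (replacement turnover numbers).
#' @return The grid with list columns `trajectory` and `summary`.
#' @export
parameter_sweep <- function(model, kinetics, config, grid) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) stop("sweep grid is empty", call. = FALSE)
  kcat_cols <- grep("^kcat_", names(grid), value = TRUE)
  unknown <- setdiff(names(grid), c("tau", "theta", kcat_cols))
  if (length(unknown) > 0L) {
    stop("unknown sweep column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  run_one <- function(i) {
    cfg <- config
    kin <- kinetics
    if ("theta" %in% names(grid)) cfg$theta <- grid$theta[i]
    if ("tau" %in% names(grid)) {
      cfg$tau <- grid$tau[i]
      kin$s_P <- cfg$tau / kin$lambda_app
    }
    for (col in kcat_cols) {
      rid <- sub("^kcat_", "", col)
      kin$kcat[kin$reaction == rid] <- grid[[col]][i]
    }
    ddd_simulate(model, kin, cfg)
  }
  trajs <- lapply(seq_len(nrow(grid)), run_one)
  grid$trajectory <- trajs
  grid$summary <- lapply(trajs, episode_summary)
  grid
}
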
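# Demand-directed dFBA loop: initialisation, stepping, culture integration,
# parameter sweep plumbing.

short_cfg <- function(...) {
  ddd_config(horizon_min = 10, dt_min = 0.5, t_aer_min = 0, ...)
}

test_that("uptake bounds follow the configured kinetics", {
  expect_equal(uptake_bound(0, 10, "fixed"), 0)
  expect_equal(uptake_bound(3, 10, "fixed"), 10)
  expect_equal(uptake_bound(0, 10, "michaelis-menten", km = 0.5), 0)
  expect_equal(uptake_bound(0.5, 10, "michaelis-menten", km = 0.5), 5)
  expect_equal(uptake_bound(5000, 10, "michaelis-menten", km = 0.5), 10,
               tolerance = 1e-3)
  expect_error(uptake_bound(-1, 10), "non-negative")
})

test_that("culture integration matches the exponential-growth closure", {
  cul <- culture_state(biomass = 1, conc = c(glc_e = 5), time_min = 0)
  # mu = 0 branch: linear drawdown
  out <- update_culture(cul, c(glc_e = -1), mu = 0, dt_h = 1)
  expect_equal(out$conc[["glc_e"]], 4)
  expect_equal(out$biomass, 1)
  # exponential branch: C' = C + v X (exp(mu dt) - 1) / mu
  out2 <- update_culture(cul, c(glc_e = -2), mu = 0.5, dt_h = 0.3)
  expect_equal(out2$biomass, exp(0.5 * 0.3))
  expect_equal(out2$conc[["glc_e"]], 5 - 2 * (exp(0.15) - 1) / 0.5)
  # flooring at zero on depletion
  out3 <- update_culture(cul, c(glc_e = -100), mu = 0, dt_h = 1)
  expect_equal(out3$conc[["glc_e"]], 0)
})

test_that("initialisation reproduces the anaerobic basal state", {
  ini <- ddd_initialize(toy, toy_kin, ddd_config())
  expect_equal(ini$expression$signal, rep(0L, 6))
  expect_true(all(ini$expression$bound > 0))
  ss <- steady_state_expression(toy_kin, 0.26, R = 0)
  expect_equal(ini$expression$mrna, ss$mrna)
  expect_equal(ini$expression$bound, ss$bound)
  # a gene without basal transcription starts with a closed bound
  kin0 <- toy_kin
  kin0$s_b[kin0$reaction == "NADH5"] <- 0
  ini0 <- ddd_initialize(toy, kin0, ddd_config())
  expect_equal(ini0$expression$bound[ini0$expression$reaction == "NADH5"], 0)
  # initial bounds double with the translation constant
  b1 <- ddd_initialize(toy, toy_kinetics(tau = 0.3), ddd_config())$expression$bound
  b2 <- ddd_initialize(toy, toy_kinetics(tau = 0.6), ddd_config())$expression$bound
  expect_equal(2 * b1, b2, tolerance = 1e-12)
  # a model that cannot grow anaerobically is rejected at setup
  # (fermentative NADH sinks closed -> no anaerobic redox balance)
  m_bad <- set_bounds(toy, c("LDH", "ADHE"), lower = 0, upper = 0)
  expect_error(ddd_initialize(m_bad, toy_kin, ddd_config()), "anaerobic")
})

test_that("the anaerobic steady state is a fixed point with oxygen closed", {
  # initialise at the growth rate the anaerobic LP actually realises, then
  # keep oxygen closed: expression, bounds and fluxes must not drift
  mu_lp <- fba(toy_anaerobic)$growth_rate
  cfg <- ddd_config(horizon_min = 15, dt_min = 0.5, t_aer_min = 1e6,
                    mu_anaerobic = mu_lp)
  tr <- ddd_simulate(toy, toy_kin, cfg)
  drift <- tr$expression |>
    dplyr::group_by(reaction) |>
    dplyr::summarise(dm = max(abs(mrna - mrna[1])) / mrna[1],
                     db = max(abs(bound - bound[1])) / bound[1])
  expect_lt(max(drift$dm), 1e-6)
  expect_lt(max(drift$db), 1e-6)
  mus <- unique(tr$culture$growth_rate)
  expect_equal(mus, rep(mu_lp, length(mus)), tolerance = 1e-5)
})

test_that("fluxes respect the capacity bounds at every step", {
  cfg <- ddd_config(horizon_min = 30, dt_min = 1, t_aer_min = 5)
  tr <- ddd_simulate(toy, toy_kin, cfg)
  expect_true(all(abs(tr$expression$flux) <= tr$expression$bound + 1e-9))
  # demand-signal audit: R = 1 exactly when |flux| >= theta * bound
  audit <- tr$expression |>
    dplyr::mutate(expected = as.integer(abs(flux) >= cfg$theta * bound))
  expect_identical(audit$signal, audit$expected)
})

test_that("without balanced enzymes the loop reduces to plain dynamic FBA", {
  kin_empty <- toy_kin[0, ]
  cfg <- short_cfg()
  tr <- ddd_simulate(toy, kin_empty, cfg)
  expect_equal(nrow(tr$expression), 0)
  # every step realises the unconstrained aerobic optimum
  mu_ref <- fba(toy_aerobic)$growth_rate
  mus <- unique(tr$culture$growth_rate)
  expect_equal(mus, rep(mu_ref, length(mus)), tolerance = 1e-5)
  # glucose declines, biomass grows
  expect_lt(dplyr::last(tr$culture$glc_e), cfg$concentrations[["glc_e"]])
  expect_gt(dplyr::last(tr$culture$biomass), cfg$biomass_0)
})

test_that("glucose drawdown equals the biomass-weighted uptake integral", {
  cfg <- ddd_config(horizon_min = 30, dt_min = 0.5, t_aer_min = 0)
  tr <- ddd_simulate(toy, toy_kin, cfg)
  cul <- tr$culture
  flux <- tr$fluxes |> dplyr::filter(reaction == "EX_glc_e")
  dt_h <- cfg$dt_min / 60
  # fine-step quadrature oracle: within each SOA step the specific uptake is
  # constant and biomass grows exponentially, so integrate v X0 exp(mu t)
  # by a dense midpoint rule and compare with the recorded drawdown
  n_sub <- 200
  tau <- (seq_len(n_sub) - 0.5) * dt_h / n_sub
  consumed <- 0
  for (k in seq_len(nrow(cul))) {
    consumed <- consumed - flux$flux[k] *
      sum(cul$biomass[k] * exp(cul$growth_rate[k] * tau)) * dt_h / n_sub
  }
  # recorded drawdown over the run (concentrations are stored at step start,
  # so add the final step's own consumption)
  final <- update_culture(
    culture_state(dplyr::last(cul$biomass),
                  c(glc_e = dplyr::last(cul$glc_e))),
    c(glc_e = dplyr::last(flux$flux)), dplyr::last(cul$growth_rate), dt_h)
  drawdown <- cfg$concentrations[["glc_e"]] - final$conc[["glc_e"]]
  expect_equal(drawdown, consumed, tolerance = 1e-6)
  # halving the step changes the consumed total by little (SOA convergence)
  cfg2 <- ddd_config(horizon_min = 30, dt_min = 0.25, t_aer_min = 0)
  tr2 <- ddd_simulate(toy, toy_kin, cfg2)
  c1 <- cfg$concentrations[["glc_e"]] - dplyr::last(tr$culture$glc_e)
  c2 <- cfg2$concentrations[["glc_e"]] - dplyr::last(tr2$culture$glc_e)
  expect_lt(abs(c1 - c2) / c2, 0.02)
})

test_that("substrate exhaustion yields a dormant (mu = 0) continuation", {
  cfg <- ddd_config(horizon_min = 40, dt_min = 1, t_aer_min = 0,
                    concentrations = c(glc_e = 0.03), biomass_0 = 0.5)
  tr <- ddd_simulate(toy, toy_kin, cfg)
  expect_true(any(tr$culture$status == "dormant"))
  dormant <- tr$culture$status == "dormant"
  expect_true(all(tr$culture$growth_rate[dormant] == 0))
  # glucose is exhausted and stays at zero
  expect_equal(dplyr::last(tr$culture$glc_e), 0)
  # fluxes are zero while dormant
  t_dorm <- tr$culture$time_min[dormant][1]
  f <- tr$fluxes |> dplyr::filter(time_min == t_dorm)
  expect_true(all(abs(f$flux) < 1e-12))
})

test_that("per-step FVA brackets the parsimonious flux", {
  cfg <- ddd_config(horizon_min = 6, dt_min = 1, t_aer_min = 0,
                    fva_reactions = c("CYTBO", "CYTBD", "NADH5"))
  tr <- ddd_simulate(toy, toy_kin, cfg)
  joined <- dplyr::inner_join(tr$fva, tr$expression,
                              by = c("time_min", "reaction"))
  expect_true(all(joined$flux >= joined$min - 1e-6))
  expect_true(all(joined$flux <= joined$max + 1e-6))
})

test_that("the aeration shift produces the transient MLE-oxidase episode", {
  cfg <- ddd_config(horizon_min = 45, dt_min = 0.5, t_aer_min = 5)
  tr <- ddd_simulate(toy, toy_kin, cfg)
  cyd <- tr$expression |> dplyr::filter(reaction == "CYTBD")
  cyo <- tr$expression |> dplyr::filter(reaction == "CYTBO")
  on <- cyd$time_min[abs(cyd$flux) > 1e-6]
  expect_gt(length(on), 0)
  t1 <- min(on); t2 <- max(on)
  # interior interval: after aeration, before the horizon
  expect_gte(t1, cfg$t_aer_min)
  expect_lt(t2, cfg$horizon_min - cfg$dt_min)
  # quiet before and after
  expect_true(all(abs(cyd$flux[cyd$time_min < t1]) < 1e-6))
  expect_true(all(abs(cyd$flux[cyd$time_min > t2]) < 1e-6))
  # efficient oxidase rides its bound while the MLE oxidase assists
  during <- cyo |> dplyr::filter(time_min >= t1, time_min <= t2)
  expect_true(all(abs(during$flux) >= during$bound * (1 - 1e-6) - 1e-9))
  # MLE oxidase mRNA rises then decays back toward basal
  basal <- cyd$mrna[1]
  expect_gt(max(cyd$mrna), basal * 1.2)
  expect_lt(dplyr::last(cyd$mrna), max(cyd$mrna) * 0.8)
  # growth after adaptation beats anaerobic growth
  expect_gt(dplyr::last(tr$culture$growth_rate), tr$culture$growth_rate[1])
})

test_that("parameter sweeps vary tau, theta and kcat coherently", {
  cfg <- ddd_config(horizon_min = 8, dt_min = 1, t_aer_min = 0)
  grid <- tidyr::expand_grid(tau = c(0.3, 0.6))
  sw <- parameter_sweep(toy, toy_kin, cfg, grid)
  expect_equal(nrow(sw), 2)
  b0 <- vapply(sw$trajectory, function(tr) {
    tr$expression$bound[tr$expression$time_min == 0 &
                          tr$expression$reaction == "CYTBO"]
  }, numeric(1))
  expect_equal(b0[2] / b0[1], 2, tolerance = 1e-9)
  # kcat override rescales that reaction's bound only
  sw2 <- parameter_sweep(toy, toy_kin, cfg,
                         tibble::tibble(kcat_CYTBO = c(341, 682)))
  b0k <- vapply(sw2$trajectory, function(tr) {
    tr$expression$bound[tr$expression$time_min == 0 &
                          tr$expression$reaction == "CYTBO"]
  }, numeric(1))
  expect_equal(b0k[2] / b0k[1], 2, tolerance = 1e-9)
  other <- vapply(sw2$trajectory, function(tr) {
    tr$expression$bound[tr$expression$time_min == 0 &
                          tr$expression$reaction == "NADH5"]
  }, numeric(1))
  expect_equal(other[1], other[2])
  expect_error(parameter_sweep(toy, toy_kin, cfg, tibble::tibble()), "empty")
  expect_error(parameter_sweep(toy, toy_kin, cfg,
                               tibble::tibble(nope = 1)), "unknown")
})

test_that("configurations validate and round trip through YAML", {
  expect_error(ddd_config(theta = 0), "theta")
  expect_error(ddd_config(dt_min = -1), "positive")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("theta: 0.4", "tau: 0.9", "dt_min: 1",
               "concentrations:", "  glc_e: 12"), path)
  cfg <- read_ddd_config(path)
  expect_equal(cfg$theta, 0.4)
  expect_equal(cfg$tau, 0.9)
  expect_equal(cfg$concentrations[["glc_e"]], 12)
  writeLines("not_a_key: 1", path)
  expect_error(read_ddd_config(path), "unknown configuration key")
})
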
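# LP core: growth FBA, parsimonious FBA (L1/L2), flux variability.

# two-route micro model: substrate A enters; route 1 is a single reaction,
# route 2 a two-reaction chain; both yield biomass product B with the same
# stoichiometry
two_route_model <- function() {
  mets <- tibble::tibble(id = c("a_e", "a_c", "x_c", "b_c"),
                         external = c(TRUE, FALSE, FALSE, FALSE))
  rxns <- dplyr::bind_rows(
    toy_rxn("EX_a", c(a_e = -1), lb = -10),
    toy_rxn("At", c(a_e = -1, a_c = 1)),
    toy_rxn("DIRECT", c(a_c = -1, b_c = 1)),
    toy_rxn("STEP1", c(a_c = -1, x_c = 1)),
    toy_rxn("STEP2", c(x_c = -1, b_c = 1)),
    toy_rxn("GROW", c(b_c = -1)))
  metabolic_model(mets, rxns, objective = "GROW", id = "two_route")
}

test_that("closing the carbon source drives growth to zero", {
  m <- set_bounds(toy_aerobic, "EX_glc_e", lower = 0)
  g <- fba(m)
  expect_equal(g$growth_rate, 0, tolerance = 1e-9)
})

test_that("FBA matches the independent LP oracle on toy scenarios", {
  for (model in list(toy_anaerobic, toy_aerobic,
                     set_bounds(toy_aerobic, "NADH16", upper = 0.2),
                     set_bounds(toy_aerobic, c("CYTBO", "PDH", "AKGDH"),
                                upper = c(4.42, 0.12, 0.032)))) {
    g <- fba(model)
    o <- lp_oracle(model, "BIOMASS", maximize = TRUE)
    expect_equal(g$status, "optimal")
    expect_equal(g$growth_rate, o$objective, tolerance = 1e-6)
  }
})

test_that("aerobic growth exceeds anaerobic growth at equal glucose uptake", {
  mu_an <- fba(toy_anaerobic)$growth_rate
  mu_ae <- fba(toy_aerobic)$growth_rate
  expect_gt(mu_ae, mu_an)
  # hand-derivable values of the toy stoichiometry
  expect_equal(mu_an, 4 / 15, tolerance = 1e-8)
  expect_equal(mu_ae, 0.7, tolerance = 1e-8)
})

test_that("optimal solutions satisfy steady state and bounds", {
  for (model in list(toy_anaerobic, toy_aerobic)) {
    for (sol in list(fba(model), pfba(model), pfba(model, norm = "l2"))) {
      v <- stats::setNames(sol$fluxes$flux, sol$fluxes$reaction)
      expect_lt(max(abs(stoich_matrix(model) %*% v)), 1e-6)
      expect_true(all(v >= pmax(model$reactions$lower_bound, -1000) - 1e-7))
      expect_true(all(v <= pmin(model$reactions$upper_bound, 1000) + 1e-7))
    }
  }
})

test_that("infeasible and degenerate models are reported, not crashed", {
  # force impossible growth
  m <- set_bounds(toy_anaerobic, "BIOMASS", lower = 5, upper = 5)
  g <- fba(m)
  expect_equal(g$status, "infeasible")
  expect_equal(nrow(g$fluxes), 0)
  expect_error(pfba(toy_anaerobic, mu_star = 5), "infeasible")
})

test_that("L1 pFBA routes flux through the shorter of two equal-yield routes", {
  m <- two_route_model()
  g <- fba(m)
  expect_equal(g$growth_rate, 10, tolerance = 1e-9)
  p1 <- pfba(m, norm = "l1")
  v <- stats::setNames(p1$fluxes$flux, p1$fluxes$reaction)
  expect_equal(unname(v["DIRECT"]), 10, tolerance = 1e-6)
  expect_equal(unname(v["STEP1"]), 0, tolerance = 1e-6)
  # enumerate both vertices: all-direct beats all-chain in total |v|
  total_direct <- 10 + 10 + 10 + 10           # EX, At, DIRECT, GROW
  total_chain <- 10 + 10 + 10 + 10 + 10       # EX, At, STEP1, STEP2, GROW
  expect_equal(sum(abs(v)), total_direct, tolerance = 1e-6)
  expect_lt(total_direct, total_chain)
})

test_that("L2 pFBA splits flux across parallel routes where L1 does not", {
  # two identical single-reaction routes: L2 minimiser of x^2 + y^2 with
  # x + y = T is the even split, analytically T^2/2
  mets <- tibble::tibble(id = c("a_e", "a_c", "b_c"),
                         external = c(TRUE, FALSE, FALSE))
  rxns <- dplyr::bind_rows(
    toy_rxn("EX_a", c(a_e = -1), lb = -8),
    toy_rxn("At", c(a_e = -1, a_c = 1)),
    toy_rxn("PAR1", c(a_c = -1, b_c = 1)),
    toy_rxn("PAR2", c(a_c = -1, b_c = 1)),
    toy_rxn("GROW", c(b_c = -1)))
  m <- metabolic_model(mets, rxns, objective = "GROW", id = "parallel")
  p2 <- pfba(m, norm = "l2")
  v2 <- stats::setNames(p2$fluxes$flux, p2$fluxes$reaction)
  expect_equal(unname(v2["PAR1"]), 4, tolerance = 1e-5)
  expect_equal(unname(v2["PAR2"]), 4, tolerance = 1e-5)
  expect_equal(sum(v2[c("PAR1", "PAR2")]^2), 8^2 / 2, tolerance = 1e-4)
  # L1 leaves the split degenerate but total flux equals the vertex value
  p1 <- pfba(m, norm = "l1")
  v1 <- stats::setNames(p1$fluxes$flux, p1$fluxes$reaction)
  expect_equal(unname(v1["PAR1"] + v1["PAR2"]), 8, tolerance = 1e-5)
})

test_that("pFBA preserves the growth optimum and reduces total flux", {
  g <- fba(toy_aerobic)
  p <- pfba(toy_aerobic, mu_star = g$growth_rate)
  expect_equal(p$growth_rate, g$growth_rate, tolerance = 1e-5)
  expect_lte(sum(abs(p$fluxes$flux)), sum(abs(g$fluxes$flux)) + 1e-7)
  # L1 objective value matches the oracle's minimal total flux
  o <- lp_oracle_l1(toy_aerobic, g$growth_rate)
  expect_equal(p$objective_value, o, tolerance = 1e-5)
})

test_that("identical parallel reactions have FVA interval [0, T]", {
  mets <- tibble::tibble(id = c("a_e", "a_c", "b_c"),
                         external = c(TRUE, FALSE, FALSE))
  rxns <- dplyr::bind_rows(
    toy_rxn("EX_a", c(a_e = -1), lb = -6),
    toy_rxn("At", c(a_e = -1, a_c = 1)),
    toy_rxn("PAR1", c(a_c = -1, b_c = 1)),
    toy_rxn("PAR2", c(a_c = -1, b_c = 1)),
    toy_rxn("GROW", c(b_c = -1)))
  m <- metabolic_model(mets, rxns, objective = "GROW")
  mu <- fba(m)$growth_rate
  iv <- fva(m, mu_star = mu, reactions = c("PAR1", "PAR2", "At"))
  t_total <- 6
  expect_equal(iv$min[iv$reaction == "PAR1"], 0, tolerance = 1e-5)
  expect_equal(iv$max[iv$reaction == "PAR1"], t_total, tolerance = 1e-4)
  expect_equal(iv$min[iv$reaction == "PAR2"], 0, tolerance = 1e-5)
  expect_equal(iv$max[iv$reaction == "PAR2"], t_total, tolerance = 1e-4)
  # unique-path reaction has a degenerate interval
  expect_equal(iv$min[iv$reaction == "At"], iv$max[iv$reaction == "At"],
               tolerance = 1e-4)
})

test_that("every pFBA flux lies inside its FVA interval", {
  mu <- fba(toy_aerobic)$growth_rate
  p <- pfba(toy_aerobic, mu_star = mu)
  iv <- fva(toy_aerobic, mu_star = mu)
  v <- stats::setNames(p$fluxes$flux, p$fluxes$reaction)
  expect_true(all(v[iv$reaction] >= iv$min - 1e-6))
  expect_true(all(v[iv$reaction] <= iv$max + 1e-6))
})

test_that("FVA extrema agree with the oracle and shrink with bounds", {
  mu <- fba(toy_aerobic)$growth_rate
  iv <- fva(toy_aerobic, mu_star = mu,
            reactions = c("NADH5", "CYTBD", "MDH2", "LDH"))
  fix <- list(BIOMASS = c(mu * (1 - 1e-6), mu))
  for (r in iv$reaction) {
    omin <- lp_oracle(toy_aerobic, r, maximize = FALSE, fix = fix)
    omax <- lp_oracle(toy_aerobic, r, maximize = TRUE, fix = fix)
    expect_equal(iv$min[iv$reaction == r], omin$objective, tolerance = 1e-5)
    expect_equal(iv$max[iv$reaction == r], omax$objective, tolerance = 1e-5)
  }
  # shrinking a bound weakly shrinks its interval
  m2 <- set_bounds(toy_aerobic, "LDH", lower = -1, upper = 1)
  iv2 <- fva(m2, mu_star = fba(m2)$growth_rate, reactions = "LDH")
  expect_gte(iv2$min, iv$min[iv$reaction == "LDH"] - 1e-6)
  expect_lte(iv2$max, iv$max[iv$reaction == "LDH"] + 1e-6)
})
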
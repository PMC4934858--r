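# Flux lumping, DE filtering, differential-flux calls, rank correlation.

test_that("fold-change aggregation uses least-absolute subunits and mean isoenzymes", {
  expect_equal(aggregate_fold_change(list(c(2.0, 0.5))), 0.5)
  expect_equal(aggregate_fold_change(list(1.0, 3.0)), 2.0)
  expect_equal(aggregate_fold_change(0.7), 0.7)
  # sign is preserved when the least-absolute subunit is negative
  expect_equal(aggregate_fold_change(list(c(2.0, -0.3))), -0.3)
  # signed mode takes the minimum signed value instead
  expect_equal(aggregate_fold_change(list(c(2.0, -0.3)), mode = "signed"), -0.3)
  expect_equal(aggregate_fold_change(list(c(2.0, 0.5)), mode = "signed"), 0.5)
  expect_error(aggregate_fold_change(list()), "at least one")
})

test_that("reaction fold changes map genes through GPR structure", {
  de <- tibble::tibble(gene = c("a", "b", "c"), logFC = c(2, 0.5, 1))
  gpr <- c(R1 = "a and b", R2 = "(a and b) or c", R3 = "d", R4 = "")
  fc <- reaction_fold_changes(de, gpr)
  expect_equal(fc$logFC[fc$reaction == "R1"], 0.5)
  expect_equal(fc$logFC[fc$reaction == "R2"], mean(c(0.5, 1)))
  expect_true(is.na(fc$logFC[fc$reaction == "R3"]))   # gene missing from table
  expect_true(is.na(fc$logFC[fc$reaction == "R4"]))   # no genes
})

test_that("the DE filter applies all three thresholds jointly", {
  tab <- tibble::tibble(
    gene = c("keep", "low_fc", "low_cpm", "high_fdr"),
    logFC = c(log2(1.3), log2(1.2), 5, 3),
    logCPM = c(2.5, 5, 1.9, 6),
    FDR = c(0.01, 0.001, 0.01, 0.2))
  kept <- de_filter(tab)
  expect_identical(kept$gene, "keep")
  # brute-force row-wise evaluation on a planted table
  tab2 <- synth_de_table(50, n_pass = 17, seed = 21)
  kept2 <- de_filter(tab2)
  brute <- tab2[abs(tab2$logFC) >= log2(1.25) & tab2$logCPM >= 2 &
                  tab2$FDR <= 0.05, ]
  expect_identical(kept2$gene, brute$gene)
  expect_identical(sort(kept2$gene), sort(tab2$gene[tab2$planted_pass]))
})

test_that("relaxing any DE threshold yields a superset", {
  tab <- synth_de_table(80, n_pass = 30, seed = 5)
  base <- de_filter(tab)$gene
  expect_true(all(base %in% de_filter(tab, min_fc = 1.1)$gene))
  expect_true(all(base %in% de_filter(tab, min_logcpm = 0)$gene))
  expect_true(all(base %in% de_filter(tab, max_fdr = 0.2)$gene))
  # the generic strict profile is more stringent on fold change
  strict <- de_profile("strict")
  kept_strict <- de_filter(tab, strict$min_fc, strict$min_logcpm,
                           strict$max_fdr)$gene
  expect_true(all(kept_strict %in% de_filter(tab, min_fc = 2,
                                             min_logcpm = -Inf)$gene))
})

test_that("flux lumping sums absolute fluxes within enzyme-set signatures", {
  gpr <- c(A1 = "g1 and g2", A2 = "g2 and g1", B = "g3", C = "")
  fluxes <- tibble::tibble(reaction = c("A1", "A2", "B", "C"),
                           flux = c(2, -1, 0.5, 99))
  lump <- lump_fluxes(fluxes, gpr)
  expect_equal(lump$flux_sum[lump$signature == "g1|g2"], 3)
  expect_equal(lump$flux_sum[lump$signature == "g3"], 0.5)
  # gene-free reactions never join a lump
  expect_false("" %in% lump$signature)
  expect_equal(nrow(lump), 2)
  # invariant to reaction order and to flux sign
  lump2 <- lump_fluxes(fluxes[c(3, 1, 4, 2), ], gpr)
  expect_equal(dplyr::arrange(lump2, signature)$flux_sum,
               dplyr::arrange(lump, signature)$flux_sum)
  # toy model: lumping equals brute-force grouping by gene sets
  p <- pfba(toy_aerobic)
  gpr_toy <- stats::setNames(toy$reactions$gpr, toy$reactions$id)
  lump_toy <- lump_fluxes(p, gpr_toy)
  v <- stats::setNames(p$fluxes$flux, p$fluxes$reaction)
  sets <- lapply(gpr_toy, enzyme_set)
  for (i in seq_len(nrow(lump_toy))) {
    members <- names(sets)[vapply(sets, function(s)
      identical(s, lump_toy$genes[[i]]), logical(1))]
    expect_equal(lump_toy$flux_sum[i], sum(abs(v[members])))
  }
})

test_that("differential-flux calls require both criteria by default", {
  expect_true(differential_flux(0.0, 0.3, c(0, 0.1), c(0.5, 0.6)))
  expect_false(differential_flux(1, 1, c(0, 0.1), c(0.5, 0.6)))  # no diff
  expect_false(differential_flux(0, 0.5, c(0, 1), c(0.4, 0.8)))  # overlap
  # touching endpoints count as overlapping (closed intervals)
  expect_false(differential_flux(0, 0.5, c(0, 0.4), c(0.4, 0.8)))
  # either-mode accepts a single criterion
  expect_true(differential_flux(0, 0.5, c(0, 1), c(0.4, 0.8),
                                criteria = "either"))
  # without intervals only the magnitude criterion applies
  expect_true(differential_flux(0, 0.26))
  expect_false(differential_flux(0, 0.24))
})

test_that("FVA lumping adds |flux| ranges per signature", {
  gpr <- c(A1 = "g1", A2 = "g1", B = "g2")
  fva_tab <- tibble::tibble(reaction = c("A1", "A2", "B"),
                            min = c(-2, 1, 0), max = c(1, 3, 0.5))
  lump <- lump_fva(fva_tab, gpr)
  # |v| over [-2,1] is [0,2]; over [1,3] is [1,3]: sum [1,5]
  expect_equal(lump$min[lump$signature == "g1"], 1)
  expect_equal(lump$max[lump$signature == "g1"], 5)
  expect_equal(lump$min[lump$signature == "g2"], 0)
})

test_that("Spearman rho and permutation p match full enumeration at n = 6", {
  set.seed(31)
  x <- stats::rnorm(6); y <- stats::rnorm(6)
  rep <- correlate_flux_expression(tibble::tibble(flux_diff = x, logFC = y))
  expect_equal(rep$p_method, "exact permutation")
  # brute-force oracle: all 720 orderings of y
  perms <- NULL
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  rhos <- vapply(permute(seq_len(6)), function(p) stats::cor(rx, ry[p]),
                 numeric(1))
  p_brute <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(rep$rho, rho_obs, tolerance = 1e-12)
  expect_equal(rep$p_value, p_brute, tolerance = 1e-12)
})

test_that("monotone pairs give |rho| = 1 and transforms leave rho unchanged", {
  x <- c(0.1, 0.4, 1, 2.2, 5)
  up <- correlate_flux_expression(tibble::tibble(flux_diff = x,
                                                 logFC = x^2 + 1))
  expect_equal(up$rho, 1)
  down <- correlate_flux_expression(tibble::tibble(flux_diff = x,
                                                   logFC = -log(x)))
  expect_equal(down$rho, -1)
  set.seed(8)
  a <- stats::rnorm(12); b <- stats::rnorm(12)
  r1 <- correlate_flux_expression(tibble::tibble(flux_diff = a, logFC = b))
  r2 <- correlate_flux_expression(tibble::tibble(flux_diff = exp(a),
                                                 logFC = b^3))
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
})

test_that("regression line and confidence band come from least squares", {
  set.seed(17)
  pts <- tibble::tibble(flux_diff = stats::rnorm(15),
                        logFC = stats::rnorm(15))
  rep <- correlate_flux_expression(pts)
  ref <- stats::lm(logFC ~ flux_diff, data = pts)
  expect_equal(rep$slope, unname(stats::coef(ref)[2]))
  expect_equal(rep$intercept, unname(stats::coef(ref)[1]))
  band <- stats::predict(ref, interval = "confidence")
  expect_equal(rep$points$conf_lo, unname(band[, "lwr"]))
  expect_true(all(rep$points$conf_lo <= rep$points$fitted))
  g <- glance(rep)
  expect_equal(g$n, 15)
  # degenerate constant input flags rho as undefined
  const <- correlate_flux_expression(
    tibble::tibble(flux_diff = rep(1, 5), logFC = stats::rnorm(5)))
  expect_true(is.na(const$rho))
  expect_error(correlate_flux_expression(
    tibble::tibble(flux_diff = 1:2, logFC = 1:2)), "at least 3")
})

test_that("the end-to-end pipeline correlates planted flux and expression changes", {
  # two conditions of the toy model: anaerobic vs aerobic parsimonious fluxes
  mu_a <- fba(toy_anaerobic)$growth_rate
  mu_b <- fba(toy_aerobic)$growth_rate
  pa <- pfba(toy_anaerobic, mu_star = mu_a)
  pb <- pfba(toy_aerobic, mu_star = mu_b)
  gpr_toy <- stats::setNames(toy$reactions$gpr, toy$reactions$id)
  # DE table aligned with the flux direction: genes of aerobically used
  # reactions up, fermentation genes down
  de <- tibble::tibble(
    gene = c("nuoA", "nuoB", "nuoG", "cyoA", "cyoB", "cyoC", "cyoD",
             "aceE", "aceF", "lpd", "gltA", "icd", "sucA", "sucB", "mdh",
             "ldhA", "pgk", "ptsG"),
    logFC = c(rep(2.2, 3), rep(2.8, 4), rep(1.6, 3), 1.2, 1.1, rep(1.4, 2),
              0.9, -2.5, 0.4, 0.4),
    logCPM = 6, FDR = 0.001)
  rep <- flux_expression_report(de, tidy(pa), tidy(pb), gpr_toy,
                                fva_a = fva(toy_anaerobic, mu_star = mu_a),
                                fva_b = fva(toy_aerobic, mu_star = mu_b))
  expect_gte(rep$n, 3)
  expect_gt(rep$rho, 0)
  expect_gt(rep$slope, 0)
})
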
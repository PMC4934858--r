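# Synthetic data: a small aerobic/anaerobic toy metabolic network with
# efficient and less-efficient parallel pathways, a matching kinetics table,
# and generated RPKM time courses / differential-expression tables with known
# ground truth.

toy_rxn <- function(id, stoich, lb = 0, ub = 1000, gpr = "") {
  tibble::tibble(id = id, stoichiometry = list(stoich),
                 lower_bound = lb, upper_bound = ub, gpr = gpr)
}

#' Toy metabolic model of the anaerobic-to-aerobic shift
#'
#' A ~30-reaction network mirroring central aerobic carbon metabolism:
#' glycolysis feeding pyruvate, pyruvate dehydrogenase into a lumped TCA leg,
#' a glyoxylate-shunt bypass, an electron transport chain with
#' proton-translocating (NADH16, CYTBO) and metabolically less efficient
#' (NADH5, CYTBD: fewer or no protons translocated) branches, a
#' malate:quinone oxidoreductase and a lactate-dependent NADH reoxidation
#' loop, ATP synthase driven by the translocated protons, and fermentative
#' outlets (lactate, ethanol) enabling anaerobic growth. Biomass consumes
#' pyruvate, ATP and NADH; coefficients are scaled so that specific growth
#' rates fall in a realistic range (anaerobic optimum ~0.27 1/h at a glucose
#' uptake of 10 mmol h^-1 gDCW^-1).
#'
#' The oxygen exchange ships closed (anaerobic base state); the simulation
#' driver opens it at the aeration time.
#'
#' @param protons_nadh16,protons_nadh5 Protons translocated per NADH oxidised
#'   by the efficient and the less-efficient NADH dehydrogenase (default 4
#'   and 0; the efficient branch must translocate strictly more).
#' @param protons_cytbo,protons_cytbd Protons translocated per quinol by the
#'   efficient and the less-efficient terminal oxidase (default 4 and 2).
#' @param protons_per_atp Protons consumed by ATP synthase per ATP (default 4).
#' @param biomass_pyr,biomass_atp,biomass_nadh Biomass composition
#'   (mmol per gDCW of pyruvate, ATP, NADH; defaults 25, 75, 25).
#' @param glc_max Default glucose uptake bound (mmol h^-1 gDCW^-1).
#' @return A `ddd_model` with gene lengths attached.
#' @export
toy_model <- function(protons_nadh16 = 4, protons_nadh5 = 0,
                      protons_cytbo = 4, protons_cytbd = 2,
                      protons_per_atp = 4,
                      biomass_pyr = 25, biomass_atp = 75, biomass_nadh = 25,
                      glc_max = 10) {
  if (protons_nadh16 <= protons_nadh5 || protons_cytbo <= protons_cytbd) {
    stop("efficient branches must translocate strictly more protons than ",
         "their less-efficient counterparts", call. = FALSE)
  }
  if (protons_per_atp <= 0) stop("protons_per_atp must be positive",
                                 call. = FALSE)
  mets <- tibble::tibble(
    id = c("glc_e", "o2_e", "lac_e", "etoh_e", "co2_e", "pyr_e",
           "glc_c", "pyr_c", "accoa_c", "icit_c", "akg_c", "mal_c", "oaa_c",
           "nad_c", "nadh_c", "adp_c", "atp_c", "q_c", "qh2_c", "o2_c",
           "lac_c", "etoh_c", "co2_c", "hp_c"),
    external = c(rep(TRUE, 6), rep(FALSE, 18)))
  rxns <- dplyr::bind_rows(
    toy_rxn("EX_glc_e", c(glc_e = -1), lb = -glc_max),
    toy_rxn("EX_o2_e", c(o2_e = -1), lb = 0),
    toy_rxn("EX_lac_e", c(lac_e = -1)),
    toy_rxn("EX_pyr_e", c(pyr_e = -1)),
    toy_rxn("EX_etoh_e", c(etoh_e = -1)),
    toy_rxn("EX_co2_e", c(co2_e = -1)),
    toy_rxn("GLCt", c(glc_e = -1, glc_c = 1), gpr = "ptsG"),
    toy_rxn("O2t", c(o2_e = -1, o2_c = 1)),
    toy_rxn("LACt", c(lac_c = -1, lac_e = 1)),
    # overflow secretion of surplus pyruvate (redox-neutral, like the
    # acetate overflow of aerobic E. coli); without it every surplus
    # pyruvate would drag one NADH into fermentation and starve the ETC
    toy_rxn("PYRt", c(pyr_c = -1, pyr_e = 1)),
    toy_rxn("ETOHt", c(etoh_c = -1, etoh_e = 1)),
    toy_rxn("CO2t", c(co2_c = -1, co2_e = 1)),
    toy_rxn("GLYC", c(glc_c = -1, adp_c = -2, nad_c = -2,
                      pyr_c = 2, atp_c = 2, nadh_c = 2), gpr = "pgk"),
    toy_rxn("PDH", c(pyr_c = -1, nad_c = -1,
                     accoa_c = 1, nadh_c = 1, co2_c = 1),
            gpr = "aceE and aceF and lpd"),
    toy_rxn("CS", c(accoa_c = -1, oaa_c = -1, icit_c = 1), gpr = "gltA"),
    toy_rxn("ICDH", c(icit_c = -1, nad_c = -1,
                      akg_c = 1, nadh_c = 1, co2_c = 1), gpr = "icd"),
    toy_rxn("AKGDH", c(akg_c = -1, nad_c = -2, adp_c = -1,
                       mal_c = 1, nadh_c = 2, atp_c = 1, co2_c = 1),
            gpr = "sucA and sucB and lpd"),
    toy_rxn("MDH", c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1),
            lb = -1000, gpr = "mdh"),
    toy_rxn("MDH2", c(mal_c = -1, q_c = -1, oaa_c = 1, qh2_c = 1),
            gpr = "mqo"),
    toy_rxn("GLYSHNT", c(icit_c = -1, accoa_c = -1, mal_c = 2),
            gpr = "aceA and aceB"),
    # malic enzyme: drains the malate pool back to pyruvate, giving the
    # glyoxylate shunt a steady-state outlet
    toy_rxn("ME", c(mal_c = -1, nad_c = -1, pyr_c = 1, nadh_c = 1,
                    co2_c = 1), gpr = "maeA"),
    toy_rxn("NADH16", c(nadh_c = -1, q_c = -1, nad_c = 1, qh2_c = 1,
                        hp_c = protons_nadh16),
            gpr = "nuoA and nuoB and nuoG"),
    toy_rxn("NADH5", drop_zero(c(nadh_c = -1, q_c = -1, nad_c = 1, qh2_c = 1,
                                 hp_c = protons_nadh5)), gpr = "ndh"),
    toy_rxn("CYTBO", c(qh2_c = -1, o2_c = -0.5, q_c = 1,
                       hp_c = protons_cytbo),
            gpr = "cyoA and cyoB and cyoC and cyoD"),
    toy_rxn("CYTBD", c(qh2_c = -1, o2_c = -0.5, q_c = 1,
                       hp_c = protons_cytbd), gpr = "cydA and cydB"),
    toy_rxn("ATPS", c(hp_c = -protons_per_atp, adp_c = -1, atp_c = 1),
            gpr = "atpA and atpB"),
    # non-growth-associated maintenance / energy spilling: without a
    # dissipative ATP sink the rigid biomass ATP:precursor ratio would make
    # surplus respiratory ATP infeasible and suppress capacity-limited
    # respiration altogether
    toy_rxn("ATPM", c(atp_c = -1, adp_c = 1)),
    toy_rxn("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1),
            lb = -1000, gpr = "ldhA"),
    toy_rxn("LDHQ", c(lac_c = -1, q_c = -1, pyr_c = 1, qh2_c = 1),
            gpr = "dld"),
    toy_rxn("ADHE", c(accoa_c = -1, nadh_c = -2, etoh_c = 1, nad_c = 2),
            gpr = "adhE"),
    toy_rxn("BIOMASS", c(pyr_c = -biomass_pyr, atp_c = -biomass_atp,
                         nadh_c = -biomass_nadh, adp_c = biomass_atp,
                         nad_c = biomass_nadh)))
  metabolic_model(mets, rxns, objective = "BIOMASS", genes = toy_genes(),
                  id = "toy_shift")
}

drop_zero <- function(x) x[x != 0]

# gene lengths: the six balanced genes carry their literature lengths; the
# remaining lengths are plausible E. coli values and only matter for the
# largest-subunit rule.
toy_genes <- function() {
  tibble::tribble(
    ~gene_id, ~length_bp, ~copies,
    "cydA", 1569, 1,
    "cydB", 1137, 1,
    "cyoA",  948, 1,
    "cyoB", 1992, 1,
    "cyoC",  615, 1,
    "cyoD",  330, 1,
    "ndh",  1305, 1,
    "nuoA",  444, 1,
    "nuoB",  663, 1,
    "nuoG", 2727, 1,
    "sucA", 2802, 12,
    "sucB", 1218, 1,
    "lpd",  1425, 1,
    "aceE", 2664, 1,
    "aceF", 1890, 1,
    "aceA", 1305, 1,
    "aceB", 1602, 1,
    "gltA", 1284, 1,
    "icd",  1251, 1,
    "mdh",   939, 1,
    "mqo",  1647, 1,
    "maeA", 1698, 1,
    "ldhA",  990, 1,
    "dld",  1716, 1,
    "adhE", 2676, 1,
    "atpA", 1542, 1,
    "atpB",  816, 1,
    "pgk",  1164, 1,
    "ptsG", 2154, 1)
}

#' Kinetics table of the six balanced toy reactions
#'
#' The expression-balanced reactions of the toy scenario with their
#' literature-derived parameters: transcription rates and degradation rates
#' per minute, turnover numbers, and the largest-subunit gene lengths
#' (2-oxoglutarate dehydrogenase with 12 copies of its largest subunit, so
#' its apparent gene length includes the ribosome-spacing correction).
#'
#' @inheritParams enzyme_kinetics
#' @return A `ddd_kinetics` tibble with rows CYTBD, CYTBO, NADH5, NADH16,
#'   AKGDH, PDH.
#' @export
toy_kinetics <- function(tau = 0.6, spacing_bp = 72) {
  enzyme_kinetics(
    reaction = c("CYTBD", "CYTBO", "NADH5", "NADH16", "AKGDH", "PDH"),
    gene = c("cydA", "cyoB", "ndh", "nuoG", "sucA", "aceE"),
    gene_length_bp = c(1569, 1992, 1305, 2727, 2802, 2664),
    copies = c(1, 1, 1, 1, 12, 1),
    s_b = c(116.3, 2.4, 5.9, 25.1, 12.1, 48.1),
    s_a = c(759.1, 610.9, 504.6, 30.0, 143.1, 2334.0),
    gamma = c(0.187, 0.210, 0.210, 10.68, 11.76, 7.5),
    kcat = c(11.7, 341, 15.8, 100, 49, 21.9),
    tau = tau, spacing_bp = spacing_bp)
}

#' Generate synthetic RPKM time courses
#'
#' Simulates RPKM time courses from the delayed-activation mRNA model
#' ([mrna_solution()]) with multiplicative Gaussian noise
#' `RPKM = m(t) (1 + e)`, `e ~ N(0, sigma^2)`, floored at 0 (noise variance
#' growing with expression level, as for RPKM data). With replicates the
#' per-time mean and standard deviation are reported.
#'
#' @param truth Tibble with columns `gene`, `s_b`, `s_a`, `T_d`, `gamma`
#'   (per-gene generative parameters).
#' @param times Sampling times (min; include pre-shift points at t < 0 for
#'   the basal state).
#' @param sigma Noise fraction (>= 0, default 0.05).
#' @param replicates Replicates per time point (default 1).
#' @param mu Growth rate (1/h).
#' @param seed Random seed.
#' @return Tibble with `gene`, `time_min`, `rpkm` and (for replicates > 1)
#'   `sd`; the generative `truth` is attached as an attribute.
#' @export
synth_expression <- function(truth, times, sigma = 0.05, replicates = 1L,
                             mu = 0.26, seed = 1L) {
  stopifnot(sigma >= 0, replicates >= 1)
  set.seed(seed)
  rows <- purrr::pmap(truth, function(gene, s_b, s_a, T_d, gamma, ...) {
    m <- mrna_solution(times, s_b, s_a, T_d, gamma, mu)
    reps <- matrix(pmax(0, m * (1 + stats::rnorm(length(m) * replicates,
                                                 sd = sigma))),
                   nrow = length(times))
    out <- tibble::tibble(gene = gene, time_min = times,
                          rpkm = rowMeans(reps))
    if (replicates > 1L) out$sd <- apply(reps, 1, stats::sd)
    out
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- truth
  out
}

#' Generate a differential-expression table with planted calls
#'
#' Builds a gene table in which exactly `n_pass` genes pass the
#' aerobic-shift thresholds (fold change 1.25, mean logCPM 2, FDR 0.05) and
#' the rest fail at least one criterion; the planted label is carried in
#' `planted_pass`.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_pass Number of genes planted to pass (0..n_genes).
#' @param seed Random seed.
#' @return Tibble with `gene`, `logFC`, `logCPM`, `FDR`, `planted_pass`.
#' @export
synth_de_table <- function(n_genes, n_pass = ceiling(n_genes / 3), seed = 1L) {
  stopifnot(n_genes >= 1, n_pass >= 0, n_pass <= n_genes)
  set.seed(seed)
  pass <- c(rep(TRUE, n_pass), rep(FALSE, n_genes - n_pass))
  lfc_pass <- function(n) sample(c(-1, 1), n, replace = TRUE) *
    stats::runif(n, log2(1.3), 3)
  tab <- tibble::tibble(
    gene = sprintf("g%03d", seq_len(n_genes)),
    logFC = ifelse(pass, lfc_pass(n_genes),
                   stats::runif(n_genes, -0.9, 0.9) *
                     log2(1.25) / 0.95),
    logCPM = ifelse(pass, stats::runif(n_genes, 2.5, 8),
                    stats::runif(n_genes, 2.5, 8)),
    FDR = ifelse(pass, stats::runif(n_genes, 0, 0.04),
                 stats::runif(n_genes, 0, 0.04)),
    planted_pass = pass)
  # failing genes break one randomly chosen criterion; logFC above already
  # fails for mode 1, the others get a passing logFC but a broken column
  fail_idx <- which(!pass)
  if (length(fail_idx) > 0L) {
    mode <- sample(1:3, length(fail_idx), replace = TRUE)
    fix_fc <- fail_idx[mode != 1L]
    tab$logFC[fix_fc] <- lfc_pass(length(fix_fc))
    low_cpm <- fail_idx[mode == 2L]
    tab$logCPM[low_cpm] <- stats::runif(length(low_cpm), -2, 1.9)
    hi_fdr <- fail_idx[mode == 3L]
    tab$FDR[hi_fdr] <- stats::runif(length(hi_fdr), 0.06, 1)
  }
  tab
}
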
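# Gene-expression dynamics: mRNA and protein balances, demand signal,
# and enzyme-capacity flux bounds.
#
# Unit conventions follow the parameter table: transcription rates s_b, s_a in
# RPKM/min and mRNA degradation gamma in 1/min (so mRNA is stepped in minutes),
# while growth mu is in 1/h, protein in mmol/gDCW and the protein synthesis
# rate s_P in mmol h^-1 RPKM^-1 gDCW^-1 (so protein is stepped in hours).
# Low-level step functions take explicitly suffixed rate/time arguments;
# user-facing functions take mu in 1/h, the scale growth rates are reported on.

#' Per-enzyme kinetics table
#'
#' Assembles the kinetic parameter table for the expression-balanced reactions:
#' one row per reaction, with the transcription parameters of its
#' rate-limiting (largest) subunit, the mRNA degradation rate, the derived
#' apparent gene length and protein synthesis rate, and the catalytic turnover
#' number.
#'
#' The protein synthesis rate defaults to `s_P = tau / Lambda_app`, with
#' `Lambda_app` the apparent gene length from [apparent_gene_length()]; an
#' explicit `s_P` column overrides the derivation.
#'
#' @param reaction,gene Reaction id and gene id of the largest subunit.
#' @param gene_length_bp Raw gene length (bp).
#' @param copies Copies of the subunit in the enzyme complex (default 1).
#' @param s_b,s_a Basal and activated transcription rates (RPKM/min).
#' @param gamma mRNA degradation rate (1/min).
#' @param kcat Turnover number; its numeric value scales protein level to the
#'   flux bound directly (see [flux_bound()]).
#' @param s_P Optional explicit protein synthesis rate
#'   (mmol h^-1 RPKM^-1 gDCW^-1); `NA` entries are derived from `tau`.
#' @param tau Translation constant (bp mmol h^-1 RPKM^-1 gDCW^-1, default 0.6).
#' @param spacing_bp Interribosomal spacing for the apparent length (default 72).
#' @return Tibble of class `ddd_kinetics` with derived columns `lambda_app`
#'   and `s_P`.
#' @export
enzyme_kinetics <- function(reaction, gene, gene_length_bp, copies = 1,
                            s_b, s_a, gamma, kcat, s_P = NA_real_,
                            tau = 0.6, spacing_bp = 72) {
  kin <- tibble::tibble(
    reaction = reaction, gene = gene,
    gene_length_bp = gene_length_bp,
    copies = rep_len(copies, length(reaction)),
    s_b = s_b, s_a = s_a, gamma = gamma, kcat = kcat,
    s_P = rep_len(s_P, length(reaction)))
  if (any(kin$s_b < 0 | kin$s_a < 0 | kin$gamma < 0 | kin$kcat < 0,
          na.rm = TRUE)) {
    stop("kinetic rates must be non-negative", call. = FALSE)
  }
  kin$lambda_app <- apparent_gene_length(kin$gene_length_bp, kin$copies,
                                         spacing_bp)
  derive <- is.na(kin$s_P)
  kin$s_P[derive] <- tau / kin$lambda_app[derive]
  attr(kin, "tau") <- tau
  attr(kin, "spacing_bp") <- spacing_bp
  class(kin) <- c("ddd_kinetics", class(kin))
  kin
}

#' Read an enzyme kinetics table
#'
#' Tab-separated file with header columns `reaction`, `gene`,
#' `gene_length_bp`, `copies` (optional), `s_b`, `s_a`, `gamma`, `kcat` and
#' optional `s_P` override.
#'
#' @param path File path.
#' @inheritParams enzyme_kinetics
#' @return A `ddd_kinetics` tibble.
#' @export
read_kinetics <- function(path, tau = 0.6, spacing_bp = 72) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("reaction", "gene", "gene_length_bp", "s_b", "s_a", "gamma", "kcat")
  if (!all(need %in% names(tab))) {
    stop("kinetics table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  enzyme_kinetics(
    reaction = tab$reaction, gene = tab$gene,
    gene_length_bp = tab$gene_length_bp,
    copies = tab$copies %||% 1,
    s_b = tab$s_b, s_a = tab$s_a, gamma = tab$gamma, kcat = tab$kcat,
    s_P = tab$s_P %||% NA_real_, tau = tau, spacing_bp = spacing_bp)
}

#' Write an enzyme kinetics table
#'
#' @param kinetics A `ddd_kinetics` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(kinetics, path) {
  readr::write_tsv(as.data.frame(kinetics), path)
  invisible(path)
}

#' Demand-driven regulatory signal
#'
#' Transcription of an enzyme is activated when the flux through its reaction
#' reaches the fraction `theta` of the current capacity bound:
#' `R = 1` iff `flux >= theta * bound` (inclusive at the boundary). Reversible
#' reactions are assessed on `|flux|` by the caller.
#'
#' @param flux Flux magnitude (>= 0, mmol h^-1 gDCW^-1).
#' @param bound Current capacity bound (>= 0).
#' @param theta Regulatory threshold in (0, 1]; default 0.6, reflecting that
#'   enzymes typically operate above half-saturation.
#' @return Integer 0/1 (vectorised).
#' @export
regulatory_signal <- function(flux, bound, theta = 0.6) {
  if (any(flux < 0) || any(bound < 0)) {
    stop("flux and bound must be non-negative (use |flux|)", call. = FALSE)
  }
  if (any(theta <= 0) || any(theta > 1)) {
    stop("theta must lie in (0, 1]", call. = FALSE)
  }
  as.integer(flux >= theta * bound)
}

#' One exact mRNA balance step
#'
#' Advances `d[mRNA]/dt = s_b + R * s_a - (mu + gamma) * [mRNA]` by `dt_min`
#' with `R` held constant, using the exact exponential update
#' `m' = m_ss + (m - m_ss) * exp(-(mu + gamma) dt)`,
#' `m_ss = (s_b + R s_a) / (mu + gamma)`. The degenerate case
#' `mu + gamma = 0` falls back to linear growth.
#'
#' @param m Current mRNA level (RPKM, vectorised).
#' @param R Regulatory signal 0/1, constant over the step.
#' @param s_b,s_a Basal and activated transcription rates (RPKM/min).
#' @param gamma mRNA degradation rate (1/min).
#' @param mu_min Growth rate in 1/min (i.e. mu[1/h] / 60).
#' @param dt_min Step length (min, > 0).
#' @return Updated mRNA level (RPKM).
#' @export
mrna_step <- function(m, R, s_b, s_a, gamma, mu_min, dt_min) {
  stopifnot(dt_min > 0)
  n <- max(length(m), length(R), length(s_b), length(s_a), length(gamma),
           length(mu_min))
  m <- rep_len(m, n); R <- rep_len(R, n)
  k <- rep_len(mu_min, n) + rep_len(gamma, n)
  synth <- rep_len(s_b, n) + R * rep_len(s_a, n)
  out <- m + synth * dt_min                     # degenerate mu + gamma = 0
  pos <- k > 0
  m_ss <- synth[pos] / k[pos]
  out[pos] <- m_ss + (m[pos] - m_ss) * exp(-k[pos] * dt_min)
  out
}

#' One exact protein balance step
#'
#' Advances `d[P]/dt = s_P * [mRNA] - mu * [P]` by `dt_h` with the mRNA level
#' held constant (protein degradation is negligible on this time scale; only
#' dilution removes protein): `p' = p_ss + (p - p_ss) * exp(-mu dt)` with
#' `p_ss = s_P m / mu`; at `mu = 0` the update is linear accumulation.
#'
#' @param p Current protein level (mmol/gDCW, vectorised).
#' @param m mRNA level (RPKM), constant over the step.
#' @param s_P Protein synthesis rate (mmol h^-1 RPKM^-1 gDCW^-1).
#' @param mu Growth rate (1/h).
#' @param dt_h Step length (h, > 0).
#' @return Updated protein level (mmol/gDCW).
#' @export
protein_step <- function(p, m, s_P, mu, dt_h) {
  stopifnot(dt_h > 0)
  n <- max(length(p), length(m), length(s_P), length(mu))
  p <- rep_len(p, n); m <- rep_len(m, n)
  s_P <- rep_len(s_P, n); mu <- rep_len(mu, n)
  out <- p + s_P * m * dt_h                     # mu = 0: pure accumulation
  pos <- mu > 0
  p_ss <- s_P[pos] * m[pos] / mu[pos]
  out[pos] <- p_ss + (p[pos] - p_ss) * exp(-mu[pos] * dt_h)
  out
}

#' Enzyme-capacity flux bound
#'
#' The upper flux bound of a balanced reaction is proportional to its
#' simulated protein level: `b = kcat * P`. The turnover number enters by its
#' numeric value (protein in mmol/gDCW, bound in mmol h^-1 gDCW^-1); with the
#' parameter table's RPKM-normalised protein levels this convention produces
#' bounds on the scale of realistic fluxes, whereas a literal per-second to
#' per-hour conversion would not. A different unit convention can be imposed
#' via `unit_factor`.
#'
#' @param kcat Turnover number (numeric value, >= 0).
#' @param protein Protein level (mmol/gDCW, >= 0).
#' @param unit_factor Multiplicative unit conversion (default 1).
#' @return Flux bound (mmol h^-1 gDCW^-1, vectorised).
#' @export
flux_bound <- function(kcat, protein, unit_factor = 1) {
  if (any(kcat < 0) || any(protein < 0)) {
    stop("kcat and protein must be non-negative", call. = FALSE)
  }
  kcat * protein * unit_factor
}

#' Steady-state expression of a balanced enzyme
#'
#' Equilibrium of the mRNA and protein balances at fixed regulatory signal:
#' `mRNA = (s_b + R s_a) / (mu/60 + gamma)` (RPKM; rates per minute) and
#' `protein = s_P * mRNA / mu` (mmol/gDCW; rates per hour). The anaerobic
#' basal state (`R = 0`, `mu = mu_anaerobic`) provides the t = 0 initial
#' condition of the aeration-shift simulation.
#'
#' @param kinetics A `ddd_kinetics` tibble.
#' @param mu Growth rate (1/h, > 0).
#' @param R Regulatory signal 0/1 (scalar or one per reaction).
#' @return Tibble with `reaction`, `mrna` (RPKM), `protein` (mmol/gDCW) and
#'   `bound` (mmol h^-1 gDCW^-1).
#' @export
steady_state_expression <- function(kinetics, mu, R = 0) {
  if (mu <= 0) stop("mu must be positive (protein steady state undefined)",
                    call. = FALSE)
  R <- rep_len(R, nrow(kinetics))
  mrna <- (kinetics$s_b + R * kinetics$s_a) / (mu / 60 + kinetics$gamma)
  protein <- kinetics$s_P * mrna / mu
  tibble::tibble(reaction = kinetics$reaction, mrna = mrna, protein = protein,
                 bound = flux_bound(kinetics$kcat, protein))
}
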
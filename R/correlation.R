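# Flux-versus-expression correlation: enzyme-set flux lumping, differential
# expression filtering, differential-flux calls and the rank correlation.

#' Aggregate subunit fold changes to a reaction-level fold change
#'
#' For an enzyme complex of several subunits the complex can change no more
#' than its least-changing subunit, so each isoenzyme contributes the
#' subunit log fold change of minimal magnitude (sign preserved); multiple
#' isoenzymes catalysing the same reaction contribute the arithmetic mean of
#' their values. `mode = "signed"` instead takes the minimal signed value
#' within each complex.
#'
#' @param logfc List of numeric vectors, one vector of subunit logFC values
#'   per isoenzyme (a single numeric vector is treated as one isoenzyme).
#' @param mode `"least-absolute"` (default) or `"signed"`.
#' @return Reaction-level log fold change (scalar).
#' @export
aggregate_fold_change <- function(logfc, mode = c("least-absolute", "signed")) {
  mode <- match.arg(mode)
  if (is.numeric(logfc)) logfc <- list(logfc)
  if (length(logfc) == 0L || any(vapply(logfc, length, integer(1)) == 0L)) {
    stop("need at least one isoenzyme, each with at least one subunit logFC",
         call. = FALSE)
  }
  per_iso <- vapply(logfc, function(x) {
    if (mode == "least-absolute") x[which.min(abs(x))] else min(x)
  }, numeric(1))
  mean(per_iso)
}

#' Reaction-level fold changes from a gene table and GPR rules
#'
#' Maps per-gene log fold changes onto reactions through their GPR rules:
#' each isoenzyme (OR branch) takes its least-absolute subunit value, and
#' isoenzymes are averaged ([aggregate_fold_change()]). Reactions with genes
#' missing from the table, or without genes, get `NA`.
#'
#' @param de Tibble with columns `gene` and `logFC`.
#' @param gpr Named character vector of GPR rules (names = reaction ids).
#' @param mode Passed to [aggregate_fold_change()].
#' @return Tibble with `reaction`, `logFC`.
#' @export
reaction_fold_changes <- function(de, gpr, mode = "least-absolute") {
  lfc <- stats::setNames(de$logFC, de$gene)
  out <- vapply(gpr, function(rule) {
    cxs <- gpr_complexes(rule)
    if (length(cxs) == 0L) return(NA_real_)
    vals <- lapply(cxs, function(g) lfc[g])
    if (any(vapply(vals, anyNA, logical(1)))) return(NA_real_)
    aggregate_fold_change(lapply(vals, unname), mode = mode)
  }, numeric(1))
  tibble::tibble(reaction = names(gpr), logFC = unname(out))
}

#' Filter a differential-expression table
#'
#' Keeps genes that pass all three thresholds: absolute fold change of at
#' least `min_fc` (i.e. `|logFC| >= log2(min_fc)`), mean logCPM of at least
#' `min_logcpm`, and FDR-adjusted p-value of at most `max_fdr`. The defaults
#' are the aerobic-shift analysis profile (fold change 1.25, logCPM 2,
#' FDR 0.05); `de_profile("strict")` gives the generic profile with fold
#' change 2.
#'
#' @param table Tibble with columns `gene`, `logFC`, `logCPM`, `FDR`.
#' @param min_fc Minimal fold change (linear scale, > 0).
#' @param min_logcpm Minimal mean logCPM.
#' @param max_fdr Maximal FDR-adjusted p-value.
#' @return The surviving rows of `table`.
#' @export
de_filter <- function(table, min_fc = 1.25, min_logcpm = 2, max_fdr = 0.05) {
  if (min_fc <= 0 || max_fdr < 0) stop("thresholds must be positive",
                                       call. = FALSE)
  keep <- abs(table$logFC) >= log2(min_fc) &
    table$logCPM >= min_logcpm &
    table$FDR <= max_fdr
  table[keep & !is.na(keep), ]
}

#' Named differential-expression threshold profiles
#'
#' @param name `"shift"` (fold change 1.25, logCPM 2, FDR 0.05) or
#'   `"strict"` (fold change 2, no logCPM floor, FDR 0.05).
#' @return List of thresholds for [de_filter()].
#' @export
de_profile <- function(name = c("shift", "strict")) {
  name <- match.arg(name)
  switch(name,
         shift = list(min_fc = 1.25, min_logcpm = 2, max_fdr = 0.05),
         strict = list(min_fc = 2, min_logcpm = -Inf, max_fdr = 0.05))
}

#' Lump fluxes by enzyme-set signature
#'
#' Sums absolute flux rates over reactions sharing the same enzyme set
#' (identical gene sets in the GPR, regardless of tree shape), so reactions
#' that differ only in cofactor usage are pooled; reactions without genes are
#' excluded.
#'
#' @param fluxes Tibble with columns `reaction`, `flux` (or a `ddd_flux`).
#' @param gpr Named character vector of GPR rules (names = reaction ids).
#' @return Tibble with `signature` (canonical gene-set string), `genes`
#'   (list column) and `flux_sum` (mmol h^-1 gDCW^-1).
#' @export
lump_fluxes <- function(fluxes, gpr) {
  if (inherits(fluxes, "ddd_flux")) fluxes <- fluxes$fluxes
  sig <- enzyme_signature(gpr[fluxes$reaction])
  keep <- !is.na(sig) & nzchar(sig)
  tibble::tibble(signature = sig[keep], flux = abs(fluxes$flux[keep])) |>
    dplyr::group_by(signature) |>
    dplyr::summarise(flux_sum = sum(flux), .groups = "drop") |>
    dplyr::mutate(genes = strsplit(signature, "|", fixed = TRUE),
                  .after = "signature")
}

#' Lump FVA intervals by enzyme-set signature
#'
#' Interval arithmetic companion of [lump_fluxes()]: the summed |flux| of a
#' lump ranges over the sum of the per-reaction |flux| ranges.
#'
#' @param fva_tab Tibble with `reaction`, `min`, `max` from [fva()].
#' @param gpr Named character vector of GPR rules.
#' @return Tibble with `signature`, `min`, `max` of the summed |flux|.
#' @export
lump_fva <- function(fva_tab, gpr) {
  sig <- enzyme_signature(gpr[fva_tab$reaction])
  keep <- !is.na(sig) & nzchar(sig)
  abs_lo <- pmax(pmax(fva_tab$min, -fva_tab$max), 0)  # min |v| over [min,max]
  abs_hi <- pmax(abs(fva_tab$min), abs(fva_tab$max))
  tibble::tibble(signature = sig[keep], lo = abs_lo[keep], hi = abs_hi[keep]) |>
    dplyr::group_by(signature) |>
    dplyr::summarise(min = sum(lo), max = sum(hi), .groups = "drop")
}

#' Differential-flux call for one enzyme set
#'
#' Two criteria identify a differential flux between conditions A and B: the
#' lumped flux difference must reach `min_diff` (0.25 mmol h^-1 gDCW^-1 by
#' default) and the flux-variability intervals of the two conditions must not
#' overlap (closed intervals; touching endpoints count as overlapping).
#' `criteria = "both"` (default) requires the conjunction, `"either"` accepts
#' one criterion alone.
#'
#' @param sum_a,sum_b Lumped |flux| sums under the two conditions.
#' @param fva_a,fva_b Length-2 numeric vectors `c(min, max)` of the lumped
#'   flux under each condition (`NULL` to skip the interval criterion).
#' @param min_diff Minimal flux difference.
#' @param criteria `"both"` or `"either"`.
#' @return Logical.
#' @export
differential_flux <- function(sum_a, sum_b, fva_a = NULL, fva_b = NULL,
                              min_diff = 0.25, criteria = c("both", "either")) {
  criteria <- match.arg(criteria)
  diff_ok <- abs(sum_a - sum_b) >= min_diff
  if (is.null(fva_a) || is.null(fva_b)) return(diff_ok)
  stopifnot(length(fva_a) == 2L, length(fva_b) == 2L,
            fva_a[1] <= fva_a[2], fva_b[1] <= fva_b[2])
  disjoint <- fva_a[2] < fva_b[1] || fva_b[2] < fva_a[1]
  if (criteria == "both") diff_ok && disjoint else diff_ok || disjoint
}

# exact permutation p-value for Spearman rho by full enumeration (no ties)
spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- all_permutations(n)
  rho_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlate flux differences with expression fold changes
#'
#' Spearman rank correlation of paired (flux difference, logFC) points with
#' an ordinary least-squares regression line and pointwise 95% confidence
#' band. The permutation p-value is exact (full enumeration over all
#' orderings) for n <= 8 points without ties; larger n (or ties) use the
#' t-approximation.
#'
#' @param points Tibble with columns `flux_diff` and `logFC` (extra columns
#'   such as identifiers are carried through).
#' @param exact_max Largest n for which the exact permutation p is computed.
#' @return Object of class `ddd_correlation` with `rho`, `p_value`,
#'   `p_method`, `slope`, `intercept`, `n`, the regression `fit`, and the
#'   input with fitted values and confidence band attached.
#' @export
correlate_flux_expression <- function(points, exact_max = 8L) {
  points <- tibble::as_tibble(points)
  if (!all(c("flux_diff", "logFC") %in% names(points))) {
    stop("points need columns flux_diff and logFC", call. = FALSE)
  }
  points <- points[stats::complete.cases(points[, c("flux_diff", "logFC")]), ]
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  x <- points$flux_diff; y <- points$logFC
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rho <- NA_real_; p <- NA_real_; method <- "undefined (constant input)"
  } else {
    rho <- stats::cor(rank(x), rank(y))
    has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    if (n <= exact_max && !has_ties) {
      p <- spearman_exact_p(x, y)
      method <- "exact permutation"
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      method <- "t-approximation"
    }
  }
  fit <- stats::lm(logFC ~ flux_diff, data = points)
  band <- stats::predict(fit, interval = "confidence", level = 0.95)
  points$fitted <- unname(band[, "fit"])
  points$conf_lo <- unname(band[, "lwr"])
  points$conf_hi <- unname(band[, "upr"])
  structure(list(rho = rho, p_value = p, p_method = method,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = n, fit = fit, points = points),
            class = "ddd_correlation")
}

#' @export
print.ddd_correlation <- function(x, ...) {
  cat("<ddd_correlation> n = ", x$n, ", Spearman rho = ",
      format(x$rho, digits = 3), ", p = ", format(x$p_value, digits = 3),
      " (", x$p_method, ")\n", sep = "")
  cat("  regression: logFC = ", format(x$intercept, digits = 3), " + ",
      format(x$slope, digits = 3), " * flux_diff\n", sep = "")
  invisible(x)
}

#' Tidy a flux-expression correlation
#'
#' @param x A `ddd_correlation`.
#' @param ... Unused.
#' @return The paired points with fitted values and confidence band.
#' @export
tidy.ddd_correlation <- function(x, ...) x$points

#' One-row correlation summary
#'
#' @param x A `ddd_correlation`.
#' @param ... Unused.
#' @return Tibble with `rho`, `p_value`, `p_method`, `slope`, `intercept`, `n`.
#' @export
glance.ddd_correlation <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, p_method = x$p_method,
                 slope = x$slope, intercept = x$intercept, n = x$n)
}

#' Full correlation pipeline from tables
#'
#' Convenience wrapper reproducing the flux-versus-transcript analysis: lump
#' fluxes of both conditions by enzyme set, call differential fluxes (flux
#' difference plus disjoint FVA intervals when supplied), map filtered gene
#' fold changes to enzyme sets, and correlate the lumped flux differences of
#' the differential enzyme sets with their fold changes.
#'
#' @param de Tibble with `gene`, `logFC`, `logCPM`, `FDR`.
#' @param flux_a,flux_b Tibbles with `reaction`, `flux` for conditions A
#'   (reference) and B.
#' @param gpr Named character vector of GPR rules.
#' @param fva_a,fva_b Optional FVA tibbles (`reaction`, `min`, `max`).
#' @param thresholds DE thresholds, see [de_profile()].
#' @param min_diff Minimal lumped flux difference.
#' @param criteria Differential-flux rule, `"both"` or `"either"`.
#' @return A `ddd_correlation`.
#' @export
flux_expression_report <- function(de, flux_a, flux_b, gpr,
                                   fva_a = NULL, fva_b = NULL,
                                   thresholds = de_profile("shift"),
                                   min_diff = 0.25,
                                   criteria = c("both", "either")) {
  criteria <- match.arg(criteria)
  de_kept <- de_filter(de, thresholds$min_fc, thresholds$min_logcpm,
                       thresholds$max_fdr)
  lump_a <- lump_fluxes(flux_a, gpr)
  lump_b <- lump_fluxes(flux_b, gpr)
  lumped <- dplyr::full_join(
    dplyr::select(lump_a, signature, sum_a = flux_sum),
    dplyr::select(lump_b, signature, sum_b = flux_sum), by = "signature") |>
    tidyr::replace_na(list(sum_a = 0, sum_b = 0))
  iv_a <- if (!is.null(fva_a)) lump_fva(fva_a, gpr) else NULL
  iv_b <- if (!is.null(fva_b)) lump_fva(fva_b, gpr) else NULL
  is_diff <- vapply(seq_len(nrow(lumped)), function(i) {
    sig <- lumped$signature[i]
    a_iv <- if (!is.null(iv_a)) unlist(iv_a[iv_a$signature == sig,
                                            c("min", "max")]) else NULL
    b_iv <- if (!is.null(iv_b)) unlist(iv_b[iv_b$signature == sig,
                                            c("min", "max")]) else NULL
    if (!is.null(a_iv) && length(a_iv) == 0L) a_iv <- NULL
    if (!is.null(b_iv) && length(b_iv) == 0L) b_iv <- NULL
    differential_flux(lumped$sum_a[i], lumped$sum_b[i], a_iv, b_iv,
                      min_diff = min_diff, criteria = criteria)
  }, logical(1))
  # reaction-level fold changes restricted to filtered genes
  rx_fc <- reaction_fold_changes(de_kept, gpr)
  rx_fc$signature <- enzyme_signature(gpr[rx_fc$reaction])
  sig_fc <- rx_fc |>
    dplyr::filter(!is.na(logFC), nzchar(signature)) |>
    dplyr::distinct(signature, logFC)
  pts <- lumped[is_diff, ] |>
    dplyr::inner_join(sig_fc, by = "signature") |>
    dplyr::mutate(flux_diff = sum_b - sum_a) |>
    dplyr::select(signature, flux_diff, logFC)
  correlate_flux_expression(pts)
}
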
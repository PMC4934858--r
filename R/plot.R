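# ggplot2 methods for trajectories, fits and correlation reports.

#' Plot a demand-directed dFBA trajectory
#'
#' Faceted time courses of the balanced reactions: parsimonious flux and its
#' capacity bound (dashed) on one row, simulated mRNA on the other; the FVA
#' envelope is shaded when the trajectory carries it.
#'
#' @param object A `ddd_trajectory`.
#' @param reactions Balanced reactions to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddd_trajectory <- function(object, reactions = NULL, ...) {
  expr <- object$expression
  if (!is.null(reactions)) expr <- dplyr::filter(expr, reaction %in% reactions)
  flux_panel <- expr |>
    dplyr::transmute(time_min, reaction, panel = "flux [mmol/h/gDCW]",
                     value = abs(flux), bound = bound)
  mrna_panel <- expr |>
    dplyr::transmute(time_min, reaction, panel = "mRNA [RPKM]",
                     value = mrna, bound = NA_real_)
  dat <- dplyr::bind_rows(flux_panel, mrna_panel)
  p <- ggplot2::ggplot(dat, ggplot2::aes(time_min, value))
  if (!is.null(object$fva)) {
    fva_dat <- object$fva |>
      dplyr::filter(if (is.null(reactions)) TRUE else reaction %in% reactions) |>
      dplyr::mutate(panel = "flux [mmol/h/gDCW]")
    p <- p + ggplot2::geom_ribbon(
      data = fva_dat,
      ggplot2::aes(time_min, ymin = pmax(.data$min, 0), ymax = .data$max),
      inherit.aes = FALSE, alpha = 0.2)
  }
  p +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_line(ggplot2::aes(y = bound), linetype = "dashed",
                       colour = "darkgreen", na.rm = TRUE) +
    ggplot2::facet_grid(panel ~ reaction, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$config$t_aer_min,
                        linetype = "dotted") +
    ggplot2::labs(x = "time [min]", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot an RPKM time-course fit
#'
#' @param object A `ddd_fit` from [fit_activation()].
#' @param ... Unused.
#' @return A ggplot object: data points (with error bars when replicate SDs
#'   are present) and the fitted delayed-activation model curve.
#' @export
autoplot.ddd_fit <- function(object, ...) {
  ser <- object$series
  grid <- tibble::tibble(
    time_min = seq(min(ser$time_min), max(ser$time_min), length.out = 200))
  grid$rpkm <- mrna_solution(grid$time_min, object$s_b, object$s_a,
                             object$T_d %||% 0, object$gamma, object$mu)
  p <- ggplot2::ggplot(ser, ggplot2::aes(time_min, rpkm)) +
    ggplot2::geom_point(colour = "steelblue")
  if ("sd" %in% names(ser)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = rpkm - sd, ymax = rpkm + sd),
      width = 0, colour = "steelblue")
  }
  p +
    ggplot2::geom_line(data = grid, colour = "grey30") +
    ggplot2::labs(x = "time [min]", y = "mRNA [RPKM]") +
    ggplot2::theme_bw()
}

#' Plot a flux-expression correlation
#'
#' Scatter of transcript log fold change against lumped flux difference with
#' the least-squares line and its 95% confidence band.
#'
#' @param object A `ddd_correlation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddd_correlation <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(flux_diff, logFC)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = conf_lo, ymax = conf_hi),
                         fill = "red", alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = fitted), colour = "black") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "flux difference [mmol/h/gDCW]",
                  y = "transcript logFC",
                  subtitle = sprintf("Spearman rho = %.2f, p = %.3g (%s)",
                                     object$rho, object$p_value,
                                     object$p_method)) +
    ggplot2::theme_bw()
}
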
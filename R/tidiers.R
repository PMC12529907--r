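#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a splay-angle PMF fit
#'
#' Transformed histogram points against `S^2` with the fitted lines of the
#' five windows; the reported +/- 1 sigma fit is drawn solid.
#'
#' @param object A `kappa_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.kappa_fit <- function(object, ...) {
  h <- object$histogram
  a_nm <- object$area_A2 / AA_PER_NM2
  pts <- dplyr::filter(tibble(s2 = h$mid^2,
                              y = -(2 / a_nm) * log(h$density),
                              ok = h$density > 0), .data$ok)
  wins <- dplyr::mutate(object$windows,
                        label = sprintf("%.2f sigma", .data$half_width_sigma))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$s2, y = .data$y)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(
      data = wins,
      ggplot2::aes(slope = .data$kappa, intercept = .data$intercept,
                   colour = .data$label,
                   linetype = .data$half_width_sigma == min(.data$half_width_sigma))
    ) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = expression(S^2 ~ (rad^2)),
                  y = expression(-2 * k[B] * T / A[L] %*% ln ~ P(S)),
                  colour = "fit window",
                  title = sprintf("kappa = %.1f +/- %.1f kBT",
                                  object$kappa, object$kappa_std)) +
    ggplot2::theme_minimal()
}

#' Plot a property estimate's blocks
#'
#' @param object A `prop_estimate`.
#' @param ... Ignored.
#' @return A ggplot of block values with the aggregate mean line.
#' @export
autoplot.prop_estimate <- function(object, ...) {
  ggplot2::ggplot(object$blocks,
                  ggplot2::aes(x = .data$block, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$value, linetype = "dashed") +
    ggplot2::labs(x = "block", y = paste0(object$property, " (", object$units, ")"),
                  title = sprintf("%s = %.2f +/- %.2f %s", object$property,
                                  object$value, object$std, object$units)) +
    ggplot2::theme_minimal()
}

#' Plot a PSO convergence history
#'
#' @param object A `pso_fit`.
#' @param ... Ignored.
#' @return A ggplot of the global-best objective per iteration.
#' @export
autoplot.pso_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$gbest)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "global-best objective") +
    ggplot2::theme_minimal()
}

#' Heatmap of partial correlation coefficients
#'
#' Parameter-by-property PCC heatmap; cells with `|PCC|` above the
#' annotation threshold show their value (the conventional presentation
#' filter, not a statistic).
#'
#' @param pcc Long tibble with `parameter`, `property`, `pcc` (as returned
#'   by [sensitivity_analysis()]).
#' @param annotate_above Absolute PCC threshold for cell labels (default
#'   0.2).
#' @return A ggplot.
#' @export
plot_pcc_heatmap <- function(pcc, annotate_above = 0.2) {
  pcc <- dplyr::mutate(pcc, label = ifelse(abs(.data$pcc) > annotate_above,
                                           sprintf("%.2f", .data$pcc), ""))
  ggplot2::ggplot(pcc, ggplot2::aes(x = .data$property, y = .data$parameter,
                                    fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC") +
    ggplot2::theme_minimal()
}
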
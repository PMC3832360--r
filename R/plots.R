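#' Plot the fitted variance and correlation functions of a GxE fit
#'
#' Two panels: genetic and environmental variance against the environmental
#' index (standardized TDEE), and the genetic correlation against the
#' pairwise environmental difference — the standard way a continuous GxE
#' analysis is displayed.
#'
#' @param object A `gxee_fit`.
#' @param q_grid,dq_grid Evaluation grids (see [evaluate_functions()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gxee_fit
#' @export
autoplot.gxee_fit <- function(object, q_grid = seq(-2, 2, by = 0.05),
                              dq_grid = seq(0, 4, by = 0.05), ...) {
  funs <- evaluate_functions(object, q_grid = q_grid, dq_grid = dq_grid)
  d <- dplyr::bind_rows(
    funs$variance |>
      tidyr::pivot_longer(c("sigma2_g", "sigma2_e"),
                          names_to = "curve", values_to = "value") |>
      dplyr::mutate(x = .data$q, panel = "variance vs TDEE (z)"),
    funs$correlation |>
      dplyr::transmute(x = .data$dq, value = .data$rho_g, curve = "rho_g",
                       panel = "genetic correlation vs |dTDEE| (z)")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value,
                                  colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot heritability estimates of a study report
#'
#' Point estimates with truncated Wald 95% intervals, one row per trait.
#'
#' @param report A [run_study()] result.
#' @return A ggplot object.
#' @export
plot_heritability <- function(report) {
  stopifnot(inherits(report, "study_report"))
  ggplot2::ggplot(report$heritability,
                  ggplot2::aes(x = .data$h2, y = .data$trait)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = expression(h^2), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the genetic covariance surface of a GxE fit
#'
#' The covariance between a fully related pair (`2Phi = 1`) as a joint
#' function of one member's environment and the pairwise difference.
#'
#' @param fit A `gxee_fit`.
#' @inheritParams autoplot.gxee_fit
#' @return A ggplot object.
#' @export
plot_covariance_surface <- function(fit, q_grid = seq(-2, 2, by = 0.1),
                                    dq_grid = seq(0, 4, by = 0.1)) {
  funs <- evaluate_functions(fit, q_grid = q_grid, dq_grid = dq_grid)
  ggplot2::ggplot(funs$covariance,
                  ggplot2::aes(x = .data$q, y = .data$dq, fill = .data$cov_g)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "TDEE (z)", y = "|pairwise TDEE difference| (z)",
                  fill = "genetic cov") +
    ggplot2::theme_minimal()
}
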
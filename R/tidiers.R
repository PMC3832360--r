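#' Tidy a polygenic fit
#'
#' @param x A `polygenic_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy polygenic_fit
#' @export
tidy.polygenic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "sigma2_g", "sigma2_e", "h2"),
    estimate = c(x$mu, x$sigma2_g, x$sigma2_e, x$h2),
    std.error = c(NA, NA, NA, x$se_h2)
  )
}

#' @rdname tidy.polygenic_fit
#' @method glance polygenic_fit
#' @export
glance.polygenic_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se_h2 = x$se_h2, logLik = x$loglik,
                 logLik_sporadic = x$loglik_sporadic,
                 nobs = x$n, n_families = x$n_families, converged = x$converged)
}

#' Tidy a GxE fit
#'
#' Slopes and the decay rate are estimated per unit of standardized TDEE;
#' when the fit knows the raw-TDEE standard deviation, they are also reported
#' per 1000 kcal/day in `estimate_per_1000kcal`.
#'
#' @param x A `gxee_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `constrained`,
#'   `estimate_per_1000kcal`.
#' @method tidy gxee_fit
#' @export
tidy.gxee_fit <- function(x, ...) {
  p <- x$params
  terms <- c("mu", "alpha_g", "gamma_g", "lambda", "alpha_e", "gamma_e")
  est <- c(p$mu, p$alpha_g, p$gamma_g, p$lam, p$alpha_e, p$gamma_e)
  scales_with_q <- terms %in% c("gamma_g", "lambda", "gamma_e")
  rescale <- rep(NA_real_, length(terms))
  if (!is.na(x$q_scale)) rescale[scales_with_q] <- est[scales_with_q] / x$q_scale * 1000
  tibble::tibble(
    term = terms, estimate = est,
    constrained = terms %in% x$constrained,
    estimate_per_1000kcal = rescale
  )
}

#' @rdname tidy.gxee_fit
#' @method glance gxee_fit
#' @export
glance.gxee_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, n_families = x$n_families,
                 converged = x$converged,
                 constrained = paste(x$constrained, collapse = ","))
}

#' Tidy an LRT result
#'
#' @param x An `lrt_result`.
#' @param ... Unused.
#' @return One row: `contrast`, `statistic`, `p.value`, `null`.
#' @method tidy lrt_result
#' @export
tidy.lrt_result <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast, statistic = x$statistic, p.value = x$p,
    null = paste(sprintf("%g*chi2_%d", x$null$weights, x$null$dfs), collapse = "+"),
    logLik_full = x$loglik_full, logLik_reduced = x$loglik_reduced
  )
}
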
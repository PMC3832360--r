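#' Mixture chi-square null distribution
#'
#' Likelihood-ratio statistics for hypotheses that pin parameters to the
#' boundary of their space (a variance at 0, a decay rate at 0) are not
#' chi-square distributed: their null is a weighted mixture of chi-squares,
#' possibly including a point mass at zero (df = 0).
#'
#' @param weights Positive weights summing to 1.
#' @param dfs Integer degrees of freedom, `0` meaning a point mass at zero.
#' @return Object of class `mixture_chisq`.
#' @export
mixture_chisq <- function(weights, dfs) {
  if (length(weights) != length(dfs) || length(weights) == 0) {
    abort("weights and dfs must be non-empty and aligned")
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-12) {
    abort("weights must be positive and sum to 1")
  }
  if (any(dfs != round(dfs)) || any(dfs < 0)) abort("dfs must be non-negative integers")
  structure(list(weights = as.numeric(weights), dfs = as.integer(dfs)),
            class = "mixture_chisq")
}

#' Survival function of a mixture chi-square
#'
#' `P(T > t) = sum_k w_k P(chi2_{df_k} > t)`, where a df = 0 component
#' contributes 0 for `t > 0` and 1 at `t = 0` (so the p-value at a zero
#' statistic is 1).
#'
#' @param t Statistic value(s), >= 0.
#' @param null A [mixture_chisq()].
#' @return p-value(s) in `[0, 1]`.
#' @export
mixture_sf <- function(t, null) {
  if (!inherits(null, "mixture_chisq")) abort("null must be a mixture_chisq")
  if (any(t < 0)) abort("statistic must be >= 0")
  vapply(t, function(ti) {
    sum(purrr::map2_dbl(null$weights, null$dfs, function(w, df) {
      if (df == 0L) w * as.numeric(ti <= 0) else w * pchisq(ti, df, lower.tail = FALSE)
    }))
  }, numeric(1))
}

#' Likelihood-ratio statistic
#'
#' `T = 2 * (logLik_full - logLik_reduced)`. Tiny negative differences (up to
#' 1e-6) are numerical noise from the optimizer and clamped to 0; anything
#' larger means the full-model optimizer failed to dominate its own submodel
#' and is an error, not a statistic.
#'
#' @param loglik_full,loglik_reduced Maximized log-likelihoods.
#' @return Non-negative statistic.
#' @export
lrt_statistic <- function(loglik_full, loglik_reduced) {
  t <- 2 * (loglik_full - loglik_reduced)
  if (t < -1e-6) {
    abort(paste0("full-model log-likelihood is below the reduced model by ",
                 format(-t / 2), ": optimizer failure"))
  }
  max(t, 0)
}

#' Null distributions for the standard model contrasts
#'
#' * `variance_homogeneity` (`gamma_g = 0`): interior parameter, plain
#'   chi-square with 1 df.
#' * `genetic_correlation_one` (`lambda = 0`): boundary parameter, 50:50
#'   mixture of a point mass at 0 and chi-square 1.
#' * `full_vs_polygenic` (`gamma_g = gamma_e = lambda = 0`): three parameters
#'   of which one (`lambda`) is on the boundary, 50:50 mixture of chi-square
#'   2 and chi-square 3.
#' * `h2_zero` (`sigma2_g = 0`): boundary variance, 50:50 mixture of a point
#'   mass at 0 and chi-square 1.
#'
#' @param contrast Optional single contrast name; if omitted, the full
#'   mapping is returned.
#' @return A named list of [mixture_chisq()] objects, or a single one.
#' @export
standard_contrasts <- function(contrast = NULL) {
  all <- list(
    variance_homogeneity = mixture_chisq(1, 1L),
    genetic_correlation_one = mixture_chisq(c(0.5, 0.5), c(0L, 1L)),
    full_vs_polygenic = mixture_chisq(c(0.5, 0.5), c(2L, 3L)),
    h2_zero = mixture_chisq(c(0.5, 0.5), c(0L, 1L))
  )
  if (is.null(contrast)) return(all)
  if (!contrast %in% names(all)) {
    abort(paste0("unknown contrast '", contrast, "'; available: ",
                 paste(names(all), collapse = ", ")))
  }
  all[[contrast]]
}

#' Likelihood-ratio test under a mixture chi-square null
#'
#' @inheritParams lrt_statistic
#' @param contrast A contrast name from [standard_contrasts()], or a
#'   [mixture_chisq()] to use directly.
#' @param name Label for the result (defaults to the contrast name).
#' @return Object of class `lrt_result`: `contrast`, `statistic`, `p`,
#'   `null`, `loglik_full`, `loglik_reduced`.
#' @export
lrt_test <- function(loglik_full, loglik_reduced, contrast, name = NULL) {
  null <- if (inherits(contrast, "mixture_chisq")) contrast else standard_contrasts(contrast)
  t <- lrt_statistic(loglik_full, loglik_reduced)
  structure(list(
    contrast = name %||% (if (is.character(contrast)) contrast else "custom"),
    statistic = t,
    p = mixture_sf(t, null),
    null = null,
    loglik_full = loglik_full,
    loglik_reduced = loglik_reduced
  ), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  comp <- paste(sprintf("%.2f*chi2_%d", x$null$weights, x$null$dfs), collapse = " + ")
  cat(sprintf("LRT [%s]: T = %.3f, null = %s, p = %.4g\n",
              x$contrast, x$statistic, comp, x$p))
  invisible(x)
}
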
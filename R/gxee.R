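align_q <- function(q, ids) {
  if (is.data.frame(q)) {
    if (!all(c("individual_id", "q") %in% names(q))) {
      abort("q table must have columns individual_id and q (see standardize_tdee)")
    }
    qs <- attr(q, "scale")
    q <- setNames(q$q, q$individual_id)
    attr(q, "scale") <- qs
  }
  if (is.null(names(q))) {
    if (length(q) != length(ids)) abort("unnamed q must align with scores")
    names(q) <- ids
  }
  miss <- setdiff(ids, names(q))
  if (length(miss) > 0) {
    abort(paste0("no environmental value (q) for: ", paste(head(miss, 5), collapse = ", ")))
  }
  out <- unname(q[ids])
  if (anyNA(out) || any(!is.finite(out))) abort("q must be finite for all scored individuals")
  out
}

#' GxE model log-likelihood
#'
#' Gaussian log-likelihood of trait scores under the continuous
#' genotype-by-environment model (see [gxee_params()] and
#' [gxee_covariance()]), summed over independent family blocks.
#'
#' @param params A [gxee_params()] object.
#' @param scores Tibble `individual_id`, `score`.
#' @param q Environmental index: output of [standardize_tdee()], or a named
#'   (by id) or scores-aligned numeric vector.
#' @param rel Relationship matrix from [kinship_matrix()].
#' @param families Pedigree or named id -> family vector.
#' @return Scalar log-likelihood.
#' @export
gxee_loglik <- function(params, scores, q, rel, families) {
  stopifnot(inherits(params, "gxee_params"))
  b <- build_blocks(scores, rel, families)
  qv <- align_q(q, b$ids)
  ll <- cpp_gxee_loglik(b$y, qv, b$phis, b$idx, params$mu, params$alpha_g,
                        params$gamma_g, params$lam, params$alpha_e, params$gamma_e)
  if (!is.finite(ll)) abort("GxE likelihood is not finite at these parameters")
  ll
}

#' Fit the continuous GxE interaction model
#'
#' Maximum-likelihood fit of `(mu, alpha_g, gamma_g, lambda, alpha_e,
#' gamma_e)` by bounded multi-start quasi-Newton (`L-BFGS-B`), with `lambda`
#' box-constrained at 0 so the no-decay boundary is reachable. A coarse grid
#' of starts (two heritability splits for the intercepts; slopes in
#' `{-0.5, 0, 0.5}`; decay in `{0, 0.1, 1}`) is screened by likelihood and
#' the best few refined. Constrained submodels freeze the named parameters at
#' 0, which is how the polygenic model (`gamma_g = gamma_e = lambda = 0`) and
#' the single-hypothesis submodels are fitted.
#'
#' @inheritParams gxee_loglik
#' @param constraints Character vector of parameters frozen at 0: any subset
#'   of `c("gamma_g", "gamma_e", "lambda")`.
#' @param extra_starts Optional list of [gxee_params()] used as additional
#'   refinement starts (e.g. a reduced-model solution when enforcing that the
#'   full model dominates its submodels).
#' @param n_refine How many screened starts to refine fully.
#' @return Object of class `gxee_fit`: `params` ([gxee_params()]), `loglik`,
#'   `converged`, `constrained`, `n`, `n_families`, `q_scale` (SD of raw TDEE
#'   when `q` came from [standardize_tdee()], else `NA`).
#' @export
fit_gxee <- function(scores, q, rel, families, constraints = character(0),
                     extra_starts = NULL, n_refine = 3) {
  if (length(constraints) > 0) {
    constraints <- match.arg(constraints, c("gamma_g", "gamma_e", "lambda"),
                             several.ok = TRUE)
  }
  b <- build_blocks(scores, rel, families)
  q_scale <- if (is.data.frame(q)) attr(q, "scale") %||% NA_real_ else NA_real_
  qv <- align_q(q, b$ids)
  if (length(unique(qv)) < 2) abort("q is constant: the interaction model is unidentifiable")
  fam_sizes <- lengths(b$idx)
  if (sum(fam_sizes >= 2) < 2) {
    abort("need at least 2 families with at least 2 phenotyped relatives")
  }
  vtot <- var(b$y)
  mu0 <- mean(b$y)

  # full parameter order: (mu, alpha_g, gamma_g, lam, alpha_e, gamma_e)
  free <- c(TRUE, TRUE, !("gamma_g" %in% constraints), !("lambda" %in% constraints),
            TRUE, !("gamma_e" %in% constraints))
  lower_all <- c(-Inf, log(vtot) - 25, -10, 0, log(vtot) - 25, -10)
  upper_all <- c(Inf, log(vtot) + 10, 10, 50, log(vtot) + 10, 10)

  negll_full <- function(theta) {
    ll <- cpp_gxee_loglik(b$y, qv, b$phis, b$idx, theta[1], theta[2], theta[3],
                          theta[4], theta[5], theta[6])
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  negll <- function(par) {
    theta <- numeric(6)
    theta[free] <- par
    negll_full(theta)
  }

  gg_starts <- if (free[3]) c(-0.5, 0, 0.5) else 0
  lam_starts <- if (free[4]) c(0, 0.1, 1) else 0
  grid <- tidyr::expand_grid(h2s = c(0.2, 0.5), gg = gg_starts, lam = lam_starts)
  starts <- purrr::pmap(grid, function(h2s, gg, lam) {
    c(mu0, log(h2s * vtot), gg, lam, log((1 - h2s) * vtot), 0)
  })
  for (ex in extra_starts %||% list()) {
    stopifnot(inherits(ex, "gxee_params"))
    starts <- c(starts, list(pmin(pmax(
      c(ex$mu, ex$alpha_g, ex$gamma_g, ex$lam, ex$alpha_e, ex$gamma_e),
      lower_all + 1e-9), upper_all - 1e-9)))
  }
  vals <- vapply(starts, negll_full, numeric(1))
  n_extra <- length(extra_starts %||% list())
  keep <- unique(c(order(vals)[seq_len(min(n_refine, length(starts)))],
                   if (n_extra > 0) length(starts) - seq_len(n_extra) + 1))

  best <- NULL
  for (k in keep) {
    par0 <- starts[[k]][free]
    opt <- optim(par0, negll, method = "L-BFGS-B",
                 lower = lower_all[free], upper = upper_all[free],
                 control = list(factr = 1e6, maxit = 1000, ndeps = rep(1e-5, sum(free))))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- numeric(6)
  theta[free] <- best$par
  params <- gxee_params(mu = theta[1], alpha_g = theta[2], gamma_g = theta[3],
                        lam = theta[4], alpha_e = theta[5], gamma_e = theta[6])
  structure(list(
    params = params, loglik = -best$value, converged = best$convergence == 0,
    constrained = constraints, n = b$n, n_families = b$n_families,
    q_scale = q_scale
  ), class = "gxee_fit")
}

#' @export
print.gxee_fit <- function(x, ...) {
  p <- x$params
  cat("Continuous GxE variance-components fit\n")
  if (length(x$constrained) > 0) {
    cat("  constrained at 0:", paste(x$constrained, collapse = ", "), "\n")
  }
  cat(sprintf("  n = %d individuals in %d families\n", x$n, x$n_families))
  cat(sprintf("  alpha_g = %.4f, gamma_g = %.4f, lambda = %.4f\n",
              p$alpha_g, p$gamma_g, p$lam))
  cat(sprintf("  alpha_e = %.4f, gamma_e = %.4f, mu = %.4f\n",
              p$alpha_e, p$gamma_e, p$mu))
  cat(sprintf("  logLik = %.3f%s\n", x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
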
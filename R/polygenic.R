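# Shared plumbing: align a score table with the relationship matrix and
# partition it into per-family blocks for the C++ likelihoods.

family_map <- function(families) {
  if (inherits(families, "fam_pedigree") || is.data.frame(families)) {
    setNames(as.character(families$family_id), families$individual_id)
  } else if (!is.null(names(families))) {
    setNames(as.character(families), names(families))
  } else {
    abort("families must be a pedigree or a named id -> family vector")
  }
}

build_blocks <- function(scores, rel, families, q = NULL) {
  fmap <- family_map(families)
  ids <- as.character(scores$individual_id)
  missing_rel <- setdiff(ids, rownames(rel))
  if (length(missing_rel) > 0) {
    abort(paste0("phenotyped individuals absent from the pedigree/relationship matrix: ",
                 paste(head(missing_rel, 5), collapse = ", "),
                 if (length(missing_rel) > 5) ", ..." else ""))
  }
  missing_fam <- setdiff(ids, names(fmap))
  if (length(missing_fam) > 0) {
    abort(paste0("no family assignment for: ", paste(head(missing_fam, 5), collapse = ", ")))
  }
  y <- as.numeric(scores$score)
  if (anyNA(y)) abort("scores must be complete; drop missing values upstream")
  fam <- unname(fmap[ids])
  idx <- split(seq_along(ids), fam)
  phis <- lapply(idx, function(ii) rel[ids[ii], ids[ii], drop = FALSE])
  list(y = y, ids = ids, idx = idx, phis = phis,
       q = if (!is.null(q)) as.numeric(q) else NULL,
       n = length(y), n_families = length(idx))
}

#' Polygenic model log-likelihood
#'
#' Exact Gaussian log-likelihood of trait scores under the polygenic
#' variance-components model: within each family the scores are multivariate
#' normal with mean `mu` and covariance `Omega = 2Phi sigma2_g + I sigma2_e`;
#' families are independent, so the total is the sum of family block
#' log-densities (singleton families contribute univariate normal terms).
#'
#' @param params List with `mu`, `sigma2_g` (>= 0), `sigma2_e` (> 0).
#' @param scores Tibble `individual_id`, `score` (from [prepare_trait()]).
#' @param rel Relationship matrix from [kinship_matrix()].
#' @param families Pedigree (or named id -> family vector) giving family
#'   membership.
#' @return Scalar log-likelihood.
#' @export
polygenic_loglik <- function(params, scores, rel, families) {
  if (params$sigma2_e <= 0) abort("sigma2_e must be > 0")
  if (params$sigma2_g < 0) abort("sigma2_g must be >= 0")
  b <- build_blocks(scores, rel, families)
  ll <- cpp_polygenic_loglik(b$y, b$phis, b$idx, params$mu, params$sigma2_g, params$sigma2_e)
  if (!is.finite(ll)) {
    abort("polygenic likelihood is not finite: a family covariance block failed to factor")
  }
  ll
}

# ML fit of the iid ("sporadic", sigma2_g = 0) model: closed form.
sporadic_fit <- function(y) {
  n <- length(y)
  mu <- mean(y)
  s2 <- sum((y - mu)^2) / n
  list(mu = mu, sigma2_e = s2, loglik = -0.5 * n * (log(2 * pi * s2) + 1))
}

#' Fit the polygenic variance-components model
#'
#' Maximum-likelihood estimation of `(mu, sigma2_g, sigma2_e)` by bounded
#' quasi-Newton (`L-BFGS-B`) on the parameterization
#' `(mu, log sigma2_e, sigma2_g)` with `sigma2_g` box-constrained at 0, so
#' the no-heritability boundary is reachable. Three starts (heritability 0.1,
#' 0.4, 0.7 of the sample variance) are refined and the best likelihood kept.
#' The standard error of `h2 = sigma2_g / (sigma2_g + sigma2_e)` comes from
#' the inverse observed information via the delta method (reported `NA` when
#' `sigma2_g` sits on the boundary, where the Wald theory fails).
#'
#' @inheritParams polygenic_loglik
#' @param starts Heritability fractions used to initialize the variance split.
#' @return Object of class `polygenic_fit`: `sigma2_g`, `sigma2_e`, `h2`,
#'   `se_h2`, `mu`, `loglik`, `loglik_sporadic`, `n`, `n_families`,
#'   `converged`.
#' @export
fit_polygenic <- function(scores, rel, families, starts = c(0.1, 0.4, 0.7)) {
  b <- build_blocks(scores, rel, families)
  fam_sizes <- lengths(b$idx)
  if (sum(fam_sizes >= 2) < 2) {
    abort("need at least 2 families with at least 2 phenotyped relatives to identify h2")
  }
  vtot <- var(b$y)
  mu0 <- mean(b$y)

  negll <- function(par) {
    # par = (mu, log sigma2_e, sigma2_g)
    ll <- cpp_polygenic_loglik(b$y, b$phis, b$idx, par[1], par[3], exp(par[2]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  for (h2s in starts) {
    par0 <- c(mu0, log((1 - h2s) * vtot), h2s * vtot)
    opt <- optim(par0, negll, method = "L-BFGS-B",
                 lower = c(-Inf, log(vtot) - 20, 0),
                 upper = c(Inf, log(vtot) + 20, Inf),
                 control = list(factr = 1e6, maxit = 500, ndeps = rep(1e-5, 3)))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  mu <- best$par[1]
  s2e <- exp(best$par[2])
  s2g <- best$par[3]
  h2 <- s2g / (s2g + s2e)
  spor <- sporadic_fit(b$y)

  se_h2 <- NA_real_
  if (s2g > 1e-8) {
    nll_nat <- function(p) {
      if (p[2] < 0 || p[3] <= 0) return(1e10)
      ll <- cpp_polygenic_loglik(b$y, b$phis, b$idx, p[1], p[2], p[3])
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    H <- tryCatch(optimHess(c(mu, s2g, s2e), nll_nat), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        d <- c(0, s2e, -s2g) / (s2g + s2e)^2
        v <- drop(t(d) %*% V %*% d)
        if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
      }
    }
  }

  structure(list(
    sigma2_g = s2g, sigma2_e = s2e, h2 = h2, se_h2 = se_h2,
    mu = mu, loglik = -best$value, loglik_sporadic = spor$loglik,
    n = b$n, n_families = b$n_families,
    converged = best$convergence == 0
  ), class = "polygenic_fit")
}

#' Likelihood-ratio test for heritability
#'
#' Tests `sigma2_g = 0` against the polygenic model. Because the null pins
#' `sigma2_g` to the boundary of its parameter space, the LRT statistic is
#' distributed as a 50:50 mixture of a point mass at 0 and a chi-square with
#' 1 df, so `p = 0.5 * P(chi2_1 > T)` for `T > 0` and `p = 1` at `T = 0`.
#'
#' @param fit A [fit_polygenic()] result.
#' @return An `lrt_result` (see [lrt_test()]).
#' @export
h2_test <- function(fit) {
  stopifnot(inherits(fit, "polygenic_fit"))
  lrt_test(fit$loglik, fit$loglik_sporadic, contrast = "h2_zero")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat("Polygenic variance-components fit\n")
  cat(sprintf("  n = %d individuals in %d families\n", x$n, x$n_families))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f\n", x$sigma2_g, x$sigma2_e))
  cat(sprintf("  h2 = %.3f (SE %s)\n", x$h2,
              if (is.na(x$se_h2)) "NA" else sprintf("%.3f", x$se_h2)))
  cat(sprintf("  logLik = %.3f (sporadic %.3f)\n", x$loglik, x$loglik_sporadic))
  invisible(x)
}
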
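#' Parameters of the continuous GxE variance model
#'
#' The model lets both variance components vary log-linearly with the
#' environmental index `q` (standardized TDEE):
#' `sigma2_g(q) = exp(alpha_g + gamma_g * q)` and
#' `sigma2_e(q) = exp(alpha_e + gamma_e * q)`, and lets the genetic
#' correlation between relatives decay exponentially in their environmental
#' distance: `rho_g(q_i, q_j) = exp(-lambda * |q_i - q_j|)`. The exponential
#' keeps variances positive for any slope; `gamma_g = 0` is variance
#' homogeneity and `lambda = 0` is a genetic correlation of exactly 1 — the
#' two null hypotheses of no interaction.
#'
#' @param mu Grand mean of the (adjusted, normalized) trait scores.
#' @param alpha_g,gamma_g Genetic log-variance intercept and slope per unit q.
#' @param lam Genetic-correlation decay rate per unit q (>= 0).
#' @param alpha_e,gamma_e Environmental log-variance intercept and slope.
#' @return A list of class `gxee_params`.
#' @export
gxee_params <- function(mu = 0, alpha_g = 0, gamma_g = 0, lam = 0,
                        alpha_e = 0, gamma_e = 0) {
  p <- list(mu = mu, alpha_g = alpha_g, gamma_g = gamma_g, lam = lam,
            alpha_e = alpha_e, gamma_e = gamma_e)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1)))) {
    abort("all parameters must be finite scalars")
  }
  if (p$lam < 0) abort("lam (correlation decay rate) must be >= 0")
  structure(p, class = "gxee_params")
}

#' Genetic variance as a function of the environment
#'
#' `sigma2_g(q) = exp(alpha_g + gamma_g * q)`, the log-linear variance model.
#'
#' @param q Environmental index (standardized TDEE), any numeric vector.
#' @param params A [gxee_params()] object.
#' @return Strictly positive variances, same length as `q`.
#' @export
genetic_variance <- function(q, params) {
  stopifnot(inherits(params, "gxee_params"))
  eta <- params$alpha_g + params$gamma_g * q
  if (any(abs(eta) > 700)) {
    abort("log-variance exceeds +-700: rescale the environment (see standardize_tdee)")
  }
  exp(eta)
}

#' Environmental variance as a function of the environment
#'
#' `sigma2_e(q) = exp(alpha_e + gamma_e * q)`.
#'
#' @inheritParams genetic_variance
#' @export
environmental_variance <- function(q, params) {
  stopifnot(inherits(params, "gxee_params"))
  eta <- params$alpha_e + params$gamma_e * q
  if (any(abs(eta) > 700)) {
    abort("log-variance exceeds +-700: rescale the environment (see standardize_tdee)")
  }
  exp(eta)
}

#' Genetic correlation between two environments
#'
#' `rho_g = exp(-lambda * |q_i - q_j|)`: 1 when the pair shares the same
#' environment or when `lambda = 0` (the "same genes everywhere" null), and
#' decaying towards 0 as environments diverge.
#'
#' @param q_i,q_j Environmental indices (recycled to a common length).
#' @param lam Decay rate, >= 0.
#' @return Correlations in (0, 1].
#' @export
genetic_correlation <- function(q_i, q_j, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam < 0) {
    abort("lam must be a finite scalar >= 0")
  }
  exp(-lam * abs(q_i - q_j))
}

#' Family covariance blocks under the GxE model
#'
#' Assembles, for each family, the phenotypic covariance
#' `Omega_ij = 2Phi_ij * rho_g(q_i, q_j) * sigma_g(q_i) * sigma_g(q_j) +
#' delta_ij * sigma2_e(q_i)` with `sigma_g(q) = exp((alpha_g + gamma_g q)/2)`.
#' With `gamma_g = gamma_e = 0` and `lambda = 0` this reduces exactly to the
#' polygenic covariance `2Phi sigma2_g + I sigma2_e`. The same block builder
#' backs the model likelihood and the trait simulator.
#'
#' @param ids Individual ids, aligned with `q`.
#' @param q Environmental index vector (standardized TDEE).
#' @param rel Relationship matrix from [kinship_matrix()] (must contain `ids`).
#' @param params A [gxee_params()] object.
#' @param families Named list mapping family id -> ids, or a vector of family
#'   ids aligned with `ids`. If omitted, all ids are treated as one block.
#' @return Named list of symmetric covariance matrices, one per family, with
#'   dimnames the member ids.
#' @export
gxee_covariance <- function(ids, q, rel, params, families = NULL) {
  stopifnot(inherits(params, "gxee_params"))
  ids <- as.character(ids)
  if (length(ids) != length(q)) abort("ids and q must be aligned")
  if (!all(ids %in% rownames(rel))) abort("ids missing from relationship matrix")
  fam_split <- if (is.null(families)) {
    list(all = ids)
  } else if (is.list(families)) {
    families
  } else {
    split(ids, as.character(families))
  }
  purrr::imap(fam_split, function(members, fam_id) {
    sel <- match(members, ids)
    if (anyNA(sel)) abort(paste0("family ", fam_id, " member missing from ids"))
    phi <- rel[members, members, drop = FALSE]
    S <- cpp_gxee_block(phi, q[sel], params$alpha_g, params$gamma_g, params$lam,
                        params$alpha_e, params$gamma_e)
    dimnames(S) <- list(members, members)
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0) {
      abort(paste0("covariance block not positive definite for family ", fam_id,
                   " (min eigenvalue ", format(ev_min), ")"))
    }
    S
  })
}

#' Evaluate the fitted variance and correlation functions on grids
#'
#' Produces the curves a GxE analysis reports: genetic and environmental
#' variance over a grid of environmental values, the genetic correlation over
#' a grid of pairwise environmental differences, and the genetic covariance
#' surface for a fully related pair (`2Phi = 1`),
#' `cov(q, q + dq) = rho_g(dq) * sigma_g(q) * sigma_g(q + dq)`.
#'
#' @param fit A `gxee_fit` (from [fit_gxee()]) or a [gxee_params()] object.
#' @param q_grid Grid of environmental values (standardized TDEE).
#' @param dq_grid Grid of non-negative pairwise differences.
#' @return A list of tibbles: `variance` (`q`, `sigma2_g`, `sigma2_e`),
#'   `correlation` (`dq`, `rho_g`), and `covariance` (`q`, `dq`, `cov_g`).
#' @export
evaluate_functions <- function(fit, q_grid = seq(-2, 2, by = 0.1),
                               dq_grid = seq(0, 4, by = 0.1)) {
  params <- if (inherits(fit, "gxee_fit")) fit$params else fit
  stopifnot(inherits(params, "gxee_params"))
  if (any(!is.finite(q_grid)) || any(!is.finite(dq_grid))) abort("grids must be finite")
  if (any(dq_grid < 0)) abort("dq_grid must be non-negative")
  variance <- tibble::tibble(
    q = q_grid,
    sigma2_g = genetic_variance(q_grid, params),
    sigma2_e = environmental_variance(q_grid, params)
  )
  correlation <- tibble::tibble(
    dq = dq_grid,
    rho_g = genetic_correlation(dq_grid, 0, params$lam)
  )
  surface <- tidyr::expand_grid(q = q_grid, dq = dq_grid) |>
    dplyr::mutate(cov_g = genetic_correlation(.data$dq, 0, params$lam) *
                    sqrt(genetic_variance(.data$q, params)) *
                    sqrt(genetic_variance(.data$q + .data$dq, params)))
  list(variance = variance, correlation = correlation, covariance = surface)
}
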
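test_that("variance and correlation functions obey their closed forms", {
  p <- gxee_params(alpha_g = log(2), gamma_g = 0)
  expect_equal(genetic_variance(c(-3, 0, 2), p), rep(2, 3))
  p2 <- gxee_params(alpha_g = 0, gamma_g = 1)
  expect_equal(genetic_variance(log(3), p2), 3)
  expect_error(genetic_variance(800, p2), "rescale")

  expect_equal(genetic_correlation(1.3, -0.2, 0), 1)
  expect_equal(genetic_correlation(0.7, 0.7, 5), 1)
  expect_equal(genetic_correlation(log(2), 0, 1), 0.5)
  expect_error(genetic_correlation(0, 1, -0.1), ">= 0")
  expect_error(gxee_params(lam = -1), ">= 0")
})

test_that("covariance blocks match an elementwise brute-force construction", {
  set.seed(13)
  ped <- ped_nuclear(1, k = 3)
  rel <- kinship_matrix(ped)
  ids <- ped$individual_id
  q <- rnorm(5)
  p <- gxee_params(mu = 0.3, alpha_g = -0.4, gamma_g = 0.6, lam = 0.5,
                   alpha_e = -0.9, gamma_e = -0.2)
  S <- gxee_covariance(ids, q, rel, p)[[1]]
  B <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    B[i, j] <- rel[i, j] * exp(-p$lam * abs(q[i] - q[j])) *
      exp(0.5 * (p$alpha_g + p$gamma_g * q[i])) *
      exp(0.5 * (p$alpha_g + p$gamma_g * q[j])) +
      (i == j) * exp(p$alpha_e + p$gamma_e * q[i])
  }
  expect_equal(unname(S), B, tolerance = 1e-12)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("covariance has the advertised special cases", {
  ped <- ped_nuclear(1, k = 2)
  rel <- kinship_matrix(ped)
  ids <- ped$individual_id
  # sib pair at equal environment: off-diagonal ignores lambda
  q_eq <- c(0.8, -0.1, 0.7, 0.7)
  p <- gxee_params(alpha_g = -0.5, gamma_g = 0.4, lam = 3, alpha_e = -0.5)
  S <- gxee_covariance(ids, q_eq, rel, p)[[1]]
  expect_equal(S[3, 4], 0.5 * exp(p$alpha_g + p$gamma_g * 0.7), tolerance = 1e-12)
  # gamma = lambda = 0 collapses to the polygenic covariance
  p0 <- gxee_params(alpha_g = log(0.4), alpha_e = log(0.6))
  S0 <- gxee_covariance(ids, rnorm(4), rel, p0)[[1]]
  expect_equal(unname(S0), unname(rel * 0.4 + diag(4) * 0.6), tolerance = 1e-12)
})

test_that("GxE likelihood matches the dense oracle and respects reparameterization", {
  skip_if_not_installed("mvtnorm")
  truth <- gxee_params(alpha_g = -0.7, gamma_g = 0.5, lam = 0.3, alpha_e = -0.7)
  d <- sim_dataset(3, truth, k = 2, seed = 31)
  p <- gxee_params(mu = 0.1, alpha_g = -0.3, gamma_g = 0.2, lam = 0.4,
                   alpha_e = -0.6, gamma_e = 0.1)
  ll <- gxee_loglik(p, d$scores, d$q, d$rel, d$ped)
  fam <- setNames(d$ped$family_id, d$ped$individual_id)[d$scores$individual_id]
  oracle <- oracle_dense_loglik(d$scores$score, unname(d$q[d$scores$individual_id]),
                                d$rel[d$scores$individual_id, d$scores$individual_id],
                                unname(fam), p)
  expect_equal(ll, oracle, tolerance = 1e-8)

  # shifting q by c while moving alpha -> alpha - gamma*c leaves the likelihood unchanged
  cshift <- 0.9
  p_shift <- gxee_params(mu = p$mu, alpha_g = p$alpha_g - p$gamma_g * cshift,
                         gamma_g = p$gamma_g, lam = p$lam,
                         alpha_e = p$alpha_e - p$gamma_e * cshift, gamma_e = p$gamma_e)
  ll_shift <- gxee_loglik(p_shift, d$scores, d$q + cshift, d$rel, d$ped)
  expect_equal(ll, ll_shift, tolerance = 1e-10)
})

test_that("constrained GxE fit reproduces the polygenic fit (nesting)", {
  truth <- gxee_params(alpha_g = log(0.4), alpha_e = log(0.6))
  for (seed in c(41, 42)) {
    d <- sim_dataset(60, truth, seed = seed)
    pf <- fit_polygenic(d$scores, d$rel, d$ped)
    gf <- fit_gxee(d$scores, d$q, d$rel, d$ped,
                   constraints = c("gamma_g", "gamma_e", "lambda"))
    expect_equal(gf$loglik, pf$loglik, tolerance = 1e-6)
    expect_equal(gf$params$gamma_g, 0)
    expect_equal(gf$params$lam, 0)
    expect_equal(gf$params$gamma_e, 0)
  }
})

test_that("full fit dominates its submodels", {
  truth <- gxee_params(alpha_g = -0.7, gamma_g = 0.5, lam = 0.3, alpha_e = -0.7)
  d <- sim_dataset(80, truth, seed = 51)
  full <- fit_gxee(d$scores, d$q, d$rel, d$ped)
  for (con in list("gamma_g", "lambda", c("gamma_g", "gamma_e", "lambda"))) {
    red <- fit_gxee(d$scores, d$q, d$rel, d$ped, constraints = con)
    expect_gte(full$loglik, red$loglik - 1e-6)
  }
})

test_that("function evaluation grids reflect the fitted parameters", {
  p_up <- gxee_params(alpha_g = -0.5, gamma_g = 0.4, lam = 0.6, alpha_e = -0.5)
  funs <- evaluate_functions(p_up)
  expect_true(all(diff(funs$variance$sigma2_g) > 0))
  expect_equal(funs$correlation$rho_g[funs$correlation$dq == 0], 1)
  expect_true(all(diff(funs$correlation$rho_g) < 0))

  p_null <- gxee_params(alpha_g = -0.5, gamma_g = 0, lam = 0, alpha_e = -0.5)
  funs0 <- evaluate_functions(p_null)
  expect_equal(diff(range(funs0$covariance$cov_g)), 0, tolerance = 1e-12)
  expect_error(evaluate_functions(p_null, dq_grid = c(-1, 0)), "non-negative")
})

test_that("tidy reports both environmental scales", {
  truth <- gxee_params(alpha_g = -0.7, gamma_g = 0.5, lam = 0.3, alpha_e = -0.7)
  d <- sim_dataset(40, truth, seed = 61)
  qtab <- tibble::tibble(individual_id = names(d$q), q = unname(d$q))
  attr(qtab, "scale") <- 500  # pretend raw TDEE had SD 500 kcal/day
  fit <- fit_gxee(d$scores, qtab, d$rel, d$ped)
  td <- tidy(fit)
  gg <- td[td$term == "gamma_g", ]
  expect_equal(gg$estimate_per_1000kcal, gg$estimate / 500 * 1000)
  expect_true(is.na(td$estimate_per_1000kcal[td$term == "mu"]))
})
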
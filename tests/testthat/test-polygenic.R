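test_that("polygenic likelihood reduces to known Gaussian densities", {
  # single unrelated individual, standard normal params
  ped1 <- as_pedigree(tibble::tibble(
    family_id = "F1", individual_id = "a", father_id = NA, mother_id = NA, sex = "male"
  ))
  rel1 <- kinship_matrix(ped1)
  sc1 <- tibble::tibble(individual_id = "a", score = 0)
  ll <- polygenic_loglik(list(mu = 0, sigma2_g = 0, sigma2_e = 1), sc1, rel1, ped1)
  expect_equal(ll, -0.5 * log(2 * pi))

  # sigma2_g = 0 collapses to iid normal regardless of pedigree structure
  ped <- ped_nuclear(3, k = 2)
  rel <- kinship_matrix(ped)
  set.seed(5)
  sc <- tibble::tibble(individual_id = ped$individual_id, score = rnorm(nrow(ped)))
  ll0 <- polygenic_loglik(list(mu = 0.2, sigma2_g = 0, sigma2_e = 1.3), sc, rel, ped)
  expect_equal(ll0, sum(dnorm(sc$score, 0.2, sqrt(1.3), log = TRUE)), tolerance = 1e-10)
})

test_that("block likelihood equals a dense multivariate-normal oracle", {
  skip_if_not_installed("mvtnorm")
  ped <- ped_nuclear(1, k = 3)  # 5-member family
  rel <- kinship_matrix(ped)
  set.seed(6)
  y <- rnorm(5)
  sc <- tibble::tibble(individual_id = ped$individual_id, score = y)
  for (i in 1:5) {
    p <- list(mu = rnorm(1), sigma2_g = runif(1, 0.1, 2), sigma2_e = runif(1, 0.1, 2))
    ll <- polygenic_loglik(p, sc, rel, ped)
    S <- rel * p$sigma2_g + diag(5) * p$sigma2_e
    expect_equal(ll, mvtnorm::dmvnorm(y, rep(p$mu, 5), S, log = TRUE), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to family and member ordering", {
  truth <- gxee_params(alpha_g = log(0.5), alpha_e = log(0.5))
  d <- sim_dataset(6, truth, seed = 11)
  p <- list(mu = 0.1, sigma2_g = 0.4, sigma2_e = 0.6)
  ll1 <- polygenic_loglik(p, d$scores, d$rel, d$ped)
  perm <- sample(nrow(d$scores))
  ll2 <- polygenic_loglik(p, d$scores[perm, ], d$rel, d$ped)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("ML fit matches a dense grid-search oracle on a toy dataset", {
  skip_if_not_installed("mvtnorm")
  truth <- gxee_params(alpha_g = log(0.5), alpha_e = log(0.5))
  d <- sim_dataset(3, truth, k = 2, seed = 21)
  fit <- fit_polygenic(d$scores, d$rel, d$ped)
  y <- d$scores$score
  dense_ll <- function(s2g, s2e) {
    S <- d$rel * s2g + diag(length(y)) * s2e
    mvtnorm::dmvnorm(y, rep(fit$mu, length(y)), S, log = TRUE)
  }
  # coarse pass then fine pass at step 1e-3 around the coarse optimum
  coarse <- expand.grid(s2g = seq(0.001, 3, by = 0.05), s2e = seq(0.01, 3, by = 0.05))
  coarse$ll <- mapply(dense_ll, coarse$s2g, coarse$s2e)
  top <- coarse[which.max(coarse$ll), ]
  fine <- expand.grid(
    s2g = seq(max(1e-4, top$s2g - 0.06), top$s2g + 0.06, by = 1e-3),
    s2e = seq(max(1e-3, top$s2e - 0.06), top$s2e + 0.06, by = 1e-3)
  )
  fine$ll <- mapply(dense_ll, fine$s2g, fine$s2e)
  best <- fine[which.max(fine$ll), ]
  expect_equal(fit$sigma2_g, best$s2g, tolerance = 2e-3)
  expect_equal(fit$sigma2_e, best$s2e, tolerance = 2e-3)
})

test_that("fit recovers heritability on sib-pair families and nests the sporadic model", {
  truth <- gxee_params(alpha_g = log(0.5), alpha_e = log(0.5))  # h2 = 0.5, var 1
  h2s <- vapply(1:200, function(s) {
    d <- sim_dataset(300, truth, k = 2, seed = 1000 + s)
    fit_polygenic(d$scores, d$rel, d$ped)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.5), 0.05)

  d <- sim_dataset(50, truth, seed = 3)
  fit <- fit_polygenic(d$scores, d$rel, d$ped)
  expect_gte(fit$loglik, fit$loglik_sporadic)
  expect_true(fit$converged)
  expect_equal(fit$h2 + fit$sigma2_e / (fit$sigma2_g + fit$sigma2_e), 1)
})

test_that("h2 boundary test is calibrated under the null", {
  set.seed(77)
  pk <- ped_nuclear_cached(60, k = 2)
  sig <- replicate(100, {
    sc <- tibble::tibble(individual_id = pk$ped$individual_id,
                         score = rnorm(nrow(pk$ped)))
    h2_test(fit_polygenic(sc, pk$rel, pk$ped))$p < 0.05
  })
  expect_gte(mean(!sig), 0.90)
})

test_that("tidy and glance expose the fit", {
  truth <- gxee_params(alpha_g = log(0.4), alpha_e = log(0.6))
  d <- sim_dataset(40, truth, seed = 8)
  fit <- fit_polygenic(d$scores, d$rel, d$ped)
  td <- tidy(fit)
  expect_equal(td$term, c("mu", "sigma2_g", "sigma2_e", "h2"))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(d$scores))
  expect_true(gl$logLik >= gl$logLik_sporadic)
})

test_that("underpowered designs are refused", {
  ped <- as_pedigree(tibble::tibble(
    family_id = c("F1", "F2"), individual_id = c("a", "b"),
    father_id = NA_character_, mother_id = NA_character_,
    sex = c("male", "female")
  ))
  rel <- kinship_matrix(ped)
  sc <- tibble::tibble(individual_id = c("a", "b"), score = c(0.1, -0.2))
  expect_error(fit_polygenic(sc, rel, ped), "at least 2 families")
})
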
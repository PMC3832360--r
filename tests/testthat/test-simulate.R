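test_that("pedigree simulation builds valid nuclear families deterministically", {
  cfg <- sim_config(n_families = 1, offspring_dist = c(`2` = 1),
                    participation = c(father = 1, mother = 1, offspring = 1))
  set.seed(1)
  ped <- simulate_pedigrees(cfg)
  expect_equal(nrow(ped), 4)
  expect_equal(sum(ped$founder), 2)
  expect_equal(unique(ped$father_id[!ped$founder]), ped$individual_id[ped$role == "father"])

  s1 <- simulate_study(sim_config(n_families = 20), seed = 99)
  s2 <- simulate_study(sim_config(n_families = 20), seed = 99)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$pedigree, s2$pedigree)
})

test_that("default study size and participation match the design profile", {
  sizes <- vapply(1:20, function(s) {
    set.seed(s)
    ped <- simulate_pedigrees(sim_config())
    sum(ped$phenotyped)
  }, numeric(1))
  expect_lt(abs(mean(sizes) - 958) / 958, 0.05)
  # every family keeps at least two participants
  set.seed(5)
  ped <- simulate_pedigrees(sim_config())
  per_fam <- tapply(ped$phenotyped, ped$family_id, sum)
  expect_gte(min(per_fam), 2)
})

test_that("TDEE draws honor role moments and truncation", {
  # many singleton 'father' families so all draws share one role
  ped <- as_pedigree(tibble::tibble(
    family_id = sprintf("S%05d", 1:10000),
    individual_id = sprintf("S%05d_fa", 1:10000),
    father_id = NA_character_, mother_id = NA_character_, sex = "male"
  ))
  ped$role <- "father"
  set.seed(2)
  td <- simulate_tdee(ped, sim_config())
  se <- 962.71 / sqrt(10000)
  expect_lt(abs(mean(td$tdee) - 3561.79), 3 * se + 3)  # +3 for truncation bias
  expect_lt(abs(sd(td$tdee) - 962.71) / 962.71, 0.05)

  # a low-mean role hits the floor but never crosses it
  cfg_low <- sim_config(tdee_moments = tibble::tibble(
    role = "father", mean = 700, sd = 300
  ))
  td_low <- simulate_tdee(ped, cfg_low)
  expect_gte(min(td_low$tdee), 500)
})

test_that("emitted diaries reproduce the drawn TDEE within one cost quantum", {
  cfg <- sim_config(n_families = 15, emit_diaries = TRUE)
  st <- simulate_study(cfg, seed = 17)
  expect_false(is.null(st$diaries))
  w <- setNames(st$phenotypes$weight, st$phenotypes$individual_id)
  rec <- tdee_from_diary_table(st$diaries,
                               tibble::tibble(individual_id = names(w), weight = unname(w)))
  joined <- dplyr::inner_join(rec, st$phenotypes, by = "individual_id")
  quantum <- joined$weight * (0.38 - 0.26) / 3
  expect_true(all(abs(joined$tdee.x - joined$tdee.y) <= quantum + 1e-9))
})

test_that("trait simulation reproduces the model's second moments", {
  # sib pairs at a common environment: cov(sib1, sib2) = 0.5 * exp(ag + gg*q)
  n_pair <- 20000
  ped <- ped_nuclear(n_pair, k = 2)
  p <- gxee_params(alpha_g = -0.7, gamma_g = 0.5, lam = 0.3, alpha_e = -0.7)
  qv <- 0.6
  q <- setNames(rep(qv, nrow(ped)), ped$individual_id)
  set.seed(23)
  tv <- simulate_traits(ped, q, rel = NULL, params = p)
  sib1 <- tv$value[grepl("_o1$", tv$individual_id)]
  sib2 <- tv$value[grepl("_o2$", tv$individual_id)]
  emp <- stats::cov(sib1, sib2)
  expected <- 0.5 * exp(p$alpha_g + p$gamma_g * qv)
  v_marg <- exp(p$alpha_g + p$gamma_g * qv) + exp(p$alpha_e)
  se <- sqrt((v_marg^2 + expected^2) / n_pair)  # Var of a bivariate-normal sample cov
  expect_lt(abs(emp - expected), 3 * se)
})

test_that("polygenic truth is the gamma = lambda = 0 special case, bit for bit", {
  ped <- ped_nuclear(5, k = 2)
  rel <- kinship_matrix(ped)
  q <- setNames(rnorm(nrow(ped)), ped$individual_id)
  p_poly <- gxee_params(alpha_g = log(0.4), alpha_e = log(0.6))
  set.seed(9); t1 <- simulate_traits(ped, q, rel, p_poly)
  set.seed(9); t2 <- simulate_traits(ped, q, rel,
                                     gxee_params(alpha_g = log(0.4), gamma_g = 0,
                                                 lam = 0, alpha_e = log(0.6), gamma_e = 0))
  expect_identical(t1, t2)
})

test_that("gene dropping agrees with the analytic kinship", {
  ped <- as_pedigree(ped_trio())
  G <- gene_drop_kinship(ped, n_drops = 20000, seed = 3)
  A <- kinship_matrix(ped)
  # parent-offspring sharing is deterministic at one allele: estimate exact
  expect_equal(G["F1_fa", "F1_ch"], 0.5)
  expect_equal(G["F1_fa", "F1_mo"], 0)  # unrelated founders share nothing
  # inbred pedigree: Monte-Carlo within 3 SE of the recursion
  pedc <- as_pedigree(ped_consanguineous())
  Gc <- gene_drop_kinship(pedc, n_drops = 50000, seed = 4)
  Ac <- kinship_matrix(pedc)
  tol <- 3 * 1 / sqrt(50000)  # conservative: per-drop sharing has SD <= 1
  expect_true(all(abs(Gc - Ac) < tol))
})
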
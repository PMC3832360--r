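#' Configuration for the synthetic family-study generator
#'
#' Defaults emulate a nuclear-family metabolic-syndrome study of 294 families
#' and roughly 958 participants: both parents exist in every pedigree, each
#' family has 1-4 offspring aged 10-18, and participation thinning reproduces
#' the observed role profile (180 fathers, 253 mothers, 265 sons, 260
#' daughters in expectation) with at least two participants per family.
#' Role-specific TDEE means and SDs (kcal/day) are the study's descriptive
#' moments; draws are truncated below at 500 kcal/day to avoid nonphysical
#' values. Offspring ages are uniform on 10-18 and parent ages normal around
#' the study means; body weights (needed only for diary round-trips) are
#' role-conditional normals chosen as realistic for Portuguese families.
#'
#' @param n_families Number of families.
#' @param offspring_dist Probabilities of 1..4 offspring per family
#'   (mean 1.79, tuned once so expected participant counts match the role
#'   profile above).
#' @param participation Participation probability per role (offspring always
#'   participate; they are the probands).
#' @param tdee_moments Tibble `role`, `mean`, `sd` in kcal/day.
#' @param tdee_min Lower truncation for TDEE draws (kcal/day).
#' @param traits Named list of trait generating models; each element is a
#'   list with `params` (a [gxee_params()]; use zero slopes and decay for a
#'   purely polygenic trait) and optional `covariate_effects`
#'   (`intercept`, `age`, `age2`, `male`).
#' @param emit_diaries If `TRUE`, also emit 3-day diaries whose category
#'   counts reproduce each subject's drawn TDEE under `costs`.
#' @param costs An [energy_cost_table()] for diary construction.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    n_families = 294,
    offspring_dist = c(`1` = 0.39, `2` = 0.46, `3` = 0.12, `4` = 0.03),
    participation = c(father = 180 / 294, mother = 253 / 294, offspring = 1),
    tdee_moments = tibble::tribble(
      ~role, ~mean, ~sd,
      "father", 3561.79, 962.71,
      "mother", 2788.37, 527.58,
      "son", 2280.57, 774.43,
      "daughter", 2024.85, 568.43
    ),
    tdee_min = 500,
    traits = list(trait1 = list(
      params = gxee_params(alpha_g = -0.7, gamma_g = 0.5, lam = 0.3,
                           alpha_e = -0.7, gamma_e = 0),
      covariate_effects = list(intercept = 90, age = 0.6, age2 = -0.004, male = 4)
    )),
    emit_diaries = FALSE,
    costs = energy_cost_table()) {
  if (abs(sum(offspring_dist) - 1) > 1e-9) abort("offspring_dist must sum to 1")
  if (any(tdee_moments$sd <= 0)) abort("TDEE SDs must be positive")
  structure(list(
    n_families = n_families, offspring_dist = offspring_dist,
    participation = participation, tdee_moments = tdee_moments,
    tdee_min = tdee_min, traits = traits, emit_diaries = emit_diaries,
    costs = costs
  ), class = "sim_config")
}

rtruncnorm1 <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); lower <- rep_len(lower, n)
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < lower[bad]]
  }
  out
}

#' Simulate nuclear-family pedigrees with participation thinning
#'
#' Each family gets two parents and 1-4 offspring (sex Bernoulli 1/2).
#' Participation (phenotyping) is thinned per role; families ending with
#' fewer than two participants have their participation redrawn, mirroring a
#' recruitment rule of "at least two participating members".
#'
#' @param config A [sim_config()].
#' @return Pedigree tibble (see [as_pedigree()]) with extra columns `role`
#'   (`father`/`mother`/`son`/`daughter`), `phenotyped` (logical).
#' @export
simulate_pedigrees <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ko <- as.integer(names(config$offspring_dist))
  fams <- purrr::map(seq_len(config$n_families), function(i) {
    fid <- sprintf("F%03d", i)
    k <- ko[sample.int(length(ko), 1, prob = config$offspring_dist)]
    off_sex <- sample(c("male", "female"), k, replace = TRUE)
    tibble::tibble(
      family_id = fid,
      individual_id = paste0(fid, "_", c("fa", "mo", paste0("o", seq_len(k)))),
      father_id = c(NA, NA, rep(paste0(fid, "_fa"), k)),
      mother_id = c(NA, NA, rep(paste0(fid, "_mo"), k)),
      sex = c("male", "female", off_sex),
      role = c("father", "mother", ifelse(off_sex == "male", "son", "daughter"))
    )
  })
  df <- dplyr::bind_rows(fams)
  p <- config$participation
  prob <- dplyr::case_when(
    df$role == "father" ~ p[["father"]],
    df$role == "mother" ~ p[["mother"]],
    TRUE ~ p[["offspring"]]
  )
  phen <- runif(nrow(df)) < prob
  # enforce >= 2 participants per family by redrawing that family's thinning
  for (ix in split(seq_len(nrow(df)), df$family_id)) {
    while (sum(phen[ix]) < 2) phen[ix] <- runif(length(ix)) < prob[ix]
  }
  ped <- as_pedigree(df)
  ped$role <- df$role
  ped$phenotyped <- phen
  ped
}

#' Simulate role-conditional TDEE (and optional diaries)
#'
#' Draws TDEE from role-specific truncated normals. When diaries are
#' requested, each subject also gets a 3-day, 96-period-per-day category
#' diary whose counts reproduce the drawn TDEE under the configured energy
#' costs to within one 15-minute period's cost; draws below the subject's
#' all-resting diary minimum are redrawn (and counted in the `n_resampled`
#' attribute).
#'
#' @param ped Pedigree from [simulate_pedigrees()] (needs `role`).
#' @param weights Named vector of body weights (kg) by individual id;
#'   required when `config$emit_diaries` is `TRUE`.
#' @param config A [sim_config()].
#' @return Tibble `individual_id`, `tdee`; if diaries were emitted, a long
#'   diary table (`individual_id`, `day`, `p1`..`p96`) in the `diaries`
#'   attribute.
#' @export
simulate_tdee <- function(ped, config = sim_config(), weights = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(ped$role)) abort("pedigree must carry a role column (see simulate_pedigrees)")
  mom <- config$tdee_moments
  m <- setNames(mom$mean, mom$role)[ped$role]
  s <- setNames(mom$sd, mom$role)[ped$role]
  lower <- rep(config$tdee_min, nrow(ped))
  n_resampled <- 0L
  if (config$emit_diaries) {
    if (is.null(weights)) abort("weights are required to emit diaries")
    w <- weights[ped$individual_id]
    base <- w * 288 * unclass(config$costs)[1] / 3  # all-resting minimum, kcal/day
    pre <- rtruncnorm1(nrow(ped), m, s, config$tdee_min)
    n_resampled <- sum(pre < base)
    lower <- pmax(lower, base)
  }
  tdee <- rtruncnorm1(nrow(ped), m, s, lower)
  out <- tibble::tibble(individual_id = ped$individual_id, tdee = tdee)
  if (config$emit_diaries) {
    w <- weights[ped$individual_id]
    diaries <- purrr::pmap(list(out$individual_id, out$tdee, w), function(id, td, wi) {
      codes <- diary_for_tdee(td, wi, config$costs)
      mat <- matrix(codes, nrow = 3, ncol = 96, byrow = TRUE)
      colnames(mat) <- paste0("p", 1:96)
      dplyr::bind_cols(tibble::tibble(individual_id = id, day = 1:3),
                       tibble::as_tibble(mat))
    }) |> dplyr::bind_rows()
    attr(out, "diaries") <- diaries
    attr(out, "n_resampled") <- n_resampled
  }
  out
}

# Greedy diary construction: start from 288 resting periods and upgrade
# periods to the highest categories first until the target 3-day energy is
# met; the leftover is below one category-2 period's cost.
diary_for_tdee <- function(tdee, weight, costs = energy_cost_table()) {
  cc <- unclass(costs)
  target <- tdee * 3 / weight           # kcal/kg over 3 days
  n <- c(288L, integer(8))
  extra <- target - 288 * cc[1]
  if (extra < -1e-9) abort("TDEE below the all-resting diary minimum: infeasible")
  for (cat in 9:2) {
    delta <- cc[cat] - cc[1]
    k <- min(floor(extra / delta + 1e-12), n[1])
    if (k > 0) {
      n[cat] <- n[cat] + as.integer(k)
      n[1] <- n[1] - as.integer(k)
      extra <- extra - k * delta
    }
  }
  rep.int(1:9, n)
}

#' Simulate trait values under the GxE (or polygenic) covariance model
#'
#' Per family, draws a multivariate normal vector with covariance assembled
#' by [gxee_covariance()] — the exact generative twin of the model the
#' likelihood fits — and adds the configured age/sex mean effects. A purely
#' polygenic trait is the special case `gamma_g = gamma_e = lambda = 0`.
#'
#' @param ped Pedigree (with `family_id`).
#' @param q Named standardized-TDEE vector (by individual id) covering `ids`.
#' @param rel Relationship matrix for the pedigree; when `NULL`, per-family
#'   kinship blocks are computed on the fly (cheaper for very many families).
#' @param params Generating [gxee_params()].
#' @param ids Which individuals to simulate (default: all of `ped`).
#' @param mean_fun Optional function(ped rows) -> mean vector to add.
#' @return Tibble `individual_id`, `value` (latent score scale plus mean
#'   effects).
#' @export
simulate_traits <- function(ped, q, rel = NULL, params, ids = ped$individual_id,
                            mean_fun = NULL) {
  fmap <- setNames(ped$family_id, ped$individual_id)
  fam_split <- split(ids, fmap[ids])
  if (is.null(rel)) {
    fam_rows <- split(seq_len(nrow(ped)), ped$family_id)
    blocks <- purrr::imap(fam_split, function(members, fam_id) {
      rows <- fam_rows[[fam_id]]
      phi <- family_kinship(ped$individual_id[rows], ped$father_id[rows],
                            ped$mother_id[rows], fam_id)[members, members, drop = FALSE]
      S <- cpp_gxee_block(phi, unname(q[members]), params$alpha_g, params$gamma_g,
                          params$lam, params$alpha_e, params$gamma_e)
      dimnames(S) <- list(members, members)
      S
    })
  } else {
    blocks <- gxee_covariance(ids, unname(q[ids]), rel, params, families = fam_split)
  }
  vals <- purrr::imap(blocks, function(S, fam) {
    L <- t(chol(S))
    z <- rnorm(nrow(S))
    tibble::tibble(individual_id = rownames(S), value = params$mu + drop(L %*% z))
  }) |> dplyr::bind_rows()
  vals <- vals[match(ids, vals$individual_id), ]
  if (!is.null(mean_fun)) {
    vals$value <- vals$value + mean_fun(ped[match(ids, ped$individual_id), ])
  }
  vals
}

#' Simulate a complete synthetic family study
#'
#' One call produces the full fixture bundle every pipeline stage consumes:
#' pedigree with participation, ages, weights, TDEE (optionally diaries), and
#' one or more trait columns generated under the configured covariance model
#' with age/sex mean effects. Deterministic given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_study`: `pedigree`, `phenotypes` (tibble
#'   of participants: `individual_id`, `family_id`, `sex`, `age`, `weight`,
#'   `tdee`, one column per trait), `diaries` (or `NULL`), `truth` (the
#'   generating config).
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ped <- simulate_pedigrees(config)

  age <- dplyr::case_when(
    ped$role == "father" ~ rnorm(nrow(ped), 45.36, 5.17),
    ped$role == "mother" ~ rnorm(nrow(ped), 43.49, 4.47),
    TRUE ~ runif(nrow(ped), 10, 18)
  )
  age <- ifelse(ped$role %in% c("father", "mother"), pmax(age, 25), age)
  wmom <- list(father = c(78, 10), mother = c(65, 9), son = c(55, 12), daughter = c(48, 9))
  weight <- vapply(ped$role, function(r) rnorm(1, wmom[[r]][1], wmom[[r]][2]), numeric(1))
  weight <- pmax(weight, 25)
  weights <- setNames(weight, ped$individual_id)

  tdee_tbl <- simulate_tdee(ped, config, weights = weights)
  diaries <- attr(tdee_tbl, "diaries")

  keep <- ped$phenotyped
  ids <- ped$individual_id[keep]
  std <- standardize_tdee(tdee_tbl[keep, ])
  qv <- setNames(std$q, std$individual_id)
  rel <- kinship_matrix(ped)

  phen <- tibble::tibble(
    individual_id = ids,
    family_id = ped$family_id[keep],
    sex = ped$sex[keep],
    age = age[keep],
    weight = weight[keep],
    tdee = tdee_tbl$tdee[keep]
  )
  for (tr in names(config$traits)) {
    spec <- config$traits[[tr]]
    ce <- spec$covariate_effects %||% list(intercept = 0, age = 0, age2 = 0, male = 0)
    mean_fun <- function(rows) {
      a <- age[match(rows$individual_id, ped$individual_id)]
      ce$intercept + ce$age * a + ce$age2 * a^2 + ce$male * (rows$sex == "male")
    }
    tv <- simulate_traits(ped, qv, rel, spec$params, ids = ids, mean_fun = mean_fun)
    phen[[tr]] <- tv$value
  }
  if (!is.null(diaries)) diaries <- diaries[diaries$individual_id %in% ids, ]

  structure(list(pedigree = ped, phenotypes = phen, diaries = diaries,
                 truth = config, seed = seed),
            class = "synthetic_study")
}

#' Gene-dropping estimate of the relationship matrix
#'
#' Monte-Carlo oracle for [kinship_matrix()]: founders receive unique allele
#' labels (two each), alleles are transmitted down the pedigree by fair
#' Mendelian sampling, and the estimated relationship is twice the average of
#' the four cross-individual allele-matching indicators. The standard error
#' of each entry scales as `1/sqrt(n_drops)`.
#'
#' @param ped Pedigree.
#' @param n_drops Number of independent drops (>= 1).
#' @param seed Integer seed.
#' @return Symmetric matrix of estimated relationships, ids as dimnames.
#' @export
gene_drop_kinship <- function(ped, n_drops = 10000, seed = 1) {
  ped <- if (inherits(ped, "fam_pedigree")) ped else as_pedigree(ped)
  if (n_drops < 1) abort("n_drops must be >= 1")
  set.seed(seed)
  ids <- ped$individual_id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  allele_counter <- 0L
  for (fam in split(ped, ped$family_id)) {
    ord <- pedigree_order(fam)
    fa <- setNames(fam$father_id, fam$individual_id)
    mo <- setNames(fam$mother_id, fam$individual_id)
    al <- list()  # per id: n_drops x 2 matrix of allele labels
    for (id in ord) {
      f <- fa[[id]]; m <- mo[[id]]
      pick <- function(parent) {
        if (is.na(parent)) {
          # unobserved parent of a single-known-parent child: fresh founder alleles
          allele_counter <<- allele_counter + 2L
          lab <- allele_counter
          cbind(rep(lab - 1L, n_drops), rep(lab, n_drops))[cbind(seq_len(n_drops),
                sample.int(2L, n_drops, replace = TRUE))]
        } else {
          al[[parent]][cbind(seq_len(n_drops), sample.int(2L, n_drops, replace = TRUE))]
        }
      }
      if (is.na(f) && is.na(m)) {
        allele_counter <- allele_counter + 2L
        al[[id]] <- cbind(rep(allele_counter - 1L, n_drops), rep(allele_counter, n_drops))
      } else {
        al[[id]] <- cbind(pick(f), pick(m))
      }
    }
    for (i in seq_along(ord)) for (j in seq_len(i)) {
      a <- al[[ord[i]]]; b <- al[[ord[j]]]
      share <- (a[, 1] == b[, 1]) + (a[, 1] == b[, 2]) +
               (a[, 2] == b[, 1]) + (a[, 2] == b[, 2])
      est <- 2 * mean(share / 4)
      A[ord[i], ord[j]] <- A[ord[j], ord[i]] <- est
    }
  }
  A
}
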
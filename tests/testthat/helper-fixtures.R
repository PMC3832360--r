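# Pedigree fixtures and independent oracles shared across tests.

ped_trio <- function(fid = "F1") {
  tibble::tibble(
    family_id = fid,
    individual_id = paste0(fid, c("_fa", "_mo", "_ch")),
    father_id = c(NA, NA, paste0(fid, "_fa")),
    mother_id = c(NA, NA, paste0(fid, "_mo")),
    sex = c("male", "female", "female")
  )
}

# F families of two parents and k offspring each, globally unique ids.
ped_nuclear <- function(n_fam, k = 2) {
  fid <- rep(sprintf("F%04d", seq_len(n_fam)), each = k + 2)
  tag <- rep(c("fa", "mo", paste0("o", seq_len(k))), n_fam)
  is_off <- !(tag %in% c("fa", "mo"))
  sex <- character(length(tag))
  sex[tag == "fa"] <- "male"
  sex[tag == "mo"] <- "female"
  off_no <- as.integer(sub("^o", "", tag[is_off]))
  sex[is_off] <- ifelse(off_no %% 2 == 1, "male", "female")
  tibble::tibble(
    family_id = fid,
    individual_id = paste0(fid, "_", tag),
    father_id = ifelse(is_off, paste0(fid, "_fa"), NA),
    mother_id = ifelse(is_off, paste0(fid, "_mo"), NA),
    sex = sex
  ) |> famgxe::as_pedigree()
}

# pedigree + kinship cached across tests (both are deterministic)
.ped_cache <- new.env(parent = emptyenv())
ped_nuclear_cached <- function(n_fam, k = 2) {
  key <- paste0(n_fam, "_", k)
  if (is.null(.ped_cache[[key]])) {
    ped <- ped_nuclear(n_fam, k = k)
    .ped_cache[[key]] <- list(ped = ped, rel = famgxe::kinship_matrix(ped))
  }
  .ped_cache[[key]]
}

# Three generations with a consanguineous (half-sib) mating producing an
# inbred child: grandparents gf/gm1/gm2, half sibs hs1/hs2, child in.
ped_consanguineous <- function() {
  tibble::tibble(
    family_id = "C1",
    individual_id = c("gf", "gm1", "gm2", "hs1", "hs2", "in1", "in2"),
    father_id = c(NA, NA, NA, "gf", "gf", "hs1", "hs1"),
    mother_id = c(NA, NA, NA, "gm1", "gm2", "hs2", "hs2"),
    sex = c("male", "female", "female", "male", "female", "female", "male")
  )
}

# Exact expected-allele-sharing oracle: enumerates every Mendelian
# transmission configuration (2 binary inheritance choices per non-founder,
# all equally likely) and averages allele sharing. Independent of the
# recursive tabular method. Feasible for pedigrees with <= ~8 non-founders.
oracle_kinship_enum <- function(ped) {
  ped <- famgxe::as_pedigree(ped)
  ids <- ped$individual_id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (fam in split(ped, ped$family_id)) {
    ord <- famgxe:::pedigree_order(fam)
    fa <- setNames(fam$father_id, fam$individual_id)
    mo <- setNames(fam$mother_id, fam$individual_id)
    nf <- ord[!(is.na(fa[ord]) & is.na(mo[ord]))]
    stopifnot(length(nf) <= 8)
    # allele labels: founders (and implicit unknown parents) get fresh pairs
    counter <- 0L
    founder_alleles <- list()
    for (id in ord) {
      if (is.na(fa[[id]]) && is.na(mo[[id]])) {
        founder_alleles[[id]] <- c(counter + 1L, counter + 2L)
        counter <- counter + 2L
      }
    }
    implicit <- list()  # fresh alleles for each missing parent of a non-founder
    for (id in nf) {
      if (is.na(fa[[id]]) || is.na(mo[[id]])) {
        implicit[[id]] <- c(counter + 1L, counter + 2L)
        counter <- counter + 2L
      }
    }
    # choices: for each non-founder, paternal pick (1/2) and maternal pick (1/2)
    n_choice <- 2L * length(nf)
    grid <- as.matrix(expand.grid(rep(list(1:2), n_choice)))
    share_sum <- matrix(0, length(ord), length(ord))
    for (g in seq_len(nrow(grid))) {
      choice <- grid[g, ]
      al <- founder_alleles
      for (k in seq_along(nf)) {
        id <- nf[k]
        pat <- if (is.na(fa[[id]])) implicit[[id]][choice[2 * k - 1]] else al[[fa[[id]]]][choice[2 * k - 1]]
        mat <- if (is.na(mo[[id]])) implicit[[id]][choice[2 * k]] else al[[mo[[id]]]][choice[2 * k]]
        al[[id]] <- c(pat, mat)
      }
      for (i in seq_along(ord)) for (j in seq_len(i)) {
        a <- al[[ord[i]]]; b <- al[[ord[j]]]
        s <- (a[1] == b[1]) + (a[1] == b[2]) + (a[2] == b[1]) + (a[2] == b[2])
        share_sum[i, j] <- share_sum[i, j] + s / 4
      }
    }
    est <- 2 * share_sum / nrow(grid)
    for (i in seq_along(ord)) for (j in seq_len(i)) {
      A[ord[i], ord[j]] <- A[ord[j], ord[i]] <- est[i, j]
    }
  }
  A
}

# Dense multivariate-normal log-likelihood oracle: assembles the full
# covariance matrix elementwise in R and calls mvtnorm::dmvnorm once on the
# whole vector. Independent of the per-family C++ block path.
oracle_dense_loglik <- function(y, q, rel_full, fam, params) {
  n <- length(y)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (fam[i] == fam[j]) {
      S[i, j] <- rel_full[i, j] * exp(-params$lam * abs(q[i] - q[j])) *
        exp(0.5 * (params$alpha_g + params$gamma_g * q[i])) *
        exp(0.5 * (params$alpha_g + params$gamma_g * q[j]))
      if (i == j) S[i, j] <- S[i, j] + exp(params$alpha_e + params$gamma_e * q[i])
    }
  }
  mvtnorm::dmvnorm(y, mean = rep(params$mu, n), sigma = S, log = TRUE)
}

# Scores/q/rel bundle for a simulated dataset on a (cached) nuclear pedigree.
sim_dataset <- function(n_fam, truth, k = 2, seed = 1, q_sd = 1) {
  pk <- ped_nuclear_cached(n_fam, k = k)
  set.seed(seed)
  q <- setNames(rnorm(nrow(pk$ped), 0, q_sd), pk$ped$individual_id)
  tv <- famgxe::simulate_traits(pk$ped, q, pk$rel, truth)
  list(ped = pk$ped, rel = pk$rel, q = q,
       scores = tibble::tibble(individual_id = tv$individual_id, score = tv$value))
}
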
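#' Validate a study's input bundle
#'
#' Cross-checks pedigree, phenotype and (optional) diary tables before a run:
#' phenotyped ids must exist in the pedigree, traits must be phenotype
#' columns, diaries must have complete days of in-range codes. Problems are
#' reported as findings rather than errors so the caller decides fatality;
#' [run_study()] refuses to run on fatal findings.
#'
#' @param pedigree Pedigree tibble.
#' @param phenotypes Phenotype tibble (`individual_id`, covariates, traits).
#' @param diaries Optional long diary table (`individual_id`, `day`,
#'   `p1`..`p96`).
#' @param traits Optional trait names expected in `phenotypes`.
#' @return Tibble of findings (`severity` in fatal/info, `scope`, `message`),
#'   with a role-count summary (see [family_summary()]) in the
#'   `role_counts` attribute.
#' @export
validate_inputs <- function(pedigree, phenotypes, diaries = NULL, traits = NULL) {
  ped <- if (inherits(pedigree, "fam_pedigree")) pedigree else as_pedigree(pedigree)
  f <- list()
  note <- function(severity, scope, message) {
    f[[length(f) + 1]] <<- tibble::tibble(severity = severity, scope = scope,
                                          message = message)
  }
  orphan <- setdiff(phenotypes$individual_id, ped$individual_id)
  if (length(orphan) > 0) {
    note("fatal", "phenotypes", paste0("ids absent from pedigree: ",
                                       paste(head(orphan, 10), collapse = ", ")))
  }
  for (tr in traits %||% character(0)) {
    if (!tr %in% names(phenotypes)) {
      note("fatal", "phenotypes", paste0("trait column missing: ", tr))
    } else {
      n_miss <- sum(is.na(phenotypes[[tr]]))
      if (n_miss > 0) note("info", "phenotypes",
                           paste0(tr, ": ", n_miss, " missing values (listwise-deleted)"))
    }
  }
  if (!is.null(diaries)) {
    pcols <- paste0("p", 1:96)
    miss <- setdiff(c("individual_id", "day", pcols), names(diaries))
    if (length(miss) > 0) {
      note("fatal", "diaries", paste0("missing columns: ", paste(head(miss, 4), collapse = ", ")))
    } else {
      for (i in seq_len(nrow(diaries))) {
        codes <- suppressWarnings(as.integer(diaries[i, pcols]))
        bad <- sum(is.na(codes) | codes < 1L | codes > 9L)
        if (bad > 0) {
          note("fatal", "diaries",
               paste0("subject ", diaries$individual_id[i], " day ", diaries$day[i],
                      ": ", 96 - bad, " valid periods (expected 96)"))
        }
      }
      days <- diaries |> dplyr::count(.data$individual_id)
      for (k in which(days$n != 3)) {
        note("fatal", "diaries", paste0("subject ", days$individual_id[k], " has ",
                                        days$n[k], " diary days (expected 3)"))
      }
      nod <- setdiff(diaries$individual_id, ped$individual_id)
      if (length(nod) > 0) {
        note("fatal", "diaries", paste0("diary ids absent from pedigree: ",
                                        paste(head(nod, 10), collapse = ", ")))
      }
    }
  }
  out <- if (length(f) > 0) dplyr::bind_rows(f) else {
    tibble::tibble(severity = character(), scope = character(), message = character())
  }
  known <- intersect(phenotypes$individual_id, ped$individual_id)
  attr(out, "role_counts") <- family_summary(ped, phenotyped = known)
  out
}

# Map a polygenic fit into GxE parameter space (intercept-only variances);
# a boundary sigma2_g is clamped to a tiny positive value so log() is defined.
polygenic_as_gxee <- function(pfit) {
  gxee_params(mu = pfit$mu,
              alpha_g = log(max(pfit$sigma2_g, 1e-8)), gamma_g = 0, lam = 0,
              alpha_e = log(pfit$sigma2_e), gamma_e = 0)
}

zero_out <- function(params, constraints) {
  p <- unclass(params)
  if ("gamma_g" %in% constraints) p$gamma_g <- 0
  if ("gamma_e" %in% constraints) p$gamma_e <- 0
  if ("lambda" %in% constraints) p$lam <- 0
  do.call(gxee_params, p)
}

# Fit full + constrained GxE models for one trait with mutual warm starts, so
# the full model is guaranteed to dominate each submodel (nesting).
fit_gxee_suite <- function(scores, q, rel, families, pfit) {
  warm <- list(polygenic_as_gxee(pfit))
  full <- fit_gxee(scores, q, rel, families, extra_starts = warm)
  sub <- list(
    gamma_g0 = fit_gxee(scores, q, rel, families, constraints = "gamma_g",
                        extra_starts = c(warm, list(zero_out(full$params, "gamma_g")))),
    lambda0 = fit_gxee(scores, q, rel, families, constraints = "lambda",
                       extra_starts = c(warm, list(zero_out(full$params, "lambda"))))
  )
  # if any submodel (or the polygenic fit) beats the full model, restart the
  # full optimizer from the offending solution
  best_sub <- max(pfit$loglik, vapply(sub, function(s) s$loglik, numeric(1)))
  if (full$loglik < best_sub - 1e-9) {
    extras <- c(warm, purrr::map(sub, "params"), list(full$params))
    full <- fit_gxee(scores, q, rel, families, extra_starts = extras)
  }
  c(list(full = full), sub)
}

#' Run the full per-trait analysis pipeline
#'
#' For each trait: covariate adjustment and inverse-normal transformation,
#' polygenic maximum-likelihood fit with heritability and its boundary LRT,
#' full and constrained GxE fits, likelihood-ratio tests (full vs polygenic
#' under a 50:50 chi2_2/chi2_3 mixture; variance homogeneity `gamma_g = 0`
#' under chi2_1; genetic correlation `lambda = 0` under a 50:50 point-mass /
#' chi2_1 mixture), and evaluation of the fitted variance and correlation
#' functions on grids. A failing trait is reported and the remaining traits
#' still run.
#'
#' @param pedigree Pedigree tibble.
#' @param phenotypes Phenotype tibble with `individual_id`, `sex`, `age`,
#'   `tdee` (kcal/day) and the trait columns.
#' @param traits Character vector of trait column names.
#' @param interactions Covariate interactions kept in the adjustment model.
#' @param offset Inverse-normal rank offset (Blom 3/8 by default).
#' @param q_grid,dq_grid Grids for the function-evaluation export.
#' @return Object of class `study_report`: tibbles `heritability` (trait, n,
#'   h2, se, p, Wald 95% CI) and `gxee_lrt` (trait, polygenic and GxE
#'   log-likelihoods, LRT, p, and the two sub-hypothesis p-values), a
#'   `functions` list of per-trait grid tibbles, `fits` (all fitted objects
#'   and LRT results per trait), `errors`, and `validation` findings.
#' @export
run_study <- function(pedigree, phenotypes, traits,
                      interactions = c("age:sex", "age2:sex"),
                      offset = 0.375,
                      q_grid = seq(-2, 2, by = 0.1), dq_grid = seq(0, 4, by = 0.1)) {
  ped <- if (inherits(pedigree, "fam_pedigree")) pedigree else as_pedigree(pedigree)
  findings <- validate_inputs(ped, phenotypes, traits = traits)
  if (any(findings$severity == "fatal")) {
    abort(paste0("fatal validation findings:\n  ",
                 paste(findings$message[findings$severity == "fatal"], collapse = "\n  ")))
  }
  if (!"tdee" %in% names(phenotypes)) abort("phenotypes must carry a tdee column (kcal/day)")
  rel <- kinship_matrix(ped)
  std <- standardize_tdee(phenotypes)

  fits <- list(); errors <- list()
  herit <- list(); lrt_rows <- list(); fun_tables <- list()
  for (tr in traits) {
    res <- tryCatch({
      scores <- prepare_trait(phenotypes, tr, interactions = interactions, offset = offset)
      qtr <- std[match(scores$individual_id, std$individual_id), ]
      attr(qtr, "scale") <- attr(std, "scale")
      pfit <- fit_polygenic(scores, rel, ped)
      h2t <- h2_test(pfit)
      suite <- fit_gxee_suite(scores, qtr, rel, ped, pfit)
      lrt_full <- lrt_test(suite$full$loglik, pfit$loglik, "full_vs_polygenic")
      lrt_gg <- lrt_test(suite$full$loglik, suite$gamma_g0$loglik, "variance_homogeneity")
      lrt_lam <- lrt_test(suite$full$loglik, suite$lambda0$loglik, "genetic_correlation_one")
      funs <- evaluate_functions(suite$full, q_grid = q_grid, dq_grid = dq_grid)
      list(scores = scores, polygenic = pfit, h2_test = h2t, gxee = suite,
           lrt = list(full_vs_polygenic = lrt_full, variance_homogeneity = lrt_gg,
                      genetic_correlation_one = lrt_lam),
           functions = funs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[tr]] <- conditionMessage(res)
      next
    }
    fits[[tr]] <- res
    pfit <- res$polygenic
    ci <- pmin(pmax(pfit$h2 + c(-1, 1) * 1.96 * pfit$se_h2, 0), 1)
    herit[[tr]] <- tibble::tibble(
      trait = tr, n = pfit$n, h2 = pfit$h2, se = pfit$se_h2,
      p = res$h2_test$p, ci_lo = ci[1], ci_hi = ci[2], loglik = pfit$loglik
    )
    lrt_rows[[tr]] <- tibble::tibble(
      trait = tr,
      loglik_polygenic = pfit$loglik,
      loglik_gxee = res$gxee$full$loglik,
      lrt = res$lrt$full_vs_polygenic$statistic,
      p = res$lrt$full_vs_polygenic$p,
      p_var_homogeneity = res$lrt$variance_homogeneity$p,
      p_rho_one = res$lrt$genetic_correlation_one$p
    )
    fun_tables[[tr]] <- dplyr::bind_rows(
      res$functions$variance |>
        tidyr::pivot_longer(c("sigma2_g", "sigma2_e"), names_to = "curve") |>
        dplyr::mutate(dq = NA_real_),
      res$functions$correlation |>
        dplyr::transmute(dq = .data$dq, curve = "rho_g", value = .data$rho_g,
                         q = NA_real_),
      res$functions$covariance |>
        dplyr::transmute(q = .data$q, dq = .data$dq, curve = "cov_g",
                         value = .data$cov_g)
    ) |> dplyr::select("curve", "q", "dq", "value")
  }
  structure(list(
    heritability = dplyr::bind_rows(herit),
    gxee_lrt = dplyr::bind_rows(lrt_rows),
    functions = fun_tables,
    fits = fits,
    errors = errors,
    validation = findings,
    tdee_scale = list(center = attr(std, "center"), scale = attr(std, "scale"))
  ), class = "study_report")
}

#' Write a study report to disk
#'
#' Emits `heritability.tsv` (per-trait h2 table), `gxee_lrt.tsv` (per-trait
#' log-likelihoods, LRT and p-values), `functions_<trait>.csv` (variance /
#' correlation / covariance-surface grids) and `report.json` (all parameters
#' and tests at full precision, plus provenance).
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    heritability = file.path(dir, "heritability.tsv"),
    gxee_lrt = file.path(dir, "gxee_lrt.tsv"),
    report = file.path(dir, "report.json")
  )
  readr::write_tsv(report$heritability, paths["heritability"])
  readr::write_tsv(report$gxee_lrt, paths["gxee_lrt"])
  for (tr in names(report$functions)) {
    p <- file.path(dir, paste0("functions_", tr, ".csv"))
    readr::write_csv(report$functions[[tr]], p)
    paths[paste0("functions_", tr)] <- p
  }
  json <- list(
    provenance = list(package = "famgxe",
                      version = as.character(utils::packageVersion("famgxe")),
                      timestamp = format(Sys.time(), tz = "UTC")),
    tdee_scale = report$tdee_scale,
    traits = purrr::map(report$fits, function(res) {
      full <- res$gxee$full
      qs <- full$q_scale
      per1000 <- function(x) if (is.na(qs)) NA else x / qs * 1000
      list(
        polygenic = res$polygenic[c("sigma2_g", "sigma2_e", "h2", "se_h2",
                                    "mu", "loglik", "n", "n_families", "converged")],
        gxee = list(params = unclass(full$params),
                    params_per_1000kcal = list(gamma_g = per1000(full$params$gamma_g),
                                               gamma_e = per1000(full$params$gamma_e),
                                               lam = per1000(full$params$lam)),
                    loglik = full$loglik, converged = full$converged),
        tests = purrr::map(res$lrt, function(t) {
          list(contrast = t$contrast, statistic = t$statistic, p = t$p,
               loglik_full = t$loglik_full, loglik_reduced = t$loglik_reduced)
        })
      )
    }),
    errors = report$errors
  )
  jsonlite::write_json(json, paths["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(paths)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Family study report:", nrow(x$heritability), "trait(s)\n\n")
  print(x$heritability)
  cat("\n")
  print(x$gxee_lrt)
  if (length(x$errors) > 0) {
    cat("\nFailed traits:\n")
    for (tr in names(x$errors)) cat("  ", tr, ": ", x$errors[[tr]], "\n", sep = "")
  }
  invisible(x)
}
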
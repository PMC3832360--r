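#' Adjust a trait for age and sex covariates
#'
#' Fits an ordinary least-squares model of the raw trait on
#' `{1, sex, age, age^2, age:sex, age^2:sex}` — age, its square, sex and
#' their interactions — and returns the residuals. This mirrors the
#' preliminary covariate screen of family studies: means are cleaned of
#' demographic structure before any variance-components modeling, so the
#' genetic model only carries a grand mean. Rows with a missing trait value
#' or missing covariates are excluded (listwise deletion) and reported via
#' the `excluded` attribute; they are never imputed.
#'
#' @param phenotypes Data frame with columns `individual_id`, `sex`
#'   (`"male"`/`"female"` or 1/2), `age` (years) and the trait column.
#' @param trait Name of the trait column.
#' @param interactions Which sex interactions to keep; any subset of
#'   `c("age:sex", "age2:sex")` (default both).
#' @return Tibble `individual_id`, `residual` for the complete cases, with
#'   attributes `model` (deparsed formula), `n`, `excluded` (ids dropped),
#'   and `coef` (fitted coefficients).
#' @export
adjust_covariates <- function(phenotypes, trait,
                              interactions = c("age:sex", "age2:sex")) {
  need <- c("individual_id", "sex", "age", trait)
  miss <- setdiff(need, names(phenotypes))
  if (length(miss) > 0) abort(paste0("phenotype table missing columns: ", paste(miss, collapse = ", ")))
  if (length(interactions) > 0) {
    interactions <- match.arg(interactions, c("age:sex", "age2:sex"), several.ok = TRUE)
  }

  d <- tibble::tibble(
    individual_id = as.character(phenotypes$individual_id),
    y = as.numeric(phenotypes[[trait]]),
    sex = parse_sex(phenotypes$sex),
    age = as.numeric(phenotypes$age)
  )
  if (any(d$age <= 0, na.rm = TRUE)) abort("ages must be positive")
  keep <- complete.cases(d$y, d$sex, d$age) & d$sex != "unknown"
  excluded <- d$individual_id[!keep]
  d <- d[keep, ]
  d$age2 <- d$age^2
  d$male <- as.numeric(d$sex == "male")

  terms <- c("age", "age2", "male")
  if ("age:sex" %in% interactions) terms <- c(terms, "I(age * male)")
  if ("age2:sex" %in% interactions) terms <- c(terms, "I(age2 * male)")
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  p <- length(terms) + 1
  if (nrow(d) < p + 2) abort(paste0("need at least ", p + 2, " complete cases for trait ", trait))

  X <- model.matrix(fml, data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    abort(paste0("covariate design is rank deficient for trait ", trait,
                 "; collinear columns: ", paste(bad, collapse = ", ")))
  }
  fit <- lm(fml, data = d)
  out <- tibble::tibble(individual_id = d$individual_id, residual = unname(resid(fit)))
  attr(out, "model") <- paste(trait, "~", paste(terms, collapse = " + "))
  attr(out, "n") <- nrow(d)
  attr(out, "excluded") <- excluded
  attr(out, "coef") <- stats::coef(fit)
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their rank fractions,
#' `qnorm((rank - c) / (n - 2c + 1))`, with the Blom offset `c = 3/8` by
#' default (`c = 0` gives Van der Waerden scores, `c = 0.5` Hazen). Ties get
#' the average of their ranks, so tied inputs map to equal scores. The result
#' has near-Gaussian margins, which is what the variance-components
#' likelihood assumes.
#'
#' @param x Numeric vector, `n >= 3`, not all equal.
#' @param offset Rank offset `c` in `[0, 0.5]`; default Blom (3/8).
#' @return Numeric vector of normalized scores, same length and order as `x`.
#' @export
inverse_normal <- function(x, offset = 0.375) {
  x <- as.numeric(x)
  if (anyNA(x)) abort("inverse_normal expects complete data; drop NAs first")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations for the inverse normal transformation")
  if (length(unique(x)) == 1) abort("all values equal: no ordering information to transform")
  if (!is.finite(offset) || offset < 0 || offset > 0.5) abort("offset must be in [0, 0.5]")
  r <- rank(x, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Prepare a trait for variance-components analysis
#'
#' Covariate adjustment ([adjust_covariates()]) followed by the rank-based
#' inverse normal transformation ([inverse_normal()]) of the residuals. The
#' resulting scores are what the polygenic and GxE models consume.
#'
#' @inheritParams adjust_covariates
#' @inheritParams inverse_normal
#' @return Tibble `individual_id`, `score`, with the adjustment attributes of
#'   [adjust_covariates()] plus `trait` and `offset`.
#' @export
prepare_trait <- function(phenotypes, trait, interactions = c("age:sex", "age2:sex"),
                          offset = 0.375) {
  res <- adjust_covariates(phenotypes, trait, interactions = interactions)
  y_sd <- sd(as.numeric(phenotypes[[trait]]), na.rm = TRUE)
  if (!is.finite(y_sd) || y_sd == 0 || sd(res$residual) < 1e-10 * y_sd) {
    abort(paste0("trait ", trait, " has no residual variation after adjustment"))
  }
  out <- tibble::tibble(individual_id = res$individual_id,
                        score = inverse_normal(res$residual, offset = offset))
  for (a in c("model", "n", "excluded", "coef")) attr(out, a) <- attr(res, a)
  attr(out, "trait") <- trait
  attr(out, "offset") <- offset
  out
}
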
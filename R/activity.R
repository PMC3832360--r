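#' Per-category energy costs for the 3-day activity diary
#'
#' The diary records the dominant activity of each 15-minute period on a
#' 9-level intensity scale (1 = sleeping/resting in bed ... 9 = high-intensity
#' sport). Converting period counts to energy requires the approximate median
#' energy cost of each category in kcal/kg per 15 minutes. These defaults are
#' external constants taken from the Bouchard 3-day diary literature — they
#' are not estimated by this package and should be replaced whenever a study
#' uses its own calibration.
#'
#' @param costs Numeric vector of 9 strictly increasing positive values,
#'   kcal/kg/15 min.
#' @return A validated numeric vector of length 9 (class `energy_cost_table`).
#' @export
energy_cost_table <- function(costs = c(0.26, 0.38, 0.57, 0.69, 0.84,
                                        1.20, 1.40, 1.50, 1.95)) {
  costs <- as.numeric(costs)
  if (length(costs) != 9) abort("energy cost table must have 9 entries (categories 1..9)")
  if (any(!is.finite(costs)) || any(costs <= 0)) abort("energy costs must be positive and finite")
  if (any(diff(costs) <= 0)) abort("energy costs must be strictly increasing in category")
  structure(costs, class = "energy_cost_table")
}

#' Total daily energy expenditure from a 3-day activity diary
#'
#' Each subject's diary holds 3 days x 96 quarter-hour category codes in 1..9.
#' The number of 15-minute periods in each category is summed over the three
#' days, weighted by that category's median energy cost (kcal/kg/15 min),
#' summed over categories, multiplied by body weight (kg), and divided by 3:
#' `tdee = weight * sum_c n_c * cost_c / 3` in kcal/day.
#'
#' @param diary Integer vector of 288 category codes (3 x 96, any order:
#'   the result depends only on category counts), or a 3 x 96 matrix.
#' @param weight Body weight in kg (> 0).
#' @param costs An [energy_cost_table()].
#' @return TDEE in kcal/day (scalar).
#' @export
tdee_from_diary <- function(diary, weight, costs = energy_cost_table()) {
  diary <- as.integer(diary)
  if (length(diary) != 288) {
    abort(paste0("diary must contain exactly 288 quarter-hour periods (3 days x 96), got ",
                 length(diary)))
  }
  if (anyNA(diary) || any(diary < 1L | diary > 9L)) {
    abort("diary codes must all be in 1..9")
  }
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) || weight <= 0) {
    abort("weight must be a positive scalar (kg)")
  }
  counts <- tabulate(diary, nbins = 9L)
  as.numeric(weight * sum(counts * unclass(costs)) / 3)
}

#' TDEE for a table of diaries
#'
#' Convenience wrapper applying [tdee_from_diary()] per subject to a long
#' diary table.
#'
#' @param diaries Data frame with columns `individual_id`, `day` (1..3) and
#'   `p1`..`p96` (category codes), one row per subject-day.
#' @param weights Data frame with columns `individual_id`, `weight` (kg).
#' @param costs An [energy_cost_table()].
#' @return Tibble with columns `individual_id`, `tdee` (kcal/day).
#' @export
tdee_from_diary_table <- function(diaries, weights, costs = energy_cost_table()) {
  pcols <- paste0("p", 1:96)
  miss <- setdiff(c("individual_id", "day", pcols), names(diaries))
  if (length(miss) > 0) abort(paste0("diary table missing columns: ", paste(head(miss, 4), collapse = ", ")))
  wmap <- setNames(weights$weight, weights$individual_id)
  diaries |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != 3 || !setequal(d$day, 1:3)) {
        abort(paste0("subject ", key$individual_id, " must have exactly days 1..3, got ",
                     paste(sort(d$day), collapse = ",")))
      }
      w <- wmap[[as.character(key$individual_id)]]
      if (is.null(w)) abort(paste0("no weight for subject ", key$individual_id))
      codes <- as.integer(t(as.matrix(d[order(d$day), pcols])))
      tibble::tibble(tdee = tdee_from_diary(codes, w, costs))
    }) |>
    dplyr::ungroup()
}

#' Standardize TDEE to z-scores
#'
#' The interaction model evaluates `exp(gamma * q)` and `exp(-lambda *
#' |q_i - q_j|)`; raw kcal/day values (~2000-3500) would overflow or force
#' minuscule slopes, so TDEE enters the model standardized to mean 0, SD 1
#' (denominator n - 1). The transform is recorded so slopes and decay rates
#' can be reported on both the standardized and the per-1000-kcal/day scale.
#'
#' @param df Data frame with columns `individual_id` and `tdee` (kcal/day).
#' @return Tibble `individual_id`, `tdee`, `q` (z-score), with attributes
#'   `center` and `scale` holding the mean and SD used.
#' @export
standardize_tdee <- function(df) {
  if (!all(c("individual_id", "tdee") %in% names(df))) {
    abort("expected columns individual_id and tdee")
  }
  x <- df$tdee
  if (sum(!is.na(x)) < 2 || length(unique(x[!is.na(x)])) < 2) {
    abort("TDEE is constant or near-empty; the interaction model is unidentifiable")
  }
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  out <- tibble::tibble(individual_id = as.character(df$individual_id),
                        tdee = x, q = (x - m) / s)
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}
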
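#' Read a pedigree file
#'
#' Reads a pedigree in either the classic LINKAGE layout (whitespace-delimited,
#' no header: family, id, father, mother, sex with 1 = male, 2 = female,
#' 0 = unknown) or a headered CSV with columns `family`, `id`, `father`,
#' `mother`, `sex`. Missing parents may be coded `"0"`, an empty string, or
#' `"NA"`; all three are normalized to `NA` internally.
#'
#' @param path Path to the pedigree file.
#' @param dialect `"linkage"` or `"csv"`.
#' @param strict_sex If `TRUE`, unknown sex is forbidden everywhere; by
#'   default it is allowed for founders only.
#' @return A validated pedigree tibble with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex` (one of `"male"`,
#'   `"female"`, `"unknown"`) and `founder`, in input order.
#' @export
read_pedigree <- function(path, dialect = c("linkage", "csv"), strict_sex = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  if (dialect == "linkage") {
    raw <- read.table(path, header = FALSE, colClasses = "character",
                      col.names = c("family", "id", "father", "mother", "sex"))
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    need <- c("family", "id", "father", "mother", "sex")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      abort(paste0("pedigree CSV is missing columns: ", paste(miss, collapse = ", ")))
    }
  }
  as_pedigree(tibble::tibble(
    family_id = as.character(raw$family),
    individual_id = as.character(raw$id),
    father_id = as.character(raw$father),
    mother_id = as.character(raw$mother),
    sex = as.character(raw$sex)
  ), strict_sex = strict_sex)
}

parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    x %in% c("1", "m", "male") ~ "male",
    x %in% c("2", "f", "female") ~ "female",
    x %in% c("0", "u", "unknown", "", "na") | is.na(x) ~ "unknown",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    abort(paste0("unrecognized sex code(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | trimws(x) %in% c("0", "", "NA")] <- NA_character_
  trimws(x)
}

#' Validate a pedigree data frame
#'
#' Checks the structural invariants a family study relies on: ids unique
#' within each family, parent references resolving within the same family,
#' fathers male (or unknown sex), mothers female (or unknown sex), and no
#' individual being its own ancestor. Founders are rows with both parents
#' missing; a single known parent is allowed.
#'
#' @param df Data frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`.
#' @inheritParams read_pedigree
#' @return A pedigree tibble (see [read_pedigree()]), input order preserved.
#' @export
as_pedigree <- function(df, strict_sex = FALSE) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(paste0("pedigree is missing columns: ", paste(miss, collapse = ", ")))

  ped <- tibble::tibble(
    family_id = as.character(df$family_id),
    individual_id = trimws(as.character(df$individual_id)),
    father_id = normalize_parent(df$father_id),
    mother_id = normalize_parent(df$mother_id),
    sex = parse_sex(df$sex)
  )
  if (anyNA(ped$family_id) || anyNA(ped$individual_id) ||
      any(ped$individual_id == "")) {
    abort("family_id and individual_id must be non-missing")
  }

  dup <- ped |>
    dplyr::count(.data$family_id, .data$individual_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate individual id within family: ",
                 paste(dup$family_id, dup$individual_id, sep = ":", collapse = ", ")))
  }

  for (fam in split(ped, ped$family_id)) {
    ids <- fam$individual_id
    for (col in c("father_id", "mother_id")) {
      ref <- fam[[col]]
      bad <- !is.na(ref) & !(ref %in% ids)
      if (any(bad)) {
        abort(paste0("parent id not found in family ", fam$family_id[1], ": ",
                     paste(unique(ref[bad]), collapse = ", "),
                     " (cross-family parent links are not supported)"))
      }
    }
    sex_of <- setNames(fam$sex, ids)
    fa <- fam$father_id[!is.na(fam$father_id)]
    if (any(sex_of[fa] == "female")) {
      abort(paste0("individual listed as father but recorded female in family ",
                   fam$family_id[1], ": ",
                   paste(unique(fa[sex_of[fa] == "female"]), collapse = ", ")))
    }
    mo <- fam$mother_id[!is.na(fam$mother_id)]
    if (any(sex_of[mo] == "male")) {
      abort(paste0("individual listed as mother but recorded male in family ",
                   fam$family_id[1], ": ",
                   paste(unique(mo[sex_of[mo] == "male"]), collapse = ", ")))
    }
    check_acyclic(fam)
  }

  ped$founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  unk <- ped$sex == "unknown" & (if (strict_sex) TRUE else !ped$founder)
  if (any(unk)) {
    abort(paste0("unknown sex not allowed for ",
                 if (strict_sex) "any individual (strict_sex = TRUE): " else "non-founders: ",
                 paste(ped$individual_id[unk], collapse = ", ")))
  }

  class(ped) <- c("fam_pedigree", class(ped))
  ped
}

# Kahn-style topological order of one family; errors on a cycle.
# Returns individual ids with parents before children.
pedigree_order <- function(fam) {
  ids <- fam$individual_id
  placed <- character(0)
  remaining <- seq_len(nrow(fam))
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i) {
      fa <- fam$father_id[i]; mo <- fam$mother_id[i]
      (is.na(fa) || fa %in% placed) && (is.na(mo) || mo %in% placed)
    }, logical(1))]
    if (length(ready) == 0) {
      abort(paste0("pedigree cycle detected in family ", fam$family_id[1],
                   " involving: ", paste(ids[remaining], collapse = ", ")))
    }
    placed <- c(placed, ids[ready])
    remaining <- setdiff(remaining, ready)
  }
  placed
}

check_acyclic <- function(fam) invisible(pedigree_order(fam))

# Tabular-method kinship for one family, on bare vectors (no data-frame
# overhead; used per family by kinship_matrix and the trait simulator).
family_kinship <- function(ids, fa, mo, family_id = "?") {
  n <- length(ids)
  pos <- setNames(seq_len(n), ids)
  fi <- ifelse(is.na(fa), 0L, pos[fa])
  mi <- ifelse(is.na(mo), 0L, pos[mo])
  placed <- logical(n)
  ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!placed & (fi == 0L | placed[pmax(fi, 1L)]) &
                     (mi == 0L | placed[pmax(mi, 1L)]))
    if (length(ready) == 0) {
      abort(paste0("pedigree cycle detected in family ", family_id))
    }
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  K <- matrix(0, n, n)
  for (oi in seq_along(ord)) {
    i <- ord[oi]; f <- fi[i]; m <- mi[i]
    K[i, i] <- if (f > 0 && m > 0) 0.5 * (1 + K[f, m]) else 0.5
    if (oi > 1) for (oj in seq_len(oi - 1)) {
      j <- ord[oj]
      v <- 0
      if (f > 0) v <- v + K[j, f]
      if (m > 0) v <- v + K[j, m]
      K[i, j] <- K[j, i] <- 0.5 * v
    }
  }
  A <- 2 * K
  dimnames(A) <- list(ids, ids)
  A
}

#' Expected additive relationship matrix (2*kinship)
#'
#' Computes twice the kinship coefficient, the expected fraction of alleles
#' shared identical by descent, for every pair of individuals, by the
#' recursive tabular method: processing each family in parental order,
#' `phi(i,i) = (1 + phi(fa_i, mo_i)) / 2` and
#' `phi(i,j) = (phi(fa_i, j) + phi(mo_i, j)) / 2` for j already processed,
#' with missing-parent terms contributing 0. Members of different families
#' are unrelated by construction (value 0), so the matrix is block-diagonal
#' by family. The diagonal is `1 + f` with `f` the inbreeding coefficient.
#'
#' @param ped A pedigree from [read_pedigree()] or [as_pedigree()].
#' @return A symmetric numeric matrix with dimnames equal to the individual
#'   ids, rows/columns in pedigree input order.
#' @export
kinship_matrix <- function(ped) {
  ped <- if (inherits(ped, "fam_pedigree")) ped else as_pedigree(ped)
  ids <- ped$individual_id
  if (anyDuplicated(ids)) {
    abort("individual ids must be globally unique to build a relationship matrix")
  }
  A <- matrix(0, nrow(ped), nrow(ped), dimnames = list(ids, ids))
  for (rows in split(seq_len(nrow(ped)), ped$family_id)) {
    A[rows, rows] <- family_kinship(ids[rows], ped$father_id[rows],
                                    ped$mother_id[rows], ped$family_id[rows[1]])
  }
  A
}

#' Summarize a pedigree and its phenotyped subset
#'
#' Counts individuals by family role (fathers and mothers are individuals who
#' appear as someone's parent; sons and daughters are individuals with at
#' least one recorded parent) and reports the mean number of phenotyped
#' individuals per phenotyped family, the "average family size" of a
#' participation-based family study.
#'
#' @param ped A pedigree.
#' @param phenotyped Character vector of phenotyped individual ids; defaults
#'   to everyone in the pedigree. Ids absent from the pedigree are an error.
#' @return A one-row tibble: `n_families`, `n_phenotyped`, `fathers`,
#'   `mothers`, `sons`, `daughters`, `mean_family_size` (NA if nobody is
#'   phenotyped; report at 1 decimal).
#' @export
family_summary <- function(ped, phenotyped = NULL) {
  ped <- if (inherits(ped, "fam_pedigree")) ped else as_pedigree(ped)
  phenotyped <- phenotyped %||% ped$individual_id
  unknown <- setdiff(phenotyped, ped$individual_id)
  if (length(unknown) > 0) {
    abort(paste0("phenotyped ids absent from pedigree: ",
                 paste(head(unknown, 5), collapse = ", "),
                 if (length(unknown) > 5) ", ..." else ""))
  }
  role <- character(nrow(ped))
  for (ix in split(seq_len(nrow(ped)), ped$family_id)) {
    fam <- ped[ix, ]
    role[ix] <- dplyr::case_when(
      fam$individual_id %in% fam$father_id ~ "father",
      fam$individual_id %in% fam$mother_id ~ "mother",
      !fam$founder & fam$sex == "male" ~ "son",
      !fam$founder & fam$sex == "female" ~ "daughter",
      TRUE ~ "other"
    )
  }
  phen <- ped$individual_id %in% phenotyped
  fam_n <- tapply(phen, ped$family_id, sum)
  fam_n <- fam_n[fam_n > 0]
  tibble::tibble(
    n_families = length(fam_n),
    n_phenotyped = sum(phen),
    fathers = sum(phen & role == "father"),
    mothers = sum(phen & role == "mother"),
    sons = sum(phen & role == "son"),
    daughters = sum(phen & role == "daughter"),
    mean_family_size = if (sum(phen) == 0) NA_real_ else sum(phen) / length(fam_n)
  )
}
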
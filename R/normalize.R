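## Creatinine normalization and Bristol-Stool-Chart stratification.

#' Normalize a urinary concentration to creatinine
#'
#' Divides a urinary analyte concentration (µmol/L) by urinary creatinine
#' (mmol/L) to correct for dilution, yielding µmol analyte per mmol
#' creatinine. Vectorized; recycles scalar creatinine.
#'
#' @param value analyte concentration in µmol/L, non-negative.
#' @param creatinine urinary creatinine in mmol/L, strictly positive.
#' @return concentration in µmol/mmol creatinine.
#' @examples
#' normalize_to_creatinine(10, 2)  # 5
#' @export
normalize_to_creatinine <- function(value, creatinine) {
  if (any(!is.na(value) & value < 0)) {
    stop_migd("analyte values must be non-negative", "migd_domain")
  }
  if (any(!is.na(creatinine) & creatinine <= 0)) {
    stop_migd("creatinine must be positive", "migd_domain")
  }
  value / creatinine
}

#' Normalize all toxin columns of a cohort to creatinine
#'
#' Flips a raw-units cohort to µmol/mmol creatinine. A cohort already in
#' normalized units passes through unchanged (checked no-op). Subjects with
#' missing creatinine cannot be normalized: they are retained, marked in the
#' `norm_excluded` column, and their toxin flags are set to `missing` so no
#' un-normalized value can leak into downstream analyses.
#'
#' @param cohort a `migd_cohort`.
#' @return the cohort in normalized units, with a logical `norm_excluded`
#'   column.
#' @export
normalize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "migd_cohort"))
  if (attr(cohort, "unit_state") == "normalized_umol_per_mmol") {
    if (is.null(cohort$norm_excluded)) cohort$norm_excluded <- FALSE
    return(cohort)
  }
  excl <- is.na(cohort$creatinine)
  for (a in ANALYTES) {
    fcol <- paste0(a, "_flag")
    cohort[[a]][!excl] <- normalize_to_creatinine(cohort[[a]][!excl],
                                                  cohort$creatinine[!excl])
    cohort[[a]][excl] <- NA_real_
    cohort[[fcol]][excl] <- "missing"
  }
  cohort$norm_excluded <- excl
  attr(cohort, "unit_state") <- "normalized_umol_per_mmol"
  cohort
}

#' Assign Bristol Stool Chart phenotype categories
#'
#' Maps BSC types to the three stool phenotypes: types 1-2 are `hard`
#' (slow transit), 3-5 `normal`, and 6-7 `loose` (fast transit). The three
#' categories partition \{1..7\}. Missing or out-of-range types yield `NA`:
#' such subjects belong to the all-group analyses but to no BSC subgroup.
#'
#' @param bsc_type integer vector of BSC types (1-7) or `NA`.
#' @return factor with levels `hard`, `normal`, `loose`.
#' @examples
#' assign_bsc_category(c(1, 4, 7))
#' @export
assign_bsc_category <- function(bsc_type) {
  cat <- rep(NA_character_, length(bsc_type))
  valid <- !is.na(bsc_type) & bsc_type == round(bsc_type) &
    bsc_type >= 1 & bsc_type <= 7
  cat[valid & bsc_type <= 2] <- "hard"
  cat[valid & bsc_type >= 3 & bsc_type <= 5] <- "normal"
  cat[valid & bsc_type >= 6] <- "loose"
  factor(cat, levels = c("hard", "normal", "loose"))
}

#' Member BSC types of each stool phenotype
#' @return named list of integer vectors.
#' @export
bsc_category_members <- function() {
  list(hard = 1:2, normal = 3:5, loose = 6:7)
}
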
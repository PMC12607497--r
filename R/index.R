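## The composite index and its component ratios.
##
## MIGD/OGI = (PCS/TMAO * 100) / (IS/ADMA). PCS/TMAO tracks phenolic
## fermentation against methylamine metabolism; IS/ADMA tracks indolic
## detoxification against host methylation load. SDMA never enters the index.
##
## Two precision modes are exposed because published group-level tables are
## only reproducible by rounding each component ratio half-up to one decimal
## before combining ("report_1dp"), while statistics should use unrounded
## values ("full"). Every result is labelled with its mode.

PRECISION_MODES <- c("full", "report_1dp")

#' Component toxin ratios PCS/TMAO and IS/ADMA
#'
#' @param panel named numeric vector or list with elements `pcs`, `tmao`,
#'   `is`, `adma` (µmol/mmol creatinine; case-insensitive names).
#' @param precision `"full"` (unrounded) or `"report_1dp"` (each ratio
#'   rounded half-up to one decimal, the group-table convention).
#' @param floor denominator floor: TMAO or ADMA at or below it raises a
#'   `migd_near_zero_denominator` error. Default `1e-6` µmol/mmol.
#' @return list of class `migd_ratios` with elements `pcs_tmao`, `is_adma`,
#'   `precision`.
#' @examples
#' compute_ratios(c(pcs = 46.65, tmao = 2.38, is = 52.26, adma = 14.79),
#'                precision = "report_1dp")
#' @export
compute_ratios <- function(panel, precision = c("full", "report_1dp"),
                           floor = 1e-6) {
  precision <- match.arg(precision)
  panel <- as.list(panel)
  names(panel) <- tolower(names(panel))
  need <- INDEX_ANALYTES
  vals <- vapply(need, function(a) {
    v <- panel[[a]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (any(is.na(vals))) {
    stop_migd(paste0("missing analyte(s): ",
                     paste(toupper(need[is.na(vals)]), collapse = ", ")),
              "migd_missing_analyte")
  }
  if (vals[["tmao"]] <= floor || vals[["adma"]] <= floor) {
    stop_migd("TMAO or ADMA at or below the denominator floor",
              "migd_near_zero_denominator")
  }
  pcs_tmao <- vals[["pcs"]] / vals[["tmao"]]
  is_adma <- vals[["is"]] / vals[["adma"]]
  if (precision == "report_1dp") {
    pcs_tmao <- round_half_up(pcs_tmao, 1)
    is_adma <- round_half_up(is_adma, 1)
  }
  structure(list(pcs_tmao = pcs_tmao, is_adma = is_adma,
                 precision = precision),
            class = "migd_ratios")
}

#' Composite index from component ratios
#'
#' Evaluates `(PCS/TMAO * 100) / (IS/ADMA)` on a ratio pair, rounding the
#' result half-up to one decimal in `report_1dp` mode, and attaches the
#' interpretation band.
#'
#' @param ratios a `migd_ratios` object ([compute_ratios()]), or a list with
#'   `pcs_tmao` and `is_adma`.
#' @param precision overrides the precision carried by `ratios` if given.
#' @param floor denominator floor applied to `is_adma`.
#' @return list of class `migd_result`: `value`, `mode`, `precision`, `band`.
#' @examples
#' compute_migd(list(pcs_tmao = 19.6, is_adma = 3.5), precision = "report_1dp")
#' @export
compute_migd <- function(ratios, precision = NULL, floor = 1e-6) {
  precision <- precision %||% (ratios$precision %||% "full")
  precision <- match.arg(precision, PRECISION_MODES)
  if (is.null(ratios$pcs_tmao) || is.null(ratios$is_adma)) {
    stop_migd("ratios must supply pcs_tmao and is_adma", "migd_missing_analyte")
  }
  if (ratios$is_adma <= floor) {
    stop_migd("IS/ADMA at or below the denominator floor",
              "migd_near_zero_denominator")
  }
  value <- ratios$pcs_tmao * 100 / ratios$is_adma
  if (precision == "report_1dp") value <- round_half_up(value, 1)
  structure(list(value = value, mode = "ratio", precision = precision,
                 band = classify_migd(value)),
            class = "migd_result")
}

#' Interpretation band of an index value
#'
#' Classifies index values into the five interpretation bands. The published
#' ranges overlap at their edges (">300" vs ">500", "50-150" vs "150-300");
#' the package resolves them as the left-closed partition
#' `[0,50) [50,150) [150,300) [300,500) [500,Inf)`, with the severe band a
#' sub-range carved out of the high band. A boundary value therefore falls
#' in the upper band (150 is `marked`, 300 is `high`, 500 is `severe`).
#'
#' @param value non-negative numeric vector of index values.
#' @return factor with levels `low`, `mild_moderate`, `marked`, `high`,
#'   `severe`; `NA` values pass through.
#' @examples
#' classify_migd(c(40, 110.8, 238.5, 402.4, 560))
#' @export
classify_migd <- function(value) {
  if (any(!is.na(value) & value < 0)) {
    stop_migd("index values must be non-negative", "migd_domain")
  }
  cut(value, breaks = c(0, 50, 150, 300, 500, Inf), right = FALSE,
      labels = c("low", "mild_moderate", "marked", "high", "severe"))
}

#' Reporting phrases for the interpretation bands
#'
#' @param band factor or character vector of band labels.
#' @return character vector of the full interpretive phrasing used in
#'   report output.
#' @export
migd_band_phrase <- function(band) {
  phrases <- c(
    low = "Low metabolic disruption or compensatory indole pathway activity",
    mild_moderate = "Mild to moderate metabolic imbalance",
    marked = "Marked microbial-host metabolic disturbance",
    high = "High dysfunction-skewed fermentation and impaired detoxification",
    severe = "Severe imbalance-indicates high systemic fermentation burden")
  unname(phrases[as.character(band)])
}

#' Per-subject (individual-level) index values
#'
#' Computes the index for every row of a cohort. Exclusion is a value, not a
#' failure: subjects with any of the four index analytes flagged other than
#' `ok` are excluded with reason `missing_analyte`; subjects whose TMAO or
#' ADMA is at or below `floor` are excluded with `near_zero_denominator`.
#'
#' @param cohort a `migd_cohort` in normalized units, or a data frame with
#'   columns `pcs`, `tmao`, `is`, `adma` (flag columns optional).
#' @param precision `"full"` or `"report_1dp"`.
#' @param floor denominator floor (µmol/mmol), default `1e-6`.
#' @return data frame: `subject_id` (if available), `migd`, `band`,
#'   `excluded`, `exclusion_reason` (`none`, `missing_analyte`,
#'   `near_zero_denominator`), `mode`, `precision`.
#' @export
individual_level_migd <- function(cohort, precision = c("full", "report_1dp"),
                                  floor = 1e-6) {
  precision <- match.arg(precision)
  df <- as.data.frame(cohort)
  n <- nrow(df)
  flag_of <- function(a) {
    f <- df[[paste0(a, "_flag")]]
    if (is.null(f)) ifelse(is.na(df[[a]]), "missing", "ok") else f
  }
  flags_ok <- Reduce(`&`, lapply(INDEX_ANALYTES, function(a) flag_of(a) == "ok" &
                                                            !is.na(df[[a]])))
  reason <- rep("none", n)
  reason[!flags_ok] <- "missing_analyte"
  denom_bad <- flags_ok & (df$tmao <= floor | df$adma <= floor)
  reason[denom_bad] <- "near_zero_denominator"
  eligible <- reason == "none"

  value <- rep(NA_real_, n)
  pcs_tmao <- df$pcs / df$tmao
  is_adma <- df$is / df$adma
  if (precision == "report_1dp") {
    pcs_tmao <- round_half_up(pcs_tmao, 1)
    is_adma <- round_half_up(is_adma, 1)
  }
  value[eligible] <- pcs_tmao[eligible] * 100 / is_adma[eligible]
  if (precision == "report_1dp") value <- round_half_up(value, 1)

  out <- data.frame(migd = value,
                    band = classify_migd(value),
                    excluded = !eligible,
                    exclusion_reason = reason,
                    mode = "individual_level",
                    precision = precision,
                    stringsAsFactors = FALSE)
  if (!is.null(df$subject_id)) out <- cbind(subject_id = df$subject_id, out)
  out
}

#' Group-level index from per-analyte medians
#'
#' The group-table calculation mode: per-analyte medians are taken across
#' the records of a subgroup (each analyte over its own `ok` values), then
#' the component ratios and the index are computed on that median panel.
#'
#' @inheritParams individual_level_migd
#' @return list of class `migd_result` with elements `value`, `mode`
#'   (`group_level`), `precision`, `band`, `ratios`, `medians`, `n`.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' group_level_migd(coh[coh$group == "asd" & coh$bsc_category == "hard", ],
#'                  precision = "report_1dp")
#' @export
group_level_migd <- function(cohort, precision = c("full", "report_1dp"),
                             floor = 1e-6) {
  precision <- match.arg(precision)
  df <- as.data.frame(cohort)
  med <- vapply(INDEX_ANALYTES, function(a) {
    f <- df[[paste0(a, "_flag")]]
    v <- df[[a]]
    if (!is.null(f)) v <- v[f == "ok"]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  if (any(is.na(med))) {
    stop_migd(paste0("no usable values for: ",
                     paste(toupper(INDEX_ANALYTES[is.na(med)]), collapse = ", ")),
              "migd_missing_analyte")
  }
  ratios <- compute_ratios(med, precision = precision, floor = floor)
  res <- compute_migd(ratios, precision = precision, floor = floor)
  res$mode <- "group_level"
  res$ratios <- ratios
  res$medians <- med
  res$n <- nrow(df)
  res
}

#' @export
print.migd_result <- function(x, ...) {
  cat(sprintf("MIGD/OGI = %s  [%s, %s]  band: %s\n",
              format(x$value), x$mode, x$precision, as.character(x$band)))
  if (!is.null(x$ratios)) {
    cat(sprintf("  PCS/TMAO = %s,  IS/ADMA = %s\n",
                format(x$ratios$pcs_tmao), format(x$ratios$is_adma)))
  }
  invisible(x)
}
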
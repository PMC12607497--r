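## Seeded synthetic cohort generator.
##
## Emulates the reference pediatric cohort: subgroup sizes, sex proportions
## and age structure from its published demographics, and per-subgroup
## analyte distributions as log-normals calibrated to the published
## Median (Q1, Q3) summaries. Analyte quartile summaries show Q3 - median >
## median - Q1 throughout, motivating a right-skewed positive family.

#' Fit a log-normal to a median/(Q1, Q3) summary
#'
#' Closed form: `mu = ln(median)`, `sigma = ln(q3/q1) / (2 z)` with
#' `z = qnorm(0.75) = 0.674490`. The fit reproduces the median exactly and
#' the quartile ratio exactly; a two-parameter family cannot also match both
#' quartiles individually.
#'
#' @param median_target,q1_target,q3_target positive quantile targets with
#'   `0 < q1 <= median <= q3`.
#' @return list `mu`, `sigma` (log-scale location and spread).
#' @examples
#' fit_lognormal_quartiles(3.09, 1.48, 5.19)
#' @export
fit_lognormal_quartiles <- function(median_target, q1_target, q3_target) {
  if (q1_target <= 0) stop_migd("q1 must be positive (log undefined at 0)", "migd_domain")
  if (!(q1_target <= median_target && median_target <= q3_target)) {
    stop_migd("need q1 <= median <= q3", "migd_domain")
  }
  z <- stats::qnorm(0.75)
  list(mu = log(median_target), sigma = log(q3_target / q1_target) / (2 * z))
}

## Published per-subgroup Median (Q1, Q3) calibration targets,
## µmol/mmol creatinine. Control BSC strata are not published per subgroup;
## control targets are the all-control values (declared limitation).
analyte_target_table <- function() {
  tg <- rbind(
    c("adma", "control", 12.70, 9.73, 18.74),
    c("sdma", "control", 31.32, 23.01, 38.09),
    c("tmao", "control", 3.09, 1.48, 5.19),
    c("is",   "control", 63.80, 39.77, 103.18),
    c("pcs",  "control", 37.74, 20.02, 80.02),
    c("adma", "asd_all", 14.76, 10.50, 17.03),
    c("sdma", "asd_all", 29.06, 20.10, 39.77),
    c("tmao", "asd_all", 2.64, 1.64, 5.01),
    c("is",   "asd_all", 56.77, 28.22, 89.25),
    c("pcs",  "asd_all", 51.84, 17.07, 86.81),
    c("adma", "asd_hard", 14.79, 10.69, 16.95),
    c("sdma", "asd_hard", 29.09, 20.17, 36.91),
    c("tmao", "asd_hard", 2.38, 1.69, 3.52),
    c("is",   "asd_hard", 52.26, 41.88, 79.10),
    c("pcs",  "asd_hard", 46.65, 29.01, 86.73),
    c("adma", "asd_loose", 8.02, 7.57, 15.15),
    c("sdma", "asd_loose", 19.73, 14.64, 50.79),
    c("tmao", "asd_loose", 2.60, 0.04, 3.81),
    c("is",   "asd_loose", 89.25, 23.98, 108.77),
    c("pcs",  "asd_loose", 31.85, 9.09, 140.45),
    c("adma", "asd_normal", 15.09, 11.32, 19.54),
    c("sdma", "asd_normal", 29.08, 23.16, 44.29),
    c("tmao", "asd_normal", 3.19, 1.67, 5.53),
    c("is",   "asd_normal", 61.52, 27.95, 89.20),
    c("pcs",  "asd_normal", 52.65, 15.80, 84.76))
  data.frame(analyte = tg[, 1], subgroup = tg[, 2],
             median = as.numeric(tg[, 3]), q1 = as.numeric(tg[, 4]),
             q3 = as.numeric(tg[, 5]), stringsAsFactors = FALSE)
}

#' Published group-level component ratios of the reference cohort
#'
#' The group-level ratio/index table as published for the reference cohort
#' (ratios rounded to one decimal); useful as a cross-check against
#' [group_level_migd()] in `report_1dp` mode. The controls row was computed
#' from an unpublished control BSC 3-5 subgroup, so only its ratio-to-index
#' step is reproducible from these numbers.
#'
#' @return data frame: `subgroup`, `pcs_tmao`, `is_adma`, `migd`.
#' @export
reference_group_ratios <- function() {
  data.frame(
    subgroup = c("control_normal", "asd_normal", "asd_loose", "asd_hard"),
    pcs_tmao = c(12.4, 16.5, 12.3, 19.6),
    is_adma = c(5.2, 4.1, 11.1, 3.5),
    migd = c(238.5, 402.4, 110.8, 560.0),
    stringsAsFactors = FALSE)
}

#' Construct a cohort simulation specification
#'
#' @param subgroup_sizes named integer vector over the generation subgroups
#'   (`control`, `asd_hard`, `asd_loose`, `asd_normal`).
#' @param sex_proportions named numeric vector: fraction of boys per subgroup.
#' @param age_model named list per subgroup: `c(mean, sd, min, max)` in years;
#'   ages are drawn truncated-normal on `[min, max]`.
#' @param analyte_targets data frame `analyte`, `subgroup`, `median`, `q1`,
#'   `q3` (µmol/mmol creatinine).
#' @param control_bsc_types integer BSC types sampled uniformly for control
#'   subjects (the reference cohort publishes no control BSC breakdown; its
#'   group-ratio table labels controls as BSC 3-5).
#' @param loq_censoring optional named per-analyte lower threshold; simulated
#'   values below it are flagged `below_loq`.
#' @param missingness_rate probability in `[0,1)` that an analyte value is
#'   replaced by a `missing` flag, independently per cell.
#' @param correlation optional log-scale correlation matrix across the five
#'   analytes (default identity: analytes independent within subject).
#' @return list of class `migd_cohort_spec`.
#' @export
cohort_spec <- function(subgroup_sizes, sex_proportions, age_model,
                        analyte_targets, control_bsc_types = 3:5,
                        loq_censoring = NULL, missingness_rate = 0,
                        correlation = NULL) {
  stopifnot(all(subgroup_sizes > 0),
            all(sex_proportions >= 0 & sex_proportions <= 1),
            missingness_rate >= 0, missingness_rate < 1)
  for (m in age_model) stopifnot(length(m) == 4, m[3] <= m[4], m[2] >= 0)
  need <- expand.grid(analyte = ANALYTES,
                      subgroup = names(subgroup_sizes),
                      stringsAsFactors = FALSE)
  have <- paste(analyte_targets$analyte, analyte_targets$subgroup)
  gap <- !(paste(need$analyte, need$subgroup) %in% have)
  if (any(gap)) {
    stop_migd(paste0("analyte targets missing for: ",
                     paste(paste(need$analyte, need$subgroup)[gap], collapse = "; ")),
              "migd_domain")
  }
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation),
              nrow(correlation) == length(ANALYTES),
              isTRUE(all.equal(correlation, t(correlation))))
  }
  structure(list(subgroup_sizes = subgroup_sizes,
                 sex_proportions = sex_proportions,
                 age_model = age_model,
                 analyte_targets = analyte_targets,
                 control_bsc_types = control_bsc_types,
                 loq_censoring = loq_censoring,
                 missingness_rate = missingness_rate,
                 correlation = correlation),
            class = "migd_cohort_spec")
}

#' Default specification: the reference cohort
#'
#' Encodes the reference study conditions: 97 ASD children (28 hard-stool,
#' 8 loose, 61 normal) and 71 controls; per-subgroup boy fractions and
#' truncated-normal age models from the published demographics table; and
#' per-subgroup analyte quartile targets from the published concentration
#' table (control BSC strata fall back to the all-control summary).
#'
#' @return a `migd_cohort_spec`.
#' @examples
#' spec <- default_cohort_spec()
#' spec$subgroup_sizes
#' @export
default_cohort_spec <- function() {
  tg <- analyte_target_table()
  tg <- tg[tg$subgroup != "asd_all", ]
  sub <- c("control", "asd_hard", "asd_loose", "asd_normal")
  tg$subgroup <- factor(tg$subgroup, levels = sub)
  tg$subgroup <- as.character(tg$subgroup)
  cohort_spec(
    subgroup_sizes = c(control = 71L, asd_hard = 28L, asd_loose = 8L,
                       asd_normal = 61L),
    sex_proportions = c(control = 0.521, asd_hard = 0.607, asd_loose = 0.625,
                        asd_normal = 0.885),
    age_model = list(control = c(8.93, 3.82, 2.40, 16.70),
                     asd_hard = c(9.76, 4.21, 3.50, 17.00),
                     asd_loose = c(9.88, 3.15, 4.60, 13.20),
                     asd_normal = c(9.24, 3.68, 2.50, 16.70)),
    analyte_targets = tg)
}

## inverse-CDF truncated normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a cohort
#'
#' Deterministic given `spec` and `seed`. Per subject: subgroup membership
#' per the spec sizes (BSC type uniform within the phenotype's member
#' types), sex Bernoulli on the boy fraction, age truncated-normal, each
#' analyte log-normal with parameters fitted to its subgroup quartile
#' targets ([fit_lognormal_quartiles()]); optional LOQ censoring and
#' missingness are applied last. Output is in normalized units
#' (µmol/mmol creatinine); a log-normal creatinine column (median 10
#' mmol/L) is carried for completeness — the composite index is invariant
#' to it.
#'
#' @param spec a `migd_cohort_spec` (default [default_cohort_spec()]).
#' @param seed integer RNG seed, recorded in the cohort provenance.
#' @param size_multiplier scales every subgroup size (calibration studies).
#' @return a `migd_cohort`.
#' @examples
#' coh <- simulate_cohort(seed = 42)
#' table(coh$group)
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), seed = 1,
                            size_multiplier = 1) {
  stopifnot(inherits(spec, "migd_cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  members <- bsc_category_members()
  sizes <- ceiling(spec$subgroup_sizes * size_multiplier)
  chunks <- lapply(names(sizes), function(sg) {
    n <- sizes[[sg]]
    group <- if (sg == "control") "control" else "asd"
    bsc_pool <- if (sg == "control") {
      spec$control_bsc_types
    } else {
      members[[sub("^asd_", "", sg)]]
    }
    am <- spec$age_model[[sg]]
    d <- data.frame(
      group = group,
      sex = ifelse(stats::runif(n) < spec$sex_proportions[[sg]], "boy", "girl"),
      age_years = round(rtruncnorm(n, am[1], am[2], am[3], am[4]), 2),
      bsc_type = sample(rep(bsc_pool, 2), n, replace = TRUE),
      creatinine = stats::rlnorm(n, log(10), 0.4),
      stringsAsFactors = FALSE)
    ## analytes: correlated standard normals on the log scale, then scaled
    z <- matrix(stats::rnorm(n * length(ANALYTES)), nrow = n)
    if (!is.null(spec$correlation)) z <- z %*% chol(spec$correlation)
    for (j in seq_along(ANALYTES)) {
      a <- ANALYTES[j]
      t <- spec$analyte_targets[spec$analyte_targets$analyte == a &
                                  spec$analyte_targets$subgroup == sg, ]
      par <- fit_lognormal_quartiles(t$median, t$q1, t$q3)
      d[[a]] <- exp(par$mu + par$sigma * z[, j])
      d[[paste0(a, "_flag")]] <- "ok"
    }
    d
  })
  d <- do.call(rbind, chunks)
  d$subject_id <- sprintf("S%05d", seq_len(nrow(d)))

  for (a in ANALYTES) {
    loq <- spec$loq_censoring[[a]]
    if (!is.null(loq)) {
      cens <- d[[a]] < loq
      d[[a]][cens] <- NA_real_
      d[[paste0(a, "_flag")]][cens] <- "below_loq"
    }
    if (spec$missingness_rate > 0) {
      miss <- stats::runif(nrow(d)) < spec$missingness_rate
      d[[a]][miss] <- NA_real_
      d[[paste0(a, "_flag")]][miss] <- "missing"
    }
  }

  ## serialize through the validating constructor (flags survive because
  ## NA values with non-ok flags are re-derived from the flag columns)
  out <- d[, c("subject_id", "group", "sex", "age_years", "bsc_type",
               "creatinine", ANALYTES)]
  coh <- as_migd_cohort(out, unit_state = "normalized_umol_per_mmol",
                        provenance = sprintf("simulate_cohort(seed=%d)", as.integer(seed)))
  for (a in ANALYTES) coh[[paste0(a, "_flag")]] <- d[[paste0(a, "_flag")]]
  coh
}
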
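#' Fit the stool-phenotype-stratified toxin analysis
#'
#' The package's central entry point. Takes a subject-level cohort, ensures
#' creatinine-normalized units and BSC stratification, and computes: the
#' per-subject composite index with exclusion accounting, per-subgroup
#' Median (Q1, Q3) summaries for every analyte and the index, the
#' group-level ratio/index table in reporting precision with interpretation
#' bands, and Kruskal-Wallis comparisons under Benjamini-Hochberg FDR
#' control.
#'
#' @param data a `migd_cohort` ([read_cohort()], [simulate_cohort()],
#'   [as_migd_cohort()]) or a data frame with the canonical columns.
#' @param precision precision mode for the per-subject index: `"full"`
#'   (default, used for statistics) or `"report_1dp"`.
#' @param floor denominator floor in µmol/mmol creatinine; TMAO or ADMA at
#'   or below it excludes a subject with reason `near_zero_denominator`.
#' @param bh_family Benjamini-Hochberg family: `"per_analyte"` (each
#'   variable's comparisons adjusted together, default) or `"global"`.
#' @param omnibus scope of the omnibus "p TOT" test: `"three_subgroup"`
#'   (across the ASD BSC subgroups, default) or `"four_group"` (controls
#'   included).
#' @param alpha nominal significance level recorded in the configuration.
#' @param run_tests set `FALSE` to skip the comparison stage.
#' @return An object of class `"migd"`: a list with components
#'   `cohort` (normalized, stratified), `individual` (per-subject index,
#'   band, exclusion flag and reason), `summaries` (subgroup summary table),
#'   `group_index` (group-level ratios and index per subgroup, reporting
#'   precision, with band phrases), `tests` (comparison table or `NULL`),
#'   `counts` (stage-by-stage subject accounting) and `config`.
#' @examples
#' fit <- migd(simulate_cohort(seed = 7))
#' fit
#' coef(fit)
#' @seealso [summary.migd()], [plot.migd()], [analyze_cohort()]
#' @export
migd <- function(data, precision = c("full", "report_1dp"), floor = 1e-6,
                 bh_family = c("per_analyte", "global"),
                 omnibus = c("three_subgroup", "four_group"),
                 alpha = 0.05, run_tests = TRUE) {
  precision <- match.arg(precision)
  bh_family <- match.arg(bh_family)
  omnibus <- match.arg(omnibus)

  cohort <- if (inherits(data, "migd_cohort")) data else as_migd_cohort(data)
  n_read <- nrow(cohort)
  cohort <- normalize_cohort(cohort)
  n_normalized <- sum(!cohort$norm_excluded)
  n_stratified <- sum(!is.na(cohort$bsc_category))

  individual <- individual_level_migd(cohort, precision = precision,
                                      floor = floor)
  summaries <- subgroup_summaries(cohort, floor = floor)
  group_index <- group_index_table(cohort, floor = floor)
  tests <- if (run_tests) {
    run_comparisons(cohort, bh_family = bh_family, omnibus = omnibus,
                    floor = floor)
  } else NULL

  structure(list(
    cohort = cohort,
    individual = individual,
    summaries = summaries,
    group_index = group_index,
    tests = tests,
    counts = c(read = n_read, normalized = n_normalized,
               stratified = n_stratified,
               migd_eligible = sum(!individual$excluded)),
    config = list(precision = precision, floor = floor,
                  bh_family = bh_family, omnibus = omnibus, alpha = alpha)),
    class = "migd")
}

## group-level ratio/index table (reporting precision) across the five
## reporting subgroups
group_index_table <- function(cohort, floor = 1e-6) {
  df <- as.data.frame(cohort)
  keys <- list(control_all = list(group = "control", category = "all"),
               asd_all = list(group = "asd", category = "all"),
               asd_hard = list(group = "asd", category = "hard"),
               asd_loose = list(group = "asd", category = "loose"),
               asd_normal = list(group = "asd", category = "normal"))
  rows <- lapply(names(keys), function(nm) {
    sel <- subgroup_rows(df, keys[[nm]])
    base <- data.frame(subgroup = nm, n = sum(sel), pcs_tmao = NA_real_,
                       is_adma = NA_real_, migd = NA_real_,
                       band = NA_character_, interpretation = NA_character_,
                       stringsAsFactors = FALSE)
    if (sum(sel) == 0L) return(base)
    res <- tryCatch(group_level_migd(df[sel, , drop = FALSE],
                                     precision = "report_1dp", floor = floor),
                    migd_error = function(e) NULL)
    if (is.null(res)) return(base)
    base$pcs_tmao <- res$ratios$pcs_tmao
    base$is_adma <- res$ratios$is_adma
    base$migd <- res$value
    base$band <- as.character(res$band)
    base$interpretation <- migd_band_phrase(res$band)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.migd <- function(x, ...) {
  cat("Stool-phenotype-stratified urinary toxin analysis\n")
  cat(sprintf("  subjects: %d read, %d normalized, %d with BSC phenotype, %d index-eligible\n",
              x$counts[["read"]], x$counts[["normalized"]],
              x$counts[["stratified"]], x$counts[["migd_eligible"]]))
  cat("\nGroup-level MIGD/OGI (report precision):\n")
  print(x$group_index[, c("subgroup", "n", "pcs_tmao", "is_adma", "migd", "band")],
        row.names = FALSE)
  if (!is.null(x$tests)) {
    mt <- x$tests[x$tests$variable == "MIGD", ]
    if (nrow(mt) > 0L) {
      cat("\nMIGD comparisons (Kruskal-Wallis, BH-adjusted):\n")
      print(data.frame(comparison = mt$comparison,
                       H = round(mt$statistic, 3),
                       p_raw = signif(mt$p_raw, 3),
                       p_adj = signif(mt$p_adjusted, 3)), row.names = FALSE)
    }
  }
  invisible(x)
}

#' Summarize a fitted analysis
#'
#' @param object a fitted `migd` object.
#' @param ... unused.
#' @return list of class `summary.migd`: the subgroup summary table, the
#'   group-level index table, the comparison table, exclusion counts by
#'   reason, and the configuration.
#' @export
summary.migd <- function(object, ...) {
  excl <- table(factor(object$individual$exclusion_reason,
                       levels = c("none", "missing_analyte",
                                  "near_zero_denominator")))
  structure(list(summaries = object$summaries,
                 group_index = object$group_index,
                 tests = object$tests,
                 exclusions = excl,
                 counts = object$counts,
                 config = object$config),
            class = "summary.migd")
}

#' @export
print.summary.migd <- function(x, ...) {
  cat("Subgroup summaries (Median [Q1, Q3]):\n")
  s <- x$summaries
  s$median <- round(s$median, 2); s$q1 <- round(s$q1, 2); s$q3 <- round(s$q3, 2)
  print(s, row.names = FALSE)
  cat("\nGroup-level index table:\n")
  print(x$group_index, row.names = FALSE)
  cat("\nExclusions:\n")
  print(x$exclusions)
  if (!is.null(x$tests)) {
    cat("\nComparisons:\n")
    t <- x$tests
    t$statistic <- round(t$statistic, 3)
    t$p_raw <- signif(t$p_raw, 3); t$p_adjusted <- signif(t$p_adjusted, 3)
    print(t, row.names = FALSE)
  }
  invisible(x)
}

#' Group-level index values of a fitted analysis
#'
#' @param object a fitted `migd` object.
#' @param ... unused.
#' @return named numeric vector of group-level index values (reporting
#'   precision) by subgroup.
#' @export
coef.migd <- function(object, ...) {
  stats::setNames(object$group_index$migd, object$group_index$subgroup)
}

#' Per-subject index values and residual-style diagnostics
#'
#' @param object a fitted `migd` object.
#' @param ... unused.
#' @return numeric vector of per-subject index values (`NA` for excluded
#'   subjects), named by subject identifier.
#' @export
fitted.migd <- function(object, ...) {
  stats::setNames(object$individual$migd, object$individual$subject_id)
}

#' Box plot of the index by subgroup
#'
#' Draws log10 individual-level index values by analysis subgroup, with the
#' interpretation band boundaries as reference lines.
#'
#' @param x a fitted `migd` object.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.migd <- function(x, ...) {
  df <- as.data.frame(x$cohort)
  v <- x$individual$migd
  grp <- ifelse(df$group == "control", "control",
                paste0("asd_", as.character(df$bsc_category)))
  grp[df$group == "asd" & is.na(df$bsc_category)] <- "asd_unstratified"
  keep <- !is.na(v) & v > 0
  graphics::boxplot(log10(v[keep]) ~ factor(grp[keep]),
                    ylab = "log10 MIGD/OGI", xlab = "subgroup", ...)
  graphics::abline(h = log10(c(50, 150, 300, 500)), lty = 3, col = "grey50")
  invisible(x)
}
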
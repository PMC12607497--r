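## Report builders: chain the stages into the full analysis and emit the
## table analogues as CSV plus a machine-readable JSON summary. A thin CLI
## over these functions ships at inst/cli/migd.R (subcommands simulate,
## analyze, classify).

#' Simulate a cohort to disk
#'
#' Writes a simulated cohort CSV plus a provenance JSON (seed, subgroup
#' sizes, package version).
#'
#' @param output_dir directory, created if absent.
#' @param spec a `migd_cohort_spec`.
#' @param seed integer RNG seed.
#' @return paths of the files written, invisibly.
#' @export
simulate_cohort_files <- function(output_dir, spec = default_cohort_spec(),
                                  seed = 1) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- simulate_cohort(spec, seed = seed)
  cohort_path <- file.path(output_dir, "cohort.csv")
  write_cohort(coh, cohort_path)
  prov <- list(seed = as.integer(seed),
               subgroup_sizes = as.list(spec$subgroup_sizes),
               missingness_rate = spec$missingness_rate,
               n_subjects = nrow(coh),
               package_version = as.character(utils::packageVersion("migdr")))
  prov_path <- file.path(output_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(cohort = cohort_path, provenance = prov_path))
}

#' Run the full analysis and write the report bundle
#'
#' Runs [migd()] and writes: `table1.csv` (per-analyte Median (Q1, Q3) by
#' subgroup), `table2.csv` (individual-level index summaries with exclusion
#' counts), `table3.csv` (group-level ratios and index in reporting
#' precision with interpretation phrases), `tests.csv` (all comparisons)
#' and `summary.json` (counts, configuration, exclusions, version).
#'
#' @param cohort a `migd_cohort`, a fitted `migd` object, or a cohort CSV
#'   path.
#' @param output_dir directory, created if absent.
#' @param ... passed to [migd()] when `cohort` is not already fitted.
#' @return the fitted `migd` object, invisibly.
#' @export
analyze_cohort <- function(cohort, output_dir, ...) {
  fit <- if (inherits(cohort, "migd")) {
    cohort
  } else {
    if (is.character(cohort)) cohort <- read_cohort(cohort)
    migd(cohort, ...)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  t1 <- fit$summaries[fit$summaries$variable != "MIGD", ]
  write_report_csv(t1, file.path(output_dir, "table1.csv"))

  t2 <- fit$summaries[fit$summaries$variable == "MIGD", ]
  excl <- fit$individual
  t2$n_excluded_missing <- NA_integer_
  t2$n_excluded_denominator <- NA_integer_
  df <- as.data.frame(fit$cohort)
  for (i in seq_len(nrow(t2))) {
    sel <- subgroup_rows(df, list(group = t2$group[i], category = t2$category[i]))
    t2$n_excluded_missing[i] <- sum(excl$exclusion_reason[sel] == "missing_analyte")
    t2$n_excluded_denominator[i] <- sum(excl$exclusion_reason[sel] == "near_zero_denominator")
  }
  write_report_csv(t2, file.path(output_dir, "table2.csv"))

  write_report_csv(fit$group_index, file.path(output_dir, "table3.csv"))
  if (!is.null(fit$tests)) {
    write_report_csv(as.data.frame(fit$tests), file.path(output_dir, "tests.csv"))
  }

  summary_json <- list(
    counts = as.list(fit$counts),
    exclusions = list(
      missing_analyte = sum(fit$individual$exclusion_reason == "missing_analyte"),
      near_zero_denominator = sum(fit$individual$exclusion_reason == "near_zero_denominator")),
    config = fit$config,
    skipped_comparisons = if (!is.null(fit$tests) &&
                              !is.null(attr(fit$tests, "skipped"))) {
      nrow(attr(fit$tests, "skipped"))
    } else 0L,
    package_version = as.character(utils::packageVersion("migdr")))
  jsonlite::write_json(summary_json, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fit)
}

write_report_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- ifelse(is.na(df[[j]]), "",
                                          format(df[[j]], digits = 10,
                                                 trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Classify index values into interpretation bands
#'
#' @param values numeric vector of index values, or the path of a one-column
#'   text file of values.
#' @return data frame: `value`, `band`, `interpretation`; negative inputs
#'   yield an `error` row instead of a band.
#' @examples
#' classify_values(c(560, 40))
#' @export
classify_values <- function(values) {
  if (is.character(values) && length(values) == 1L && file.exists(values)) {
    values <- as.numeric(readLines(values, warn = FALSE))
  }
  values <- as.numeric(values)
  ok <- !is.na(values) & values >= 0
  band <- rep(NA_character_, length(values))
  band[ok] <- as.character(classify_migd(values[ok]))
  data.frame(value = values,
             band = band,
             interpretation = ifelse(ok, migd_band_phrase(band),
                                     "error: value must be a non-negative number"),
             stringsAsFactors = FALSE)
}
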
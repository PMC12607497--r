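## Subgroup summaries, non-parametric comparisons, FDR control, power.

#' Median and quartiles
#'
#' Linear-interpolation quantiles (type 7, the default convention of
#' mainstream statistics environments) at probabilities 0.25, 0.5, 0.75.
#'
#' @param values numeric vector with at least one finite value; `NA`s dropped.
#' @return named numeric vector `c(median, q1, q3)`.
#' @export
median_quartiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop_migd("no finite values", "migd_domain")
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Wraps [stats::kruskal.test()] (tie-corrected H, chi-square reference with
#' k-1 df), adding the degenerate convention: when all pooled values are
#' identical the statistic is undefined and the test reports `H = 0, p = 1`
#' with `degenerate = TRUE`. With two groups this is the rank test used for
#' pairwise subgroup-versus-control comparisons.
#'
#' @param groups list of two or more numeric vectors, each non-empty.
#' @return list: `statistic` (H), `df`, `p_value`, `method`, `degenerate`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop_migd("each group needs at least one value", "migd_domain")
  }
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L) stop_migd("need total n >= 3", "migd_domain")
  k <- length(groups)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = 0, df = k - 1L, p_value = 1,
                method = "kruskal_wallis", degenerate = TRUE))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "kruskal_wallis", degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, via
#' [stats::p.adjust()]; output order matches input. Inputs outside `[0,1]`
#' are fatal.
#'
#' @param p_values numeric vector of raw p-values in `[0,1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_migd("p-values must lie in [0,1]", "migd_domain")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Power of a two-sided two-sample t test
#'
#' Noncentral-t power function for equal group sizes at standardized effect
#' `d` (Cohen's d).
#'
#' @param n per-group sample size (>= 2).
#' @param d standardized effect size, positive.
#' @param alpha two-sided significance level.
#' @return power in (0,1).
#' @export
t_test_power <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  crit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
}

#' Per-group sample size for a two-sample t test
#'
#' Smallest integer n per group at which a two-sided two-sample t test
#' (equal groups, noncentral-t power function) attains the requested power
#' for standardized effect `effect_size_d`. A moderate effect in the
#' Cohen convention is d = 0.5, which yields 64 per group at alpha 0.05 and
#' power 0.80.
#'
#' @param effect_size_d Cohen's d, positive.
#' @param alpha two-sided significance level in (0,1).
#' @param power target power in (0,1).
#' @param n_max search ceiling; exceeding it is fatal (unattainable power).
#' @return integer n per group.
#' @examples
#' sample_size_two_group(0.5, 0.05, 0.80)  # 64
#' @export
sample_size_two_group <- function(effect_size_d, alpha = 0.05, power = 0.80,
                                  n_max = 1e6) {
  stopifnot(effect_size_d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  ## seed the integer search from the closed-form approximation
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- max(2L, floor(2 * (z / effect_size_d)^2) - 2L)
  while (n <= n_max && t_test_power(n, effect_size_d, alpha) < power) {
    n <- n + 1L
  }
  if (n > n_max) stop_migd("requested power unattainable within n_max", "migd_domain")
  ## the approximation may overshoot; walk back to the smallest sufficient n
  while (n > 2L && t_test_power(n - 1L, effect_size_d, alpha) >= power) {
    n <- n - 1L
  }
  as.integer(n)
}

#' Per-subgroup summary statistics
#'
#' Median and (Q1, Q3) with n for each analyte and for the individual-level
#' index, by group and BSC phenotype, plus the all-subjects column of each
#' group. Values flagged other than `ok` (and index exclusions) do not enter
#' the summaries; `n` counts the values actually summarized.
#'
#' @param cohort a normalized `migd_cohort`.
#' @param floor denominator floor for the individual-level index.
#' @return data frame: `group`, `category` (`all`, `hard`, `normal`,
#'   `loose`), `variable`, `n`, `median`, `q1`, `q3`.
#' @export
subgroup_summaries <- function(cohort, floor = 1e-6) {
  df <- as.data.frame(cohort)
  ind <- individual_level_migd(cohort, precision = "full", floor = floor)
  df$migd <- ind$migd
  vars <- c(ANALYTES, "migd")
  keys <- subgroup_keys(df)
  rows <- lapply(keys, function(k) {
    sel <- subgroup_rows(df, k)
    do.call(rbind, lapply(vars, function(v) {
      vals <- df[[v]][sel]
      if (v %in% ANALYTES) vals[df[[paste0(v, "_flag")]][sel] != "ok"] <- NA
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) {
        data.frame(group = k$group, category = k$category, variable = toupper(v),
                   n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        mq <- median_quartiles(vals)
        data.frame(group = k$group, category = k$category, variable = toupper(v),
                   n = length(vals), median = mq[["median"]], q1 = mq[["q1"]],
                   q3 = mq[["q3"]], stringsAsFactors = FALSE)
      }
    }))
  })
  out <- do.call(rbind, rows)
  out$variable[out$variable == "MIGD"] <- "MIGD"
  rownames(out) <- NULL
  out
}

subgroup_keys <- function(df) {
  keys <- list(list(group = "control", category = "all"),
               list(group = "asd", category = "all"))
  for (cat in c("hard", "loose", "normal")) {
    keys[[length(keys) + 1L]] <- list(group = "asd", category = cat)
  }
  keys
}

subgroup_rows <- function(df, key) {
  sel <- df$group == key$group
  if (key$category != "all") {
    sel <- sel & !is.na(df$bsc_category) & df$bsc_category == key$category
  }
  sel
}

#' Group comparisons with FDR control
#'
#' Runs, for each analyte and for the individual-level index (full
#' precision): control vs ASD (all); control vs each ASD BSC subgroup; and
#' the omnibus "p TOT" across subgroups (the three ASD subgroups by default,
#' or the four groups including controls). All comparisons use the
#' tie-corrected Kruskal-Wallis test; Benjamini-Hochberg adjustment is
#' applied within the family configured (per variable by default, or one
#' global family). Comparisons against an empty subgroup are skipped with a
#' diagnostic.
#'
#' @param cohort a normalized `migd_cohort`.
#' @param variables variables to test; default all five analytes plus `MIGD`.
#' @param bh_family `"per_analyte"` (default) or `"global"`.
#' @param omnibus `"three_subgroup"` (default) or `"four_group"`.
#' @param floor denominator floor for the index.
#' @return data frame of class `migd_tests`: `variable`, `comparison`,
#'   `statistic`, `df`, `p_raw`, `p_adjusted`, `method`, `adjustment`;
#'   skipped comparisons in `attr(x, "skipped")`.
#' @export
run_comparisons <- function(cohort,
                            variables = c(toupper(ANALYTES), "MIGD"),
                            bh_family = c("per_analyte", "global"),
                            omnibus = c("three_subgroup", "four_group"),
                            floor = 1e-6) {
  bh_family <- match.arg(bh_family)
  omnibus <- match.arg(omnibus)
  df <- as.data.frame(cohort)
  ind <- individual_level_migd(cohort, precision = "full", floor = floor)
  df$migd <- ind$migd

  pull <- function(v, sel) {
    col <- tolower(v)
    vals <- df[[col]][sel]
    if (col %in% ANALYTES) vals[df[[paste0(col, "_flag")]][sel] != "ok"] <- NA
    vals[!is.na(vals)]
  }
  sel_control <- df$group == "control"
  sel_asd_all <- df$group == "asd"
  sel_cat <- lapply(c(hard = "hard", loose = "loose", normal = "normal"),
                    function(cat) sel_asd_all & !is.na(df$bsc_category) &
                      df$bsc_category == cat)

  rows <- list()
  skipped <- list()
  for (v in variables) {
    add <- function(comparison, groups) {
      if (any(vapply(groups, length, integer(1)) == 0L)) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          variable = v, comparison = comparison,
          reason = "empty group", stringsAsFactors = FALSE)
        return(invisible())
      }
      kw <- kruskal_wallis(groups)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = v, comparison = comparison, statistic = kw$statistic,
        df = kw$df, p_raw = kw$p_value, p_adjusted = NA_real_,
        method = kw$method, adjustment = "benjamini_hochberg",
        stringsAsFactors = FALSE)
    }
    ctrl <- pull(v, sel_control)
    add("control_vs_asd_all", list(ctrl, pull(v, sel_asd_all)))
    for (cat in names(sel_cat)) {
      add(paste0("control_vs_asd_", cat), list(ctrl, pull(v, sel_cat[[cat]])))
    }
    omni_groups <- lapply(sel_cat, function(s) pull(v, s))
    if (omnibus == "four_group") omni_groups <- c(list(ctrl), omni_groups)
    nonempty <- vapply(omni_groups, length, integer(1)) > 0L
    if (sum(nonempty) >= 2L) {
      omni_groups <- omni_groups[nonempty]
      kw <- kruskal_wallis(omni_groups)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, comparison = "p_tot", statistic = kw$statistic,
        df = kw$df, p_raw = kw$p_value, p_adjusted = NA_real_,
        method = kw$method, adjustment = "benjamini_hochberg",
        stringsAsFactors = FALSE)
    } else {
      skipped[[length(skipped) + 1L]] <- data.frame(
        variable = v, comparison = "p_tot", reason = "fewer than 2 non-empty groups",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), comparison = character(),
               statistic = numeric(), df = numeric(), p_raw = numeric(),
               p_adjusted = numeric(), method = character(),
               adjustment = character(), stringsAsFactors = FALSE)
  if (bh_family == "global") {
    out$p_adjusted <- bh_adjust(out$p_raw)
  } else {
    for (v in unique(out$variable)) {
      i <- out$variable == v
      out$p_adjusted[i] <- bh_adjust(out$p_raw[i])
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("migd_tests", "data.frame"),
            skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
            bh_family = bh_family, omnibus = omnibus)
}
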
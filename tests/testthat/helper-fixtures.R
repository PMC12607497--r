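## In-code fixtures: small canonical cohort data frames.

## one-row-per-subject canonical data frame; toxin args are character so
## sentinels ("", "<LOQ") can be injected directly
make_cohort_df <- function(n = 3,
                           group = rep("control", n),
                           sex = rep("boy", n),
                           age = rep(8, n),
                           bsc = rep(4, n),
                           creatinine = rep(10, n),
                           adma = rep("12.7", n),
                           sdma = rep("31.3", n),
                           tmao = rep("3.09", n),
                           is = rep("63.8", n),
                           pcs = rep("37.7", n)) {
  data.frame(subject_id = sprintf("X%03d", seq_len(n)),
             group = group, sex = sex, age_years = age, bsc_type = bsc,
             creatinine = creatinine, adma = adma, sdma = sdma, tmao = tmao,
             is = is, pcs = pcs, stringsAsFactors = FALSE)
}

## a cohort spec whose four subgroups all share one analyte distribution
## (a global null), at reduced per-subgroup size
null_cohort_spec <- function(n_per_subgroup = 15) {
  spec <- default_cohort_spec()
  tg <- spec$analyte_targets
  ctrl <- tg[tg$subgroup == "control", ]
  tg_null <- do.call(rbind, lapply(unique(tg$subgroup), function(sg) {
    x <- ctrl
    x$subgroup <- sg
    x
  }))
  cohort_spec(subgroup_sizes = stats::setNames(rep(n_per_subgroup, 4),
                                               names(spec$subgroup_sizes)),
              sex_proportions = spec$sex_proportions,
              age_model = spec$age_model,
              analyte_targets = tg_null)
}

## independent hand-computed Kruskal-Wallis H (tie-corrected), straight from
## the rank-sum definition; deliberately not via kruskal.test
oracle_kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}
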
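## Reference subgroup median panels (µmol/mmol creatinine)
panel_hard <- c(pcs = 46.65, tmao = 2.38, is = 52.26, adma = 14.79)
panel_loose <- c(pcs = 31.85, tmao = 2.60, is = 89.25, adma = 8.02)
panel_normal <- c(pcs = 52.65, tmao = 3.19, is = 61.52, adma = 15.09)

test_that("component ratios reproduce the published 1-decimal values", {
  r <- compute_ratios(panel_hard, precision = "report_1dp")
  expect_equal(c(r$pcs_tmao, r$is_adma), c(19.6, 3.5))
  r <- compute_ratios(panel_loose, precision = "report_1dp")
  expect_equal(c(r$pcs_tmao, r$is_adma), c(12.3, 11.1))
  # ratio identity: equal numerator/denominator pairs give (1, 1)
  r <- compute_ratios(c(pcs = 7.3, tmao = 7.3, is = 0.2, adma = 0.2))
  expect_equal(c(r$pcs_tmao, r$is_adma), c(1, 1))
})

test_that("ratio errors carry the exclusion reason", {
  expect_error(compute_ratios(c(pcs = 1, tmao = 0, is = 1, adma = 1)),
               class = "migd_near_zero_denominator")
  expect_error(compute_ratios(c(pcs = 1, tmao = 1, adma = 1)),
               class = "migd_missing_analyte")
})

test_that("the index formula combines rounded ratios as published", {
  expect_equal(compute_migd(list(pcs_tmao = 19.6, is_adma = 3.5),
                            precision = "report_1dp")$value, 560.0)
  expect_equal(compute_migd(list(pcs_tmao = 12.4, is_adma = 5.2),
                            precision = "report_1dp")$value, 238.5)
  expect_equal(compute_migd(list(pcs_tmao = 1, is_adma = 100),
                            precision = "full")$value, 1.0)
})

test_that("half-up rounding (not banker's) is used throughout", {
  expect_equal(round_half_up(12.25, 1), 12.3)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-12.25, 1), -12.3)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("individual-level values match direct evaluation and flag exclusions", {
  df <- make_cohort_df(3, pcs = rep("46.65", 3), tmao = c("2.38", "0", "2.38"),
                       is = c("52.26", "52.26", ""), adma = rep("14.79", 3))
  out <- individual_level_migd(as_migd_cohort(df))
  expect_equal(out$migd[1], (46.65 / 2.38 * 100) / (52.26 / 14.79),
               tolerance = 1e-12)
  expect_equal(round(out$migd[1], 1), 554.7)
  expect_true(out$excluded[2])
  expect_equal(out$exclusion_reason[2], "near_zero_denominator")
  expect_true(out$excluded[3])
  expect_equal(out$exclusion_reason[3], "missing_analyte")
  expect_equal(out$exclusion_reason[1], "none")
})

test_that("group-level mode equals a sort-based median oracle", {
  set.seed(42)
  n <- 101
  df <- make_cohort_df(n, group = rep("asd", n), bsc = rep(1, n),
                       pcs = as.character(rlnorm(n, 3.8, 0.7)),
                       tmao = as.character(rlnorm(n, 0.9, 0.6)),
                       is = as.character(rlnorm(n, 4.0, 0.6)),
                       adma = as.character(rlnorm(n, 2.7, 0.3)))
  coh <- as_migd_cohort(df)
  res <- group_level_migd(coh, precision = "full")

  # oracle: sort each analyte, take the middle element, apply the formula
  mid <- function(x) sort(x)[(n + 1) / 2]
  m <- vapply(c("pcs", "tmao", "is", "adma"), function(a) mid(coh[[a]]), 1)
  expect_equal(res$value,
               (m[["pcs"]] / m[["tmao"]] * 100) / (m[["is"]] / m[["adma"]]))
  expect_equal(res$mode, "group_level")

  # mode agreement on singletons
  one <- coh[1, , drop = FALSE]
  expect_equal(group_level_migd(one, precision = "full")$value,
               individual_level_migd(one, precision = "full")$migd)
})

test_that("group-level mode on reference medians reproduces the published table", {
  # duplicated median panel: medians equal the panel itself
  df <- make_cohort_df(2, group = rep("asd", 2), bsc = c(1, 2),
                       pcs = rep("46.65", 2), tmao = rep("2.38", 2),
                       is = rep("52.26", 2), adma = rep("14.79", 2))
  res <- group_level_migd(as_migd_cohort(df), precision = "report_1dp")
  expect_equal(res$value, 560.0)
  expect_equal(as.character(res$band), "severe")
})

test_that("banding is a left-closed exhaustive partition with the published labels", {
  expect_equal(as.character(classify_migd(c(0, 49.99, 50, 149.9, 150, 299.9,
                                            300, 499.9, 500, 560, 1e6))),
               c("low", "low", "mild_moderate", "mild_moderate", "marked",
                 "marked", "high", "high", "severe", "severe", "severe"))
  expect_error(classify_migd(-1), class = "migd_domain")
  # every non-negative value lands in exactly one band
  set.seed(3)
  v <- c(runif(500, 0, 1000), 50, 150, 300, 500)
  expect_false(anyNA(classify_migd(v)))
  expect_match(migd_band_phrase("severe"), "Severe imbalance")
  expect_match(migd_band_phrase("low"), "Low metabolic disruption")
})

test_that("the index is scale-invariant and monotone in each analyte", {
  set.seed(99)
  n <- 10000
  pcs <- rlnorm(n, 3.5, 1); tmao <- rlnorm(n, 1, 1)
  is <- rlnorm(n, 4, 1); adma <- rlnorm(n, 2.6, 0.5)
  migd_of <- function(pcs, tmao, is, adma) (pcs / tmao * 100) / (is / adma)
  base <- migd_of(pcs, tmao, is, adma)

  # creatinine/scale invariance: common factor cancels
  c0 <- rlnorm(n, 0, 1)
  expect_equal(migd_of(pcs * c0, tmao * c0, is * c0, adma * c0), base,
               tolerance = 1e-9)

  # strict monotonicity directions
  eps <- 1.01
  expect_true(all(migd_of(pcs * eps, tmao, is, adma) > base))
  expect_true(all(migd_of(pcs, tmao, is, adma * eps) > base))
  expect_true(all(migd_of(pcs, tmao * eps, is, adma) < base))
  expect_true(all(migd_of(pcs, tmao, is * eps, adma) < base))

  # the same invariance holds through the package path on a sample of panels
  idx <- seq_len(200)
  df <- make_cohort_df(200, pcs = as.character(pcs[idx]),
                       tmao = as.character(tmao[idx]),
                       is = as.character(is[idx]),
                       adma = as.character(adma[idx]))
  v1 <- individual_level_migd(as_migd_cohort(df))$migd
  df2 <- df
  for (a in c("pcs", "tmao", "is", "adma")) {
    df2[[a]] <- as.character(as.numeric(df[[a]]) * c0[idx])
  }
  v2 <- individual_level_migd(as_migd_cohort(df2))$migd
  expect_equal(v1, v2, tolerance = 1e-9)
})
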
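test_that("median_quartiles uses linear-interpolation quantiles", {
  expect_equal(median_quartiles(5), c(median = 5, q1 = 5, q3 = 5))
  expect_equal(median_quartiles(c(1, 2, 3, 4, 5)), c(median = 3, q1 = 2, q3 = 4))
  expect_error(median_quartiles(numeric(0)), class = "migd_domain")
  expect_equal(median_quartiles(c(NA, 1, 2, 3, 4, 5))[["median"]], 3)
})

test_that("Kruskal-Wallis matches an exhaustive enumeration oracle on 6 observations", {
  vals <- c(1, 2, 3, 4, 5, 6)
  splits <- utils::combn(6, 3)
  for (j in seq_len(ncol(splits))) {
    g1 <- vals[splits[, j]]
    g2 <- vals[-splits[, j]]
    kw <- kruskal_wallis(list(g1, g2))
    expect_equal(kw$statistic, oracle_kw_h(list(g1, g2)), tolerance = 1e-12)
  }
  # exact permutation p of the most extreme split: 2 of 20 assignments
  # reach H >= observed
  h_obs <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic
  h_all <- apply(splits, 2, function(ix) oracle_kw_h(list(vals[ix], vals[-ix])))
  expect_equal(mean(h_all >= h_obs - 1e-12), 2 / 20)

  # and with ties present the tie-corrected H still agrees
  tied <- c(1, 1, 2, 2, 3, 3)
  kw <- kruskal_wallis(list(tied[1:3], tied[4:6]))
  expect_equal(kw$statistic, oracle_kw_h(list(tied[1:3], tied[4:6])),
               tolerance = 1e-12)
})

test_that("degenerate and symmetric inputs follow the tie conventions", {
  kw <- kruskal_wallis(list(c(1, 1, 1), c(1, 1)))
  expect_true(kw$degenerate)
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)

  kw2 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw2$statistic, 0)
  expect_equal(kw2$p_value, 1)
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), class = "migd_domain")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(8)
  for (rep in 1:20) {
    g <- list(rnorm(7), rnorm(5), rnorm(9))
    h1 <- kruskal_wallis(g)$statistic
    h2 <- kruskal_wallis(lapply(g, function(x) exp(3 * x) + 1))$statistic
    expect_equal(h1, h2, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand rule: adjusted_i = min over j with p_(j) >= p_(i) of m * p_(j) / j
  set.seed(4)
  p <- runif(9)
  m <- length(p)
  o <- order(p)
  hand <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) hand[i] <- min(pmin(1, m * sorted[i:m] / (i:m)))
  expect_equal(bh_adjust(p)[o], hand)
  # monotone, never decreases, preserves ranking
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[o]), seq_len(m))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "migd_domain")
})

test_that("sample size search matches the noncentral-t model and power.t.test", {
  expect_equal(sample_size_two_group(0.5, 0.05, 0.80), 64L)
  expect_equal(sample_size_two_group(0.8, 0.05, 0.80), 26L)
  # minimality: one fewer subject per group falls short
  expect_lt(t_test_power(63, 0.5), 0.80)
  expect_gte(t_test_power(64, 0.5), 0.80)
  expect_lt(t_test_power(25, 0.8), 0.80)
  # independent route: base R's power.t.test solves the same model
  expect_equal(sample_size_two_group(0.5, 0.05, 0.80),
               as.integer(ceiling(power.t.test(delta = 0.5, sd = 1,
                                               sig.level = 0.05,
                                               power = 0.80)$n)))
  # monotonicity properties
  expect_lte(sample_size_two_group(0.6), sample_size_two_group(0.5))
  expect_lte(sample_size_two_group(0.5, alpha = 0.10),
             sample_size_two_group(0.5, alpha = 0.05))
  expect_gte(sample_size_two_group(0.5, power = 0.90),
             sample_size_two_group(0.5, power = 0.80))
  expect_true(all(diff(t_test_power(10:100, 0.5)) > 0))
})

test_that("run_comparisons emits the full comparison scheme with BH families", {
  coh <- simulate_cohort(seed = 21)
  res <- run_comparisons(coh)
  expect_s3_class(res, "migd_tests")
  expect_setequal(unique(res$variable),
                  c("ADMA", "SDMA", "TMAO", "IS", "PCS", "MIGD"))
  expect_setequal(unique(res$comparison),
                  c("control_vs_asd_all", "control_vs_asd_hard",
                    "control_vs_asd_loose", "control_vs_asd_normal", "p_tot"))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(all(res$p_adjusted <= 1))
  # per-analyte family: adjustment within one variable is self-contained
  mt <- res[res$variable == "MIGD", ]
  expect_equal(mt$p_adjusted, bh_adjust(mt$p_raw))
  # global family differs in general
  res_g <- run_comparisons(coh, bh_family = "global")
  expect_equal(res_g$p_adjusted, bh_adjust(res_g$p_raw))

  # four-group omnibus has 3 df, three-subgroup has 2
  expect_equal(unique(res$df[res$comparison == "p_tot"]), 2)
  res4 <- run_comparisons(coh, omnibus = "four_group")
  expect_equal(unique(res4$df[res4$comparison == "p_tot"]), 3)
})

test_that("empty subgroups are skipped with a diagnostic, not an error", {
  df <- make_cohort_df(8, group = c(rep("control", 4), rep("asd", 4)),
                       bsc = c(4, 4, 4, 4, 1, 1, 4, 4),
                       tmao = as.character(1:8))
  res <- run_comparisons(as_migd_cohort(df), variables = "TMAO")
  skipped <- attr(res, "skipped")
  expect_true("control_vs_asd_loose" %in% skipped$comparison)
  expect_false("control_vs_asd_loose" %in% res$comparison)
})

test_that("the comparison pipeline controls type-I error under the null", {
  # 500 null cohorts; designated statistic: raw omnibus p for the index
  spec <- null_cohort_spec(n_per_subgroup = 15)
  reps <- 500
  p_omni <- numeric(reps)
  bh_hits <- 0L
  bh_total <- 0L
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(spec, seed = 20000 + r)
    res <- run_comparisons(coh)
    p_omni[r] <- res$p_raw[res$variable == "MIGD" & res$comparison == "p_tot"]
    bh_hits <- bh_hits + sum(res$p_adjusted < 0.05)
    bh_total <- bh_total + nrow(res)
  }
  rate <- mean(p_omni < 0.05)
  envelope <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gte(rate, 0.05 - envelope)
  expect_lte(rate, 0.05 + envelope)
  # BH-significant fraction stays at or below nominal plus simulation error
  expect_lte(bh_hits / bh_total, 0.05 + 2 * sqrt(0.05 * 0.95 / bh_total))
})

test_that("the omnibus test detects a large location shift at the power-note n", {
  # ASD-hard shifted by +2 SD of the control distribution, n = 64/group
  set.seed(77)
  reps <- 200
  hits <- 0L
  for (r in seq_len(reps)) {
    ctrl <- rnorm(64)
    hard <- rnorm(64) + 2
    normal <- rnorm(64)
    p <- kruskal_wallis(list(ctrl, hard, normal))$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / reps, 0.95)
})
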
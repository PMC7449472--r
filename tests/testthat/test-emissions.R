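test_that("total carbonyls sums the six-analyte panel and flags gaps", {
  expect_equal(total_carbonyls(fixture_session(amounts = rep(0, 6))), 0)
  expect_equal(total_carbonyls(fixture_session(amounts = 1:6)), 21)
  s <- fixture_session()
  s$propanal <- NULL
  expect_error(total_carbonyls(s), "propanal")
  s <- fixture_session()
  s$acetone <- NA
  expect_error(total_carbonyls(s), "acetone")
})

test_that("normalization divides by e-liquid consumed and rejects zero", {
  expect_equal(normalize_per_eliquid(
    fixture_session(amounts = rep(21 / 6, 6), eliquid_g = 1)), 21)
  expect_equal(normalize_per_eliquid(
    fixture_session(amounts = rep(10 / 6, 6), eliquid_g = 0.5)), 20)
  expect_error(normalize_per_eliquid(
    fixture_session(eliquid_g = 0)), "positive")
})

test_that("session reader converts nmol to ug and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(fixture_session("ECA", "R1"), fixture_session("ECA", "R2"))
  df$unit <- c("ug", "nmol")
  write.csv(df, path, row.names = FALSE)
  back <- read_sessions(path)
  # row 1 unchanged; row 2 scaled by molar mass / 1000 per analyte
  expect_equal(back$formaldehyde[1], 1)
  expect_equal(back$formaldehyde[2], 1 * 30.026 / 1000)
  expect_equal(back$benzaldehyde[2], 6 * 106.124 / 1000)
  expect_identical(unique(back$unit), "ug")
  # blank analyte cell is an error, not zero
  df2 <- rbind(fixture_session("ECA", "R1"))
  df2$acetone <- NA
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_sessions(path), "acetone")
})

test_that("Grubbs statistic matches hand arithmetic and conventions", {
  # {1,2,3}: mean 2, s = 1, max deviation 1; tie resolves to larger value
  g <- grubbs_statistic(c(1, 2, 3))
  expect_equal(g$G, 1)
  expect_identical(g$index, 3L)
  # zero variance => G = 0
  expect_equal(grubbs_statistic(c(5, 5, 5, 5))$G, 0)
  # {1,2,3,100}: independent arithmetic on mean 26.5 and sample SD
  v <- c(1, 2, 3, 100)
  s_hand <- sqrt(sum((v - 26.5)^2) / 3)
  g <- grubbs_statistic(v)
  expect_equal(g$G, (100 - 26.5) / s_hand)
  expect_identical(g$index, 4L)
  expect_error(grubbs_statistic(c(1, 2)), "n < 3")
})

test_that("Grubbs statistic is invariant under positive affine maps", {
  set.seed(11)
  for (i in 1:25) {
    v <- rnorm(sample(3:12, 1))
    c0 <- runif(1, 0.1, 10); d0 <- runif(1, -5, 5)
    expect_equal(grubbs_statistic(c0 * v + d0)$G, grubbs_statistic(v)$G,
                 tolerance = 1e-10)
  }
})

test_that("Grubbs critical values match the t-quantile formula and tables", {
  # independent coding of the published formula
  for (n in 3:30) for (alpha in c(0.01, 0.05))
    expect_equal(grubbs_critical_value(n, alpha),
                 oracle_grubbs_crit(n, alpha), tolerance = 1e-10)
  # frozen published two-sided table values at alpha = 0.05
  expect_equal(round(grubbs_critical_value(3, 0.05), 4), 1.1543)
  expect_equal(round(grubbs_critical_value(10, 0.05), 4), 2.2900)
  expect_equal(round(grubbs_critical_value(30, 0.05), 4), 2.9085)
  # grows with n
  expect_gt(grubbs_critical_value(10, 0.05), grubbs_critical_value(3, 0.05))
  expect_error(grubbs_critical_value(2, 0.05), "n < 3")
})

test_that("replicate screening removes gross outliers and preserves clean sets", {
  # {10,11,12}: G = 1 < 1.1543, nothing removed
  s <- screen_replicates(c(10, 11, 12))
  expect_equal(s$mean, 11)
  expect_identical(s$n_outliers_removed, 0L)
  expect_equal(s$se, sd(c(10, 11, 12)) / sqrt(3))
  # {10,11,12,500}: G = 1.49999 > G_crit(4) = 1.48125, one removal
  s <- screen_replicates(c(10, 11, 12, 500))
  expect_identical(s$n_outliers_removed, 1L)
  expect_equal(s$removed_values, 500)
  expect_equal(s$mean, 11)
  # all equal: SE 0, nothing removed
  s <- screen_replicates(rep(7, 4))
  expect_equal(s$mean, 7)
  expect_equal(s$se, 0)
  expect_identical(s$n_outliers_removed, 0L)
  expect_error(screen_replicates(c(1, 2)), "at least 3")
})

test_that("screening is permutation-invariant and keeps n >= 2", {
  set.seed(21)
  v <- c(rlnorm(4, 2, 0.2), 200)
  ref <- screen_replicates(v)
  for (i in 1:10) {
    p <- screen_replicates(sample(v))
    expect_equal(p$mean, ref$mean)
    expect_identical(p$n_used, ref$n_used)
  }
  # pathological spread: removal stops at the floor of 2 kept values
  s <- screen_replicates(c(1, 1000, 1e6))
  expect_gte(s$n_used, 2L)
})

test_that("per-device summaries group, screen and order correctly", {
  ss <- rbind(fixture_sessions_with_totals(c(10, 11, 12, 500), "EC1"),
              fixture_sessions_with_totals(c(30, 33, 36), "EC2"))
  out <- summarize_emissions(ss)
  expect_identical(out$device_id, c("EC1", "EC2"))
  expect_equal(out$mean_emission[1], 11)
  expect_identical(out$n_outliers_removed, c(1L, 0L))
  expect_identical(out$n_used, c(3L, 3L))
  expect_equal(out$mean_emission[2], 33)
  # fewer than 3 sessions for a device is an error naming it
  expect_error(summarize_emissions(
    fixture_sessions_with_totals(c(1, 2), "EC9")), "EC9")
})
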
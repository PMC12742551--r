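test_that("human-error records are excluded before analysis", {
  r <- cohort_fixture()
  expect_identical(nrow(exclude_flagged(r)), 3L)
  expect_identical(attr(exclude_flagged(r), "n_excluded"), 0L)
  r10 <- r[rep(1, 10), ]
  r10$human_error_flag <- c(TRUE, TRUE, rep(FALSE, 8))
  kept <- exclude_flagged(r10)
  expect_identical(nrow(kept), 8L)
  expect_identical(attr(kept, "n_excluded"), 2L)
  empty <- r[0, ]
  expect_identical(nrow(exclude_flagged(empty)), 0L)
})

test_that("aggregation reproduces hand-computed group summaries", {
  # means -1, 0, +1 -> mean 0, sample SD 1; minima floor -8; maxima cap 9;
  # 2 of 3 passed -> 66.7%
  a <- aggregate_cohort(cohort_fixture())
  expect_equal(a$n, 3L)
  expect_equal(a$mean, 0)
  expect_equal(a$sd, 1)
  expect_equal(a$min, -8)
  expect_equal(a$max, 9)
  expect_equal(a$pass_rate, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(a$n_passed + a$n_failed, a$n)
  # single record: SD reported as 0 with the n = 1 flag
  a1 <- aggregate_cohort(cohort_fixture()[2, ])
  expect_equal(a1$mean, 0)
  expect_equal(a1$sd, 0)
  expect_true(a1$single)
})

test_that("aggregation is a partition and is order invariant", {
  cfg <- cohort_config(n_fields = 400)
  r <- generate_parametric_cohort(cfg, seed = 5)
  by_room <- aggregate_cohort(r, "room")
  expect_equal(sum(by_room$n), nrow(r))
  expect_true(all(by_room$n_passed + by_room$n_failed == by_room$n))
  shuffled <- r[sample(nrow(r)), ]
  expect_equal(aggregate_cohort(shuffled, "room"), by_room)
  by_two <- aggregate_cohort(r, c("room", "ion"))
  expect_equal(sum(by_two$n), nrow(r))
})

test_that("one-sample tests match textbook arithmetic and detect shifts", {
  x <- c(2.1, 1.8, 2.5, 1.9, 2.3)
  res <- test_mean_shift(x)
  # independent textbook computation of the one-sample t statistic
  t_manual <- mean(x) / (sd(x) / sqrt(length(x)))
  p_manual <- 2 * pt(-abs(t_manual), df = length(x) - 1)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  # large symmetric sample around zero: no significant shift
  set.seed(31)
  expect_false(test_mean_shift(rnorm(5000))$significant)
  # the published cohort scale: n = 23014 with mean -0.5, sd 0.9
  big <- rnorm(23014, -0.5, 0.9)
  expect_true(test_mean_shift(big)$significant)
  expect_true(test_median_shift(big)$significant)
  expect_error(test_median_shift(rep(1, 10)), "identical")
  expect_error(test_mean_shift(c(1, 2)), "at least 3")
})

test_that("the Levene gate selects pooled versus Welch t-tests", {
  set.seed(12)
  a <- rnorm(200, 0, 1)
  b <- rnorm(200, 0, 1)
  res_eq <- compare_groups(a, b)
  expect_match(res_eq$test, "pooled")
  expect_false(res_eq$significant)
  b_wide <- rnorm(200, 0, 6)
  res_w <- compare_groups(a, b_wide)
  expect_match(res_w$test, "Welch")
  # 3 SD shift at n = 100 is essentially always detected
  res_shift <- compare_groups(rnorm(100, 0, 1), rnorm(100, 3, 1))
  expect_true(res_shift$significant)
  expect_error(compare_groups(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("ANOVA with Tukey flags exactly the shifted group's pairs", {
  set.seed(7)
  groups <- list(a = rnorm(100), b = rnorm(100), c = rnorm(100, 3))
  res <- compare_multi(groups)
  expect_true(res$significant)
  sig_pairs <- res$pairwise$pair[res$pairwise$significant]
  expect_setequal(sig_pairs, c("c-a", "c-b"))
  # identical groups: not significant, no post hoc run
  same <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  res0 <- compare_multi(same)
  expect_false(res0$significant)
  expect_null(res0$pairwise)
})

test_that("Pearson correlation behaves on canonical inputs", {
  x <- seq_len(50)
  expect_equal(correlate(as.numeric(x), as.numeric(x))$effect, 1)
  set.seed(3)
  res_null <- correlate(rnorm(1000), rnorm(1000))
  expect_lt(abs(res_null$effect), 0.1)
  y <- -x + rnorm(50, 0, 5)
  expect_lt(correlate(y, as.numeric(x))$effect, 0)
  expect_error(correlate(rnorm(5), rep(2, 5)), "zero variance")
})

test_that("threshold sensitivity reproduces the baseline and the no-cut limit", {
  mc <- generate_mechanistic_cohort(4, seed = 21)
  base <- aggregate_cohort(mc$records)
  ts <- threshold_sensitivity(mc$details, c(0.05, 1))
  expect_equal(ts$pass_rate[ts$threshold == 0.05], base$pass_rate)
  expect_equal(ts$mean_n_active[ts$threshold == 0.05], base$n_active_mean)
  # threshold far above any gradient activates all chambers
  expect_equal(ts$mean_n_active[ts$threshold == 1], 24)
})

test_that("time accounting sums beam time and per-step overhead", {
  expect_equal(time_accounting()$total_h, 0)
  # 2 verifications in 1 session at the default per-step times:
  # 2 x (15 + 10) + 1 x (30 + 5) = 85 min
  t2 <- time_accounting(n_verifications = 2, n_sessions = 1)
  expect_equal(t2$overhead_h, 85 / 60)
  r <- cohort_fixture()
  tr <- time_accounting(r, n_verifications = 3, n_sessions = 3)
  expect_equal(tr$beam_h, sum(r$time_s) / 3600)
  expect_equal(tr$total_h, tr$beam_h + tr$overhead_h)
  # direct component totals in hours are passed through unchanged
  tot <- time_accounting(beam_hours = 1312, overhead_hours = 2996)
  expect_equal(tot$total_h, 4308)
})
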
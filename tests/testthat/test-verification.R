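test_that("gradient estimation matches closed forms and the brute-force oracle", {
  # constant field has zero gradient
  expect_equal(estimate_gradient(uniform_grid(2), c(20, 0, 0)), 0)
  # ramp of 1 mGy/mm: central difference recovers the slope exactly
  g <- ramp_grid(slope = 0.001)
  expect_equal(estimate_gradient(g, c(20, 0, 0)), 1.0, tolerance = 1e-12)
  # random smooth grids against an independently coded finite difference
  for (seed in 1:10) {
    gs <- smooth_grid(seed)
    set.seed(seed + 100)
    ijk <- cbind(sample(2:13, 5, TRUE), sample(2:13, 5, TRUE),
                 sample(2:13, 5, TRUE))
    pos <- cbind(gs$x[ijk[, 1]], gs$y[ijk[, 2]], gs$z[ijk[, 3]])
    got <- estimate_gradient(gs, pos)
    want <- vapply(1:5, function(r) {
      brute_force_gradient(gs, ijk[r, 1], ijk[r, 2], ijk[r, 3])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
  # boundary voxels have no +/-1 neighbors
  expect_error(estimate_gradient(uniform_grid(), c(1, 0, 0)), "neighbors")
})

test_that("gradient rule deactivates chambers above the D_max fraction", {
  tol <- tolerance_config()
  d_max <- 2  # Gy -> 2000 mGy; 5% threshold = 100 mGy/mm
  expect_false(select_active_chambers(0.06 * 2000, d_max, tol))
  expect_true(select_active_chambers(0, d_max, tol))
  expect_true(select_active_chambers(100, d_max, tol))  # equality stays active
  g45 <- 0.045 * 2000
  expect_true(select_active_chambers(g45, d_max, tol))
  tol4 <- tolerance_config(gradient_threshold_fraction = 0.04)
  expect_false(select_active_chambers(g45, d_max, tol4))
  expect_error(select_active_chambers(10, 0, tol), "d_max")
})

test_that("stricter gradient thresholds never enlarge the active set", {
  set.seed(9)
  gradients <- runif(24, 0, 250)
  prev <- rep(TRUE, 24)
  for (f in seq(0.08, 0.01, by = -0.005)) {
    act <- select_active_chambers(gradients, 2,
                                  tolerance_config(gradient_threshold_fraction = f))
    expect_true(all(!act | prev))  # act subset of prev
    prev <- act
  }
})

test_that("deviation summaries normalize to D_max over the active set", {
  # hand arithmetic: (2.02 - 2)/2 = +1.0%, (1.94 - 2)/2 = -3.0%
  rec <- verification_record(planned = c(2, 2), measured = c(2.02, 1.94),
                             gradient = c(0, 0), active = c(TRUE, TRUE),
                             d_max = 2)
  s <- compute_deviation_summary(rec)
  expect_equal(s$deviations, c(1, -3))
  expect_equal(s$mean, -1)
  expect_equal(s$min, -3)
  expect_equal(s$max, 1)
  expect_equal(s$sd, sd(c(1, -3)))  # sample SD
  # identical doses give the all-zero summary
  rec0 <- verification_record(rep(2, 24), rep(2, 24), rep(0, 24),
                              rep(TRUE, 24), 2)
  s0 <- compute_deviation_summary(rec0)
  expect_equal(c(s0$mean, s0$min, s0$max, s0$sd), c(0, 0, 0, 0))
  expect_true(classify(s0)$passed)
  # single active chamber at +5% of D_max
  rec1 <- verification_record(c(2, 2), c(2 + 0.05 * 2, 9), c(0, 999),
                              c(TRUE, FALSE), 2)
  s1 <- compute_deviation_summary(rec1)
  expect_equal(c(s1$mean, s1$min, s1$max, s1$sd, s1$n_active),
               c(5, 5, 5, 0, 1))
  # deactivating everything is an error
  recx <- verification_record(c(2, 2), c(2, 2), c(999, 999),
                              c(FALSE, FALSE), 2)
  expect_error(compute_deviation_summary(recx), "no evaluable chambers")
})

test_that("tolerance classification matches the institutional limits", {
  expect_true(classify(summary_fixture(-4.9, -6.9, 6.9))$passed)
  expect_true(classify(summary_fixture(-5.0, -7.0, 7.0))$passed)  # inclusive
  r_mean <- classify(summary_fixture(-5.1, 0, 0,
                                     deviations = c(-5.1, -5.1, -5.1)))
  expect_false(r_mean$passed)
  expect_identical(r_mean$violated_criteria, "mean")
  r_min <- classify(summary_fixture(0, -7.5, 2))
  expect_false(r_min$passed)
  expect_identical(r_min$violated_criteria, "minimum")
  r_both <- classify(summary_fixture(6, -8, 9))
  expect_setequal(r_both$violated_criteria, c("mean", "minimum", "maximum"))
  # per-chamber classes by |deviation|
  s <- summary_fixture(0, -8, 6, deviations = c(-8, 6, 3, 99),
                       active = c(TRUE, TRUE, TRUE, FALSE))
  cls <- classify(s)$chamber_class
  expect_equal(as.character(cls),
               c("active_beyond_7", "active_5_to_7", "active_within_5",
                 "deactivated"))
})

test_that("deviation scoring is invariant under common dose rescaling", {
  set.seed(4)
  planned <- runif(24, 1.5, 2)
  measured <- planned * (1 + rnorm(24, 0, 0.02))
  active <- rep(c(TRUE, TRUE, FALSE), 8)
  for (c_scale in c(0.5, 3, 10)) {
    s1 <- compute_deviation_summary(
      verification_record(planned, measured, rep(0, 24), active, 2))
    s2 <- compute_deviation_summary(
      verification_record(c_scale * planned, c_scale * measured,
                          rep(0, 24), active, c_scale * 2))
    expect_equal(s1$deviations, s2$deviations, tolerance = 1e-12)
    expect_equal(s1$mean, s2$mean, tolerance = 1e-12)
    expect_identical(classify(s1)$passed, classify(s2)$passed)
  }
})

test_that("verify_field reproduces the zero-error fixed point and detects bias", {
  s <- cached_sobp()
  layout <- default_stack_layout()
  pos_a <- mean(s$target$depth_range) - 25
  ses0 <- measurement_session(c(pos_a, 0, 0), seed = 1)
  m0 <- simulate_measurement(s$grid, layout, ses0,
                             chamber = chamber_spec(sensitive_volume = 0))
  r0 <- verify_field(s$grid, layout, ses0, m0)
  expect_true(r0$passed)
  expect_equal(r0$summary$deviations, rep(0, 24), tolerance = 1e-9)
  # +6% calibration bias on chambers in the high-dose region fails the mean
  em <- error_model(calibration_bias = 0.06)
  ses_b <- measurement_session(c(pos_a, 0, 0), seed = 1, errors = em)
  m_b <- simulate_measurement(s$grid, layout, ses_b,
                              chamber = chamber_spec(sensitive_volume = 0))
  r_b <- verify_field(s$grid, layout, ses_b, m_b)
  expect_false(r_b$passed)
  expect_true("mean" %in% r_b$violated_criteria)
})

test_that("verification fails loudly when every chamber sits in the penumbra", {
  s <- cached_sobp()
  # all 24 chambers on the distal edge where gradients exceed the threshold
  layout <- default_stack_layout()
  layout$dx_mm <- rep(c(0, 2), each = 12)
  edge <- s$target$depth_range[2] + 2
  ses <- measurement_session(c(edge, 0, 0), seed = 1)
  m <- simulate_measurement(s$grid, layout, ses,
                            chamber = chamber_spec(sensitive_volume = 0))
  expect_error(verify_field(s$grid, layout, ses, m), "no evaluable chambers")
})

test_that("the repeat policy follows the institutional decision path", {
  s <- cached_sobp()
  layout <- default_stack_layout()
  pos_a <- mean(s$target$depth_range) - 25
  ses <- measurement_session(c(pos_a, 0, 0), seed = 1)
  ch0 <- chamber_spec(sensitive_volume = 0)
  pass <- verify_field(s$grid, layout, ses,
                       simulate_measurement(s$grid, layout, ses, ch0))
  expect_identical(repeat_policy(pass), "accept")
  # global bias failure: first time repeat, then adapt (no chambers beyond 7%)
  em <- error_model(calibration_bias = 0.06)
  ses_b <- measurement_session(c(pos_a, 0, 0), seed = 1, errors = em)
  fail <- verify_field(s$grid, layout, ses_b,
                       simulate_measurement(s$grid, layout, ses_b, ch0))
  expect_identical(repeat_policy(fail), "repeat_measurement")
  expect_identical(repeat_policy(fail, history = list(fail)), "adapt_plan")
  # few isolated outliers in the steepest-gradient chambers are justifiable
  make_result <- function(outlier_idx) {
    gradients <- as.numeric(1:24)  # chamber 24 steepest
    dev <- rep(0, 24)
    dev[outlier_idx] <- 8  # % of D_max, beyond +7%
    planned <- rep(2, 24)
    rec <- verification_record(planned, planned + dev / 100 * 2, gradients,
                               active = rep(TRUE, 24), d_max = 2)
    r <- classify(compute_deviation_summary(rec))
    r$record <- rec
    r
  }
  r_high <- make_result(c(23, 24))  # above the 75% gradient quantile
  expect_false(r_high$passed)
  expect_identical(repeat_policy(r_high, history = list(r_high)),
                   "accept_with_justification")
  # many outliers in low-gradient chambers force a plan adaptation
  r_low <- make_result(1:5)
  expect_false(r_low$passed)
  expect_identical(repeat_policy(r_low, history = list(r_low)), "adapt_plan")
})
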
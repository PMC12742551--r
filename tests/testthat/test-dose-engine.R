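test_that("depth-dose curves satisfy the Bragg-curve invariants", {
  cases <- expand.grid(ion = c("proton", "helium", "carbon"),
                       range = c(30, 100, 150, 250),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cv <- make_depth_dose(cases$ion[i], cases$range[i])
    expect_true(all(cv$dose >= 0))
    peak_depth <- cv$depth[which.max(cv$dose)]
    expect_lte(peak_depth, cases$range[i])
    # dose beyond range + 3 x distal falloff below 1% of the peak
    tail_dose <- depth_dose_at(cv, cases$range[i] + 3 * cv$distal_falloff)
    expect_lt(tail_dose, 0.01 * max(cv$dose))
    # monotone rise over the proximal shoulder into the peak
    shoulder <- cv$dose[cv$depth >= peak_depth - 3 * cv$peak_width &
                          cv$depth <= peak_depth]
    expect_true(all(diff(shoulder) >= 0))
  }
})

test_that("proton 150 mm curve peaks within [140, 150] mm", {
  cv <- make_depth_dose("proton", 150)
  expect_gte(cv$depth[which.max(cv$dose)], 140)
  expect_lte(cv$depth[which.max(cv$dose)], 150)
})

test_that("helium 100 mm curve is below 1% of peak at 130 mm", {
  cv <- make_depth_dose("helium", 100)
  expect_lt(depth_dose_at(cv, 130), 0.01 * max(cv$dose))
})

test_that("degenerate ranges are rejected", {
  expect_error(make_depth_dose("carbon", 0.5), "minimum supported range")
  expect_error(make_depth_dose("proton", -10), "positive")
  expect_error(make_depth_dose("proton", 400), "maximum supported range")
})

single_spot_field <- function(n = 1e8, y = 0, z = 0, fwhm = 8) {
  treatment_field("proton", layer_ranges = 100,
                  spots = data.frame(layer = 1, y_mm = y, z_mm = z,
                                     n_particles = n, fwhm_mm = fwhm))
}

test_that("dose grid is exactly linear and superposable in particle number", {
  ph <- water_phantom(120, 60, 60)
  g1 <- compute_dose_grid(single_spot_field(1e8), ph, 2)
  g2 <- compute_dose_grid(single_spot_field(2e8), ph, 2)
  expect_identical(2 * g1$values, g2$values)
  # two superimposed identical spots equal one spot with 2N particles
  f2 <- treatment_field("proton", 100,
                        rbind(single_spot_field(1e8)$spots,
                              single_spot_field(1e8)$spots))
  g_sup <- compute_dose_grid(f2, ph, 2)
  expect_equal(g_sup$values, g2$values, tolerance = 1e-12)
})

test_that("shifting spots by one grid spacing shifts the dose by one voxel", {
  ph <- water_phantom(120, 60, 60)
  g0 <- compute_dose_grid(single_spot_field(1e8, y = 0), ph, 2)
  g1 <- compute_dose_grid(single_spot_field(1e8, y = 2), ph, 2)
  ny <- dim(g0$values)[2]
  expect_equal(g1$values[, 2:ny, ], g0$values[, 1:(ny - 1), ],
               tolerance = 1e-12)
})

test_that("single-spot central-axis dose equals depth dose times Gaussian peak", {
  ph <- water_phantom(120, 60, 60)
  n <- 1e8
  fwhm <- 8
  # spot centered on a voxel-center line: y = z = 1 mm at 2 mm spacing
  g <- compute_dose_grid(single_spot_field(n, y = 1, z = 1, fwhm), ph, 2)
  cv <- make_depth_dose("proton", 100)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  j <- which(g$y == 1)
  k <- which(g$z == 1)
  expected <- n * depth_dose_at(cv, g$x) / (2 * pi * sigma^2)
  expect_equal(g$values[, j, k], expected, tolerance = 1e-9)
})

test_that("out-of-phantom footprints are rejected naming the spot", {
  ph <- water_phantom(120, 60, 60)
  f <- treatment_field("proton", 100,
                       data.frame(layer = 1, y_mm = c(0, 28), z_mm = 0,
                                  n_particles = 1e8, fwhm_mm = 8))
  expect_error(compute_dose_grid(f, ph, 2), "spot 2")
  f_deep <- single_spot_field()
  f_deep$layer_ranges <- 150
  expect_error(compute_dose_grid(f_deep, ph, 2), "exceeds phantom depth")
})

test_that("range shifter shifts ranges and the Bragg peak by its thickness", {
  f <- single_spot_field()
  f$layer_ranges <- 150
  expect_identical(apply_range_shifter(f, 0), f)
  shifted <- apply_range_shifter(f, 20)
  expect_equal(ionpsqa:::effective_ranges(shifted), 130)
  ph <- water_phantom(200, 60, 60)
  g0 <- compute_dose_grid(f, ph, 2)
  g1 <- compute_dose_grid(shifted, ph, 2)
  argmax_depth <- function(g) {
    idx <- arrayInd(which.max(g$values), dim(g$values))
    g$x[idx[1]]
  }
  expect_lte(abs((argmax_depth(g0) - argmax_depth(g1)) - 20), g0$spacing)
  expect_error(apply_range_shifter(f, 150), "<= 0 mm")
})

test_that("optimized SOBP is flat and hits the prescription", {
  s <- cached_sobp()
  expect_equal(mean_dose_in_target(s$grid, s$target), 2, tolerance = 0.01)
  axis_depths <- seq(s$target$depth_range[1] + 1,
                     s$target$depth_range[2] - 1, by = 2)
  axis_dose <- interp_dose(s$grid, cbind(axis_depths, 0, 0))
  expect_true(all(abs(axis_dose - 2) <= 0.03 * 2))
})

test_that("SOBP optimizer handles the degenerate cases", {
  target <- list(depth_range = c(90, 94), center = c(0, 0), radius = 15)
  tmpl <- sobp_field_template("proton", c(94, 94.5), target$radius,
                              layer_spacing = 10, distal_margin = 0)
  expect_length(tmpl$layer_ranges, 1L)
  f <- optimize_sobp(tmpl, target, 1)
  g <- compute_dose_grid(f, water_phantom(), 2)
  expect_equal(mean_dose_in_target(g, target), 1, tolerance = 0.01)
  f0 <- optimize_sobp(tmpl, target, 0)
  expect_true(all(f0$spots$n_particles == 0))
  g0 <- compute_dose_grid(f0, water_phantom(), 2)
  expect_true(all(g0$values == 0))
  deep <- list(depth_range = c(250, 280), center = c(0, 0), radius = 15)
  expect_error(optimize_sobp(tmpl, deep, 2), "infeasible")
})
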
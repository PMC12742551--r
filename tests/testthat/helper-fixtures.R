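# Shared fixtures, all built in code at test time.

# uniform-dose grid large enough to hold the default chamber stack
uniform_grid <- function(value = 2, nx = 40, ny = 20, nz = 24, spacing = 2) {
  dose_grid(array(value, dim = c(nx, ny, nz)), spacing,
            origin = c(0, -ny * spacing / 2, -nz * spacing / 2))
}

# dose rising linearly along the depth axis: dose(x) = slope * x (Gy/mm)
ramp_grid <- function(slope = 0.001, nx = 40, ny = 20, nz = 24, spacing = 2) {
  x <- (seq_len(nx) - 0.5) * spacing
  vals <- array(rep(slope * x, times = ny * nz), dim = c(nx, ny, nz))
  dose_grid(vals, spacing, origin = c(0, -ny * spacing / 2, -nz * spacing / 2))
}

# smooth positive pseudo-random field (separable trigonometric modes)
smooth_grid <- function(seed, n = 14, spacing = 2) {
  set.seed(seed)
  ax <- (seq_len(n) - 0.5) * spacing
  f1 <- 2 + sin(ax / stats::runif(1, 5, 9) + stats::runif(1, 0, 6))
  f2 <- 2 + cos(ax / stats::runif(1, 6, 11) + stats::runif(1, 0, 6))
  f3 <- 2 + sin(ax / stats::runif(1, 7, 13) + stats::runif(1, 0, 6))
  vals <- outer(f1, outer(f2, f3)) * 0.1
  dose_grid(array(vals, dim = c(n, n, n)), spacing,
            origin = c(0, -n * spacing / 2, -n * spacing / 2))
}

# independent brute-force central-difference gradient (mGy/mm) at voxel (i,j,k)
brute_force_gradient <- function(grid, i, j, k) {
  v <- grid$values
  s <- grid$spacing
  gx <- (v[i + 1, j, k] - v[i - 1, j, k]) / (2 * s)
  gy <- (v[i, j + 1, k] - v[i, j - 1, k]) / (2 * s)
  gz <- (v[i, j, k + 1] - v[i, j, k - 1]) / (2 * s)
  1000 * sqrt(gx^2 + gy^2 + gz^2)
}

# a small optimized proton SOBP shared across tests (computed once)
.sobp_env <- new.env()
cached_sobp <- function() {
  if (is.null(.sobp_env$grid)) {
    target <- list(depth_range = c(60, 110), center = c(0, 0), radius = 25)
    tmpl <- sobp_field_template("proton", target$depth_range, target$radius)
    field <- optimize_sobp(tmpl, target, prescribed_dose = 2)
    .sobp_env$target <- target
    .sobp_env$field <- field
    .sobp_env$grid <- compute_dose_grid(field, water_phantom(), 2)
  }
  list(target = .sobp_env$target, field = .sobp_env$field,
       grid = .sobp_env$grid)
}

# minimal deviation summary for classification tests
summary_fixture <- function(mean, min, max, deviations = NULL,
                            active = NULL) {
  if (is.null(deviations)) deviations <- c(min, mean, max)
  if (is.null(active)) active <- rep(TRUE, length(deviations))
  structure(
    list(deviations = deviations, active = active, mean = mean,
         sd = 0, min = min, max = max, n_active = sum(active)),
    class = "deviation_summary"
  )
}

# base plan for adapted-plan rule tests
base_plan <- function() {
  plan_summary(
    ion_species = "carbon", fraction_dose = 2, n_fields = 2,
    couch_angles = c(0, 90), gantry_angles = c(90, 90),
    modifiers = c(rifi = 0, rashi = 20),
    energy_levels = seq(80, 140, by = 2), total_particles = 2e9
  )
}

# perturb a base plan to violate exactly the requested rules; rules not in
# `violate` stay within tolerance (but may be perturbed benignly)
make_adapted <- function(orig, violate = character(0)) {
  p <- orig
  if ("ion_species" %in% violate) {
    p$ion_species <- "proton"
    return(p)  # short-circuits: inject nothing else
  }
  p$fraction_dose <- p$fraction_dose +
    if ("fraction_dose" %in% violate) 0.5 else 0
  if ("n_fields" %in% violate) {
    p$n_fields <- p$n_fields + 1L
    p$couch_angles <- c(p$couch_angles, 0)
    p$gantry_angles <- c(p$gantry_angles, 90)
  } else if ("angles" %in% violate) {
    p$couch_angles[1] <- p$couch_angles[1] + 15
  } else {
    p$couch_angles <- p$couch_angles + 5  # within +/-10 degrees
  }
  if ("modifiers" %in% violate) {
    p$modifiers["rashi"] <- p$modifiers["rashi"] + 150
  } else {
    p$modifiers["rashi"] <- p$modifiers["rashi"] + 50  # within 100 mm
  }
  n_new <- if ("energy_levels" %in% violate) 25 else 10
  p$energy_levels <- sort(c(p$energy_levels,
                            max(p$energy_levels) + seq_len(n_new)))
  p$total_particles <- p$total_particles *
    if ("particle_number" %in% violate) 1.25 else 1.1
  if ("field_contributions" %in% violate) {
    p$opt_meta["spot_spacing"] <- p$opt_meta["spot_spacing"] * 1.5
  }
  p
}

base_record <- function() {
  plan_record(
    approval_status = "approved", plan_label = "PLAN-001",
    review_timestamp = "2025-06-01T10:00:00", patient_name = "DOE^JOHN",
    patient_id = "PAT123", field_names = c("F1", "F2"), n_spots = 5L,
    particle_tuples = data.frame(position = 1:5, focus = rep(8, 5),
                                 energy = seq(100, 140, 10)),
    modifiers = "rifi", modifier_positions = 0, isocenter = c(0, 0, 0)
  )
}

# hand-made 3-record cohort used by aggregation tests
cohort_fixture <- function() {
  data.frame(
    field_id = c("A", "B", "C"),
    room = c("Hx", "Hx", "Ga"), ion = c("p", "C", "p"),
    tps = "Syngo", rashi = FALSE, indication = "head", year = 2020L,
    pos_a = c(50, 60, 70), pos_b = 0, pos_c = 0, volume_cm3 = 100,
    dev_mean = c(-1, 0, 1), dev_sd = c(1, 1, 2),
    dev_min = c(-3, -2, -8), dev_max = c(2, 4, 9),
    n_active = c(20, 22, 21), time_s = c(180, 200, 250),
    passed = c(TRUE, TRUE, FALSE), repeat_index = 0L,
    human_error_flag = FALSE
  )
}
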
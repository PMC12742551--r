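# Seeded cohort generators. Two modes:
#  - parametric: fast draws of field records with the statistical structure
#    the cohort analysis assumes, calibrated to published summary moments;
#  - mechanistic: full pipeline per field (SOBP plan -> dose grid -> chamber
#    measurement -> verification) at desk scale.
#
# In both modes the pass flag is always recomputed from the tolerance rules,
# never sampled, so tolerance changes propagate consistently.

#' Cohort generator configuration
#'
#' The defaults are calibrated to the published 10-year cohort: 23014
#' fields with a field-mean deviation of -0.5 +/- 0.9 % of D_max, 21 +/- 2
#' activated chambers, irradiation times of about 03:24 +/- 01:57 [mm:ss],
#' and category mixtures matching the reported room / ion / TPS / range
#' shifter / indication / year proportions. The per-chamber residual model
#' is a two-component normal mixture (narrow core plus a rare wide
#' component) whose defaults put about 0.7% of active-chamber deviations
#' beyond +/-7% of D_max, matching the reported tail frequency.
#'
#' The per-field mean deviation is drawn directly from the configured
#' location/scale (per category level on the calibration axis); chamber
#' residuals are centered within each field, so the configured distribution
#' is exactly the distribution of the per-field mean. The published tables
#' constrain only these summary moments; the within-field joint
#' distribution is one admissible choice.
#'
#' @param n_fields number of fields to generate.
#' @param location,scale mean and SD of the field-mean deviation
#'   distribution, % of D_max. May be named vectors over the levels of
#'   `calibration_axis`.
#' @param calibration_axis category axis whose levels carry per-level
#'   location/scale (`"all"` = a single component).
#' @param per_chamber_sd core SD of the within-field chamber residuals (%).
#' @param tail_weight,tail_sd mixture weight and SD (%) of the rare wide
#'   residual component.
#' @param n_active_mean,n_active_sd moments of the (rounded, clipped to
#'   1..24) number of activated chambers.
#' @param time_mean_s,time_sd_s moments of the per-field irradiation time;
#'   drawn from a log-normal with these moments to keep positivity.
#' @param proportions named list of category mixture proportions per axis
#'   (`room`, `ion`, `tps`, `rashi`, `indication`, `year`); each must sum
#'   to 1.
#' @param human_error_rate probability that a field is flagged as a human
#'   operating error.
#' @param repeat_correlation correlation of re-drawn residuals when a failed
#'   field is re-measured (failure causes are largely reproducible).
#' @param tol [tolerance_config()] used to recompute the pass flags.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_fields = 1000,
                          location = -0.5, scale = 0.9,
                          calibration_axis = "all",
                          per_chamber_sd = 1.0,
                          tail_weight = 0.03, tail_sd = 6,
                          n_active_mean = 21, n_active_sd = 2,
                          time_mean_s = 204, time_sd_s = 117,
                          proportions = default_category_proportions(),
                          human_error_rate = 0.01,
                          repeat_correlation = 0.8,
                          tol = tolerance_config()) {
  if (n_fields < 1L) stop("n_fields must be >= 1")
  if (any(scale < 0) || per_chamber_sd < 0 || tail_sd < 0) {
    stop("scales must be >= 0")
  }
  if (tail_weight < 0 || tail_weight > 1) stop("tail_weight must be in [0, 1]")
  for (ax in names(proportions)) {
    p <- proportions[[ax]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("proportions for axis '", ax, "' must be >= 0 and sum to 1")
    }
  }
  if (calibration_axis != "all") {
    lv <- names(proportions[[calibration_axis]])
    if (!identical(sort(names(location)), sort(lv)) ||
        !identical(sort(names(scale)), sort(lv))) {
      stop("location/scale must be named over the levels of '",
           calibration_axis, "'")
    }
  }
  structure(
    list(n_fields = as.integer(n_fields), location = location, scale = scale,
         calibration_axis = calibration_axis,
         per_chamber_sd = per_chamber_sd, tail_weight = tail_weight,
         tail_sd = tail_sd, n_active_mean = n_active_mean,
         n_active_sd = n_active_sd, time_mean_s = time_mean_s,
         time_sd_s = time_sd_s, proportions = proportions,
         human_error_rate = human_error_rate,
         repeat_correlation = repeat_correlation, tol = tol),
    class = "cohort_config"
  )
}

#' Default category mixture proportions
#'
#' Mixture proportions of the published cohort: 59% horizontal-room fields,
#' ion split roughly 52/47/1 between protons, carbon and helium, 77% Syngo
#' plans, 24% range-shifter use, the reported indication mix dominated by
#' head fields, and the reported per-year field counts.
#'
#' @return named list of named proportion vectors.
#' @export
default_category_proportions <- function() {
  year_counts <- c(`2016` = 2285, `2017` = 2098, `2018` = 2488,
                   `2019` = 2024, `2020` = 2504, `2021` = 2368,
                   `2022` = 2677, `2023` = 2379, `2024` = 2477,
                   `2025` = 1538)
  list(
    room = c(Hx = 0.59, Ga = 0.41),
    ion = c(p = 0.517, C = 0.472, He = 0.011),
    tps = c(Syngo = 0.77, RayStation = 0.23),
    rashi = c(`FALSE` = 0.76, `TRUE` = 0.24),
    indication = c(head = 0.68, abdomen = 0.12, spine = 0.06, thorax = 0.05,
                   prostate = 0.03, extremities = 0.02, neck = 0.02,
                   pancreas = 0.02),
    year = year_counts / sum(year_counts)
  )
}

.sample_axis <- function(p, n) {
  sample(names(p), n, replace = TRUE, prob = p)
}

.lognormal_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a parametric cohort of field records
#'
#' Draws category labels, per-field mean deviations, within-field chamber
#' residuals (centered, two-component mixture), activated-chamber counts,
#' irradiation times, stack positions and target volumes; derives each
#' field's SD/min/max from its simulated active chambers and recomputes the
#' pass flag from the tolerance rules. Byte-identical output for a fixed
#' seed and config.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return field-record data.frame (see the module header in the cohort
#'   statistics documentation for the column contract).
#' @export
generate_parametric_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  n <- config$n_fields
  pr <- config$proportions
  labels <- data.frame(
    room = .sample_axis(pr$room, n),
    ion = .sample_axis(pr$ion, n),
    tps = .sample_axis(pr$tps, n),
    rashi = .sample_axis(pr$rashi, n) == "TRUE",
    indication = .sample_axis(pr$indication, n),
    year = as.integer(.sample_axis(pr$year, n))
  )
  if (config$calibration_axis == "all") {
    loc <- rep(unname(config$location)[1L], n)
    sc <- rep(unname(config$scale)[1L], n)
  } else {
    lev <- as.character(labels[[config$calibration_axis]])
    loc <- unname(config$location[lev])
    sc <- unname(config$scale[lev])
  }
  field_mean <- stats::rnorm(n, loc, sc)
  n_active <- pmin(24L, pmax(1L, as.integer(round(
    stats::rnorm(n, config$n_active_mean, config$n_active_sd)))))
  # per-chamber residuals: core + rare wide component, centered per field
  resid <- matrix(stats::rnorm(24L * n, sd = config$per_chamber_sd),
                  nrow = 24L)
  is_tail <- matrix(stats::runif(24L * n) < config$tail_weight, nrow = 24L)
  resid[is_tail] <- stats::rnorm(sum(is_tail), sd = config$tail_sd)
  active_mask <- outer(seq_len(24L), n_active, `<=`)
  resid[!active_mask] <- NA_real_
  resid <- sweep(resid, 2L, colMeans(resid, na.rm = TRUE))
  dev <- sweep(resid, 2L, field_mean, `+`)
  dev_sd <- apply(dev, 2L, stats::sd, na.rm = TRUE)
  dev_sd[n_active == 1L] <- 0
  dev_min <- suppressWarnings(apply(dev, 2L, min, na.rm = TRUE))
  dev_max <- suppressWarnings(apply(dev, 2L, max, na.rm = TRUE))
  lp <- .lognormal_params(config$time_mean_s, config$time_sd_s)
  time_s <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
  lv <- .lognormal_params(150, 400)
  volume <- pmin(10000, pmax(10, stats::rlnorm(n, lv$meanlog, lv$sdlog)))
  records <- data.frame(
    field_id = sprintf("F%06d", seq_len(n)),
    labels,
    pos_a = stats::runif(n, 20, 180),
    pos_b = stats::rnorm(n, 0, 10),
    pos_c = stats::rnorm(n, 0, 10),
    volume_cm3 = volume,
    dev_mean = field_mean,
    dev_sd = dev_sd,
    dev_min = dev_min,
    dev_max = dev_max,
    n_active = n_active,
    time_s = time_s,
    passed = tolerances_passed(field_mean, dev_min, dev_max, config$tol),
    repeat_index = 0L,
    human_error_flag = stats::runif(n) < config$human_error_rate
  )
  records
}

#' Re-measure failed fields of a parametric cohort
#'
#' Redraws each failed field's chamber residuals with the configured
#' correlation to the original draw (failure conditions are largely
#' reproducible), producing the repeat-measurement records.
#'
#' @param records output of [generate_parametric_cohort()].
#' @param config the generating [cohort_config()].
#' @param seed integer seed.
#' @return field-record data.frame of repeats (`repeat_index = 1`).
#' @export
generate_repeats <- function(records, config, seed = 2L) {
  set.seed(as.integer(seed))
  failed <- records[!records$passed, , drop = FALSE]
  if (nrow(failed) == 0L) return(failed)
  rho <- config$repeat_correlation
  n <- nrow(failed)
  out <- failed
  for (i in seq_len(n)) {
    na <- failed$n_active[i]
    # reconstruct a residual draw consistent with the recorded summary
    old <- stats::rnorm(na, sd = max(failed$dev_sd[i], 1e-6))
    old <- old - mean(old)
    new <- rho * old + sqrt(1 - rho^2) *
      stats::rnorm(na, sd = max(failed$dev_sd[i], 1e-6))
    new <- new - mean(new)
    dev <- failed$dev_mean[i] + new
    out$dev_sd[i] <- if (na > 1L) stats::sd(dev) else 0
    out$dev_min[i] <- min(dev)
    out$dev_max[i] <- max(dev)
  }
  out$passed <- tolerances_passed(out$dev_mean, out$dev_min, out$dev_max,
                                  config$tol)
  out$repeat_index <- 1L
  out
}

#' Generate a mechanistic cohort via the full verification pipeline
#'
#' For each field: build an SOBP plan (ion, target depth and radius drawn
#' from the configured mixtures), compute its dose grid, place the chamber
#' stack over the target, simulate the measurement with the given error
#' model, and score it with [verify_field()]. Intended for desk-scale runs
#' (tens of fields on 2 mm grids).
#'
#' @param n_fields number of fields (default 20).
#' @param seed integer seed.
#' @param errors an [error_model()] applied to every field; the default
#'   carries a realistic mix of sub-millimetre positioning scatter, 0.5%
#'   reading noise and a slightly negative background offset.
#' @param chamber a [chamber_spec()]; pass `chamber_spec(sensitive_volume =
#'   0)` for ideal point chambers (with a zero error model this reproduces
#'   the planned doses exactly).
#' @param spacing grid spacing in mm.
#' @param phantom a [water_phantom()].
#' @param tol a [tolerance_config()].
#' @param ion_proportions named proportions over `c(p, C, He)`.
#' @return list with `records` (field-record data.frame) and `details`
#'   (per-field data.frames with `planned`, `measured`, `gradient`,
#'   `d_max` for threshold-sensitivity re-analysis).
#' @export
generate_mechanistic_cohort <- function(n_fields = 20, seed = 1L,
                                        errors = error_model(
                                          positioning_sd = 0.5,
                                          relative_noise_sd = 0.005,
                                          background_offset = -0.01),
                                        chamber = chamber_spec(),
                                        spacing = 2,
                                        phantom = water_phantom(),
                                        tol = tolerance_config(),
                                        ion_proportions = c(p = 0.52,
                                                            C = 0.47,
                                                            He = 0.01)) {
  set.seed(as.integer(seed))
  ion_map <- c(p = "proton", C = "carbon", He = "helium")
  ions <- .sample_axis(ion_proportions, n_fields)
  d_distal <- stats::runif(n_fields, 90, 140)
  width <- stats::runif(n_fields, 40, 55)
  radius <- stats::runif(n_fields, 15, 25)
  sub_seeds <- sample.int(.Machine$integer.max, n_fields)
  records <- vector("list", n_fields)
  details <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    target <- list(depth_range = c(d_distal[i] - width[i], d_distal[i]),
                   center = c(0, 0), radius = radius[i])
    tmpl <- sobp_field_template(ion_map[[ions[i]]], target$depth_range,
                                target$radius)
    field <- optimize_sobp(tmpl, target, prescribed_dose = 2,
                           phantom = phantom, spacing = spacing)
    grid <- compute_dose_grid(field, phantom, spacing)
    # stack rows (0..50 mm) centered on the modulation
    pos_a <- mean(target$depth_range) - 25
    session <- measurement_session(c(pos_a, 0, 0), seed = sub_seeds[i],
                                   errors = errors)
    meas <- simulate_measurement(grid, default_stack_layout(), session,
                                 chamber = chamber)
    res <- verify_field(grid, default_stack_layout(), session, meas, tol)
    s <- res$summary
    records[[i]] <- data.frame(
      field_id = sprintf("M%04d", i),
      room = "Hx", ion = ions[i], tps = "RayStation",
      rashi = FALSE, indication = "head",
      year = 2025L,
      pos_a = pos_a, pos_b = 0, pos_c = 0,
      volume_cm3 = pi * radius[i]^2 * width[i] / 1000,
      dev_mean = s$mean, dev_sd = s$sd, dev_min = s$min, dev_max = s$max,
      n_active = s$n_active,
      time_s = stats::rlnorm(1, log(180), 0.4),
      passed = res$passed,
      repeat_index = 0L,
      human_error_flag = meas$human_error_suspected
    )
    details[[i]] <- data.frame(
      planned = res$record$planned,
      measured = res$record$measured,
      gradient = res$record$gradient,
      d_max = res$record$d_max
    )
  }
  list(records = do.call(rbind, records), details = details)
}

#' Calibrate a cohort config from a summary table
#'
#' Builds a generator configuration whose cohorts reproduce, at large n, the
#' per-category field counts, mean +/- SD deviations and times of a summary
#' table (one row per level of one category axis, or a single `"all"` row).
#'
#' @param summary_table data.frame with columns `category`, `n`, `mean`,
#'   `sd` and optionally `time_mean_s`, `time_sd_s`.
#' @param axis the category axis the rows refer to (`"all"`, `"room"`,
#'   `"ion"`, `"tps"`, `"rashi"`, `"indication"`, `"year"`).
#' @param n_fields total cohort size of the generated cohorts.
#' @param ... further arguments passed to [cohort_config()].
#' @return a [cohort_config()].
#' @export
calibrate_from_summary <- function(summary_table, axis = "all",
                                   n_fields = sum(summary_table$n), ...) {
  needed <- c("category", "n", "mean", "sd")
  missing_cols <- setdiff(needed, names(summary_table))
  if (length(missing_cols)) {
    stop("summary table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(summary_table$sd < 0)) stop("negative SD in summary table")
  tm <- if ("time_mean_s" %in% names(summary_table)) {
    stats::weighted.mean(summary_table$time_mean_s, summary_table$n)
  } else 204
  ts <- if ("time_sd_s" %in% names(summary_table)) {
    stats::weighted.mean(summary_table$time_sd_s, summary_table$n)
  } else 117
  if (axis == "all") {
    if (nrow(summary_table) != 1L) {
      stop("axis 'all' expects a single summary row")
    }
    return(cohort_config(n_fields = n_fields,
                         location = summary_table$mean,
                         scale = summary_table$sd,
                         calibration_axis = "all",
                         time_mean_s = tm, time_sd_s = ts, ...))
  }
  props <- default_category_proportions()
  lv <- names(props[[axis]])
  missing_lv <- setdiff(lv, summary_table$category)
  if (length(missing_lv)) {
    stop("summary table is missing categories: ",
         paste(missing_lv, collapse = ", "))
  }
  st <- summary_table[match(lv, summary_table$category), ]
  props[[axis]] <- stats::setNames(st$n / sum(st$n), lv)
  cohort_config(n_fields = n_fields,
                location = stats::setNames(st$mean, lv),
                scale = stats::setNames(st$sd, lv),
                calibration_axis = axis,
                proportions = props,
                time_mean_s = tm, time_sd_s = ts, ...)
}
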
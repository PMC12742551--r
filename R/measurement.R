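# Ionization-chamber stack model and measurement synthesis.
#
# The 24 small-volume (PinPoint-type) chambers are mounted in a rigid stack:
# 6 rows of 4 chambers along the depth axis, distributed over three height
# levels so that no chamber shadows another. Chamber coordinates are relative
# to the stack reference point; a measurement session places that reference
# point in the phantom frame.

#' Chamber specification
#'
#' Defaults approximate a small cylindrical thimble chamber (sensitive
#' volume 30 mm^3, radius 1.45 mm, length 5 mm along the lateral axis).
#' Calibration, beam-quality (kQ = 1.026) and air-density corrections are
#' treated as exactly compensated in the simulation: the calibration chain
#' multiplies readings by `calibration_factor * kQ * air_density_correction`
#' and the dose conversion divides by the same product, so only deliberately
#' injected errors (see [error_model()]) perturb the measured dose.
#'
#' @param sensitive_volume sensitive volume in mm^3; 0 means a point chamber.
#' @param radius,length cylinder dimensions in mm (used for volume
#'   averaging).
#' @param effective_point_offset offset of the effective point of measurement
#'   along the beam axis in mm (default 0: positions are already referred to
#'   the effective point).
#' @param calibration_factor dose per reading unit (Gy).
#' @param kQ beam-quality correction factor (default 1.026).
#' @param air_density_correction dimensionless (default 1).
#' @return object of class `chamber_spec`.
#' @export
chamber_spec <- function(sensitive_volume = 30, radius = 1.45, length = 5,
                         effective_point_offset = 0, calibration_factor = 1,
                         kQ = 1.026, air_density_correction = 1) {
  if (calibration_factor <= 0) stop("calibration factor must be > 0")
  if (kQ <= 0) stop("kQ must be > 0")
  structure(
    list(sensitive_volume = sensitive_volume, radius = radius,
         length = length, effective_point_offset = effective_point_offset,
         calibration_factor = calibration_factor, kQ = kQ,
         air_density_correction = air_density_correction),
    class = "chamber_spec"
  )
}

#' Default 24-chamber stack layout
#'
#' 6 rows of 4 chambers each along the depth axis (10 mm row pitch), lateral
#' offsets -18/-6/6/18 mm within a row, rows cycling through three height
#' levels (-8, 0, +8 mm). Coordinates are relative to the stack reference
#' point (center of the first row at mid height). The exact chamber
#' coordinates of the commercial stack are not published; these are
#' documented plausible stand-ins satisfying the layout constraints
#' (24 chambers, three heights, no overlap).
#'
#' @return object of class `ic_stack_layout`: a data.frame with
#'   `chamber_id`, `dx_mm`, `dy_mm`, `dz_mm`, `volume_mm3`.
#' @export
default_stack_layout <- function() {
  rows <- rep(1:6, each = 4)
  layout <- data.frame(
    chamber_id = 1:24,
    dx_mm = (rows - 1) * 10,
    dy_mm = c(-8, 0, 8)[(rows - 1) %% 3 + 1],
    dz_mm = rep(c(-18, -6, 6, 18), times = 6),
    volume_mm3 = 30
  )
  class(layout) <- c("ic_stack_layout", "data.frame")
  validate_stack_layout(layout)
  layout
}

#' Validate a chamber stack layout
#'
#' Checks the structural invariants: exactly 24 chambers, exactly three
#' distinct height levels, and pairwise separation larger than the chamber
#' diameter.
#'
#' @param layout an `ic_stack_layout` (or compatible data.frame).
#' @param chamber_diameter minimum allowed pairwise separation in mm.
#' @return the layout, invisibly; errors on violation.
#' @export
validate_stack_layout <- function(layout, chamber_diameter = 2.9) {
  if (nrow(layout) != 24L) stop("stack layout must contain exactly 24 chambers")
  if (length(unique(layout$dy_mm)) != 3L) {
    stop("stack layout must use exactly three height levels")
  }
  pos <- as.matrix(layout[, c("dx_mm", "dy_mm", "dz_mm")])
  dmin <- min(stats::dist(pos))
  if (dmin <= chamber_diameter) {
    stop("chambers overlap: minimum separation ", round(dmin, 2), " mm")
  }
  invisible(layout)
}

#' Measurement error model
#'
#' Realizes the uncertainty taxonomy of water-phantom PSQA: the effective
#' point of measurement and stack positioning (random per-chamber offsets),
#' multiplicative reading noise, an additive background-subtraction offset
#' (slightly negative by default in realistic configurations, reflecting
#' systematic background over-subtraction), a calibration bias, and discrete
#' human-error modes (wrong calibration factor, wrongly positioned phantom,
#' wrongly computed air gap, i.e. a depth shift).
#'
#' @param positioning_sd SD of the random per-chamber position error per
#'   axis, mm.
#' @param relative_noise_sd SD of the multiplicative reading noise
#'   (fraction).
#' @param background_offset additive offset in Gy (may be negative).
#' @param calibration_bias systematic fractional bias.
#' @param human_error_mode one of `"none"`, `"wrong_calibration"`,
#'   `"wrong_position"`, `"wrong_air_gap"`.
#' @param human_error_magnitude fractional dose error applied in
#'   `wrong_calibration` mode (default 0.05).
#' @param human_error_shift stack shift in mm applied along the depth axis in
#'   `wrong_position` (default 5) and `wrong_air_gap` (default 3, scaled by
#'   3/5) modes.
#' @return object of class `error_model`.
#' @export
error_model <- function(positioning_sd = 0, relative_noise_sd = 0,
                        background_offset = 0, calibration_bias = 0,
                        human_error_mode = c("none", "wrong_calibration",
                                             "wrong_position",
                                             "wrong_air_gap"),
                        human_error_magnitude = 0.05,
                        human_error_shift = 5) {
  human_error_mode <- match.arg(human_error_mode)
  if (positioning_sd < 0 || relative_noise_sd < 0) {
    stop("error-model standard deviations must be >= 0")
  }
  structure(
    list(positioning_sd = positioning_sd,
         relative_noise_sd = relative_noise_sd,
         background_offset = background_offset,
         calibration_bias = calibration_bias,
         human_error_mode = human_error_mode,
         human_error_magnitude = human_error_magnitude,
         human_error_shift = human_error_shift),
    class = "error_model"
  )
}

#' Measurement session: stack placement and error state
#'
#' @param position stack reference-point position `(A, B, C)` in mm,
#'   phantom frame.
#' @param seed integer seed controlling all random error draws.
#' @param errors an [error_model()].
#' @return object of class `measurement_session`.
#' @export
measurement_session <- function(position, seed = 1L, errors = error_model()) {
  stopifnot(length(position) == 3L, inherits(errors, "error_model"))
  structure(
    list(position = as.numeric(position), seed = as.integer(seed),
         errors = errors),
    class = "measurement_session"
  )
}

#' Absolute chamber positions of a session
#' @keywords internal
chamber_positions <- function(layout, session) {
  cbind(session$position[1] + layout$dx_mm,
        session$position[2] + layout$dy_mm,
        session$position[3] + layout$dz_mm)
}

#' Planned (TPS-side) doses at the chamber positions
#'
#' Trilinear interpolation of the dose grid at each chamber's effective point
#' of measurement, in layout order.
#'
#' @param grid a `dose_grid`.
#' @param layout an `ic_stack_layout`.
#' @param session a `measurement_session`.
#' @return numeric vector of planned doses in Gy (one per chamber).
#' @export
planned_doses_at_chambers <- function(grid, layout, session) {
  pos <- chamber_positions(layout, session)
  tryCatch(
    interp_dose(grid, pos),
    error = function(e) {
      stop("chamber position outside the dose grid: ", conditionMessage(e))
    }
  )
}

# 3-point Gauss-Legendre nodes/weights on [-1/2, 1/2], weights sum to 1
.GL3_NODES <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)) / 2
.GL3_W <- c(5, 8, 5) / 18

#' Simulate a chamber-stack measurement
#'
#' Synthesizes the 24 measured doses from a dose grid: for each chamber the
#' grid is volume-averaged over the sensitive volume (cylinder approximated
#' as a box, fixed 3x3x3 Gauss-Legendre quadrature) at the chamber position
#' displaced by its random positioning error, then scaled by the calibration
#' bias and multiplicative noise and shifted by the background offset.
#' Beam-quality and air-density corrections cancel exactly unless a human
#' error mode overrides them. Reproducible given the session seed.
#'
#' @param grid a `dose_grid`.
#' @param layout an `ic_stack_layout`.
#' @param session a `measurement_session`.
#' @param chamber a [chamber_spec()].
#' @return object of class `measured_set`: list with `doses` (24 Gy values)
#'   and `human_error_suspected` flag.
#' @export
simulate_measurement <- function(grid, layout, session,
                                 chamber = chamber_spec()) {
  em <- session$errors
  n <- nrow(layout)
  pos <- chamber_positions(layout, session)
  pos[, 1] <- pos[, 1] + chamber$effective_point_offset
  if (em$human_error_mode == "wrong_position") {
    pos[, 1] <- pos[, 1] + em$human_error_shift
  } else if (em$human_error_mode == "wrong_air_gap") {
    pos[, 1] <- pos[, 1] + em$human_error_shift * 3 / 5
  }
  set.seed(session$seed)
  if (em$positioning_sd > 0) {
    pos <- pos + matrix(stats::rnorm(3 * n, sd = em$positioning_sd),
                        ncol = 3)
  }
  if (chamber$sensitive_volume > 0) {
    half <- c(2 * chamber$radius, 2 * chamber$radius, chamber$length)
    avg <- numeric(n)
    for (i in seq_along(.GL3_NODES)) {
      for (j in seq_along(.GL3_NODES)) {
        for (k in seq_along(.GL3_NODES)) {
          p <- cbind(pos[, 1] + .GL3_NODES[i] * half[1],
                     pos[, 2] + .GL3_NODES[j] * half[2],
                     pos[, 3] + .GL3_NODES[k] * half[3])
          avg <- avg + .GL3_W[i] * .GL3_W[j] * .GL3_W[k] * interp_dose(grid, p)
        }
      }
    }
  } else {
    avg <- interp_dose(grid, pos)
  }
  bias <- em$calibration_bias
  if (em$human_error_mode == "wrong_calibration") {
    bias <- (1 + bias) * (1 + em$human_error_magnitude) - 1
  }
  noise <- if (em$relative_noise_sd > 0) {
    stats::rnorm(n, sd = em$relative_noise_sd)
  } else {
    numeric(n)
  }
  doses <- avg * (1 + bias) * (1 + noise) + em$background_offset
  structure(
    list(doses = doses,
         human_error_suspected = em$human_error_mode != "none"),
    class = "measured_set"
  )
}

#' @export
print.measured_set <- function(x, ...) {
  cat(sprintf("<measured_set> %d chambers, %.4g-%.4g Gy%s\n",
              length(x$doses), min(x$doses), max(x$doses),
              if (x$human_error_suspected) ", human error suspected" else ""))
  invisible(x)
}
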
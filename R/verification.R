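# Field verification: gradient-based chamber deactivation, deviation
# normalization to D_max, tolerance classification and the repeat policy.

#' Institutional tolerance configuration
#'
#' Defaults follow the institutional limits for water-phantom dose
#' verification: mean deviation within +/-5% of D_max, minimum deviation
#' >= -7%, maximum deviation <= +7%, and chamber deactivation when the local
#' dose gradient (mGy/mm) exceeds 5% of D_max (with D_max expressed in mGy).
#' All tolerance boundaries are inclusive: exact equality passes.
#'
#' @param mean_tol mean-deviation tolerance, % of D_max (applied to the
#'   absolute mean).
#' @param min_tol minimum-deviation tolerance, % of D_max (negative).
#' @param max_tol maximum-deviation tolerance, % of D_max (positive).
#' @param gradient_threshold_fraction deactivation threshold as a per-mm
#'   fraction of D_max.
#' @param gradient_metric `"norm"` (Euclidean norm of the three central
#'   differences) or `"max"` (largest absolute component).
#' @return object of class `tolerance_config`.
#' @export
tolerance_config <- function(mean_tol = 5, min_tol = -7, max_tol = 7,
                             gradient_threshold_fraction = 0.05,
                             gradient_metric = c("norm", "max")) {
  gradient_metric <- match.arg(gradient_metric)
  if (mean_tol <= 0) stop("mean tolerance must be > 0")
  if (!(min_tol < 0 && max_tol > 0)) {
    stop("min tolerance must be negative and max tolerance positive")
  }
  if (gradient_threshold_fraction <= 0) {
    stop("gradient threshold fraction must be > 0")
  }
  structure(
    list(mean_tol = mean_tol, min_tol = min_tol, max_tol = max_tol,
         gradient_threshold_fraction = gradient_threshold_fraction,
         gradient_metric = gradient_metric),
    class = "tolerance_config"
  )
}

#' Local dose gradient from the six neighboring voxels
#'
#' Estimates the dose gradient at a position from the voxel enclosing it:
#' central differences along each axis using the +/-1 voxel neighbors
#' (six neighbors in total), combined into a scalar (Euclidean norm by
#' default), returned in mGy/mm.
#'
#' @param grid a `dose_grid`.
#' @param position length-3 coordinate, or n x 3 matrix, in mm.
#' @param metric `"norm"` or `"max"`.
#' @return gradient magnitude(s) in mGy/mm.
#' @export
estimate_gradient <- function(grid, position, metric = c("norm", "max")) {
  metric <- match.arg(metric)
  if (is.null(dim(position))) position <- matrix(position, nrow = 1)
  dm <- dim(grid$values)
  ax <- list(grid$x, grid$y, grid$z)
  idx <- matrix(0L, nrow = nrow(position), ncol = 3)
  for (a in 1:3) {
    i <- as.integer(round((position[, a] - ax[[a]][1]) / grid$spacing)) + 1L
    bad <- i < 2L | i > dm[a] - 1L
    if (any(bad)) {
      stop(sprintf(
        "position %d: voxel on axis %d has no +/-1 neighbors for the gradient",
        which(bad)[1], a))
    }
    idx[, a] <- i
  }
  v <- grid$values
  gx <- (v[cbind(idx[, 1] + 1L, idx[, 2], idx[, 3])] -
           v[cbind(idx[, 1] - 1L, idx[, 2], idx[, 3])]) / (2 * grid$spacing)
  gy <- (v[cbind(idx[, 1], idx[, 2] + 1L, idx[, 3])] -
           v[cbind(idx[, 1], idx[, 2] - 1L, idx[, 3])]) / (2 * grid$spacing)
  gz <- (v[cbind(idx[, 1], idx[, 2], idx[, 3] + 1L)] -
           v[cbind(idx[, 1], idx[, 2], idx[, 3] - 1L)]) / (2 * grid$spacing)
  g <- if (metric == "norm") {
    sqrt(gx^2 + gy^2 + gz^2)
  } else {
    pmax(abs(gx), abs(gy), abs(gz))
  }
  1000 * g  # Gy/mm -> mGy/mm
}

#' Select active chambers by the gradient rule
#'
#' A chamber is deactivated when its local gradient (mGy/mm) strictly
#' exceeds `gradient_threshold_fraction` times D_max expressed in mGy;
#' equality at the threshold keeps the chamber active.
#'
#' @param gradients gradient magnitudes in mGy/mm.
#' @param d_max whole-field maximum dose in Gy.
#' @param tol a [tolerance_config()].
#' @return logical vector of active flags.
#' @export
select_active_chambers <- function(gradients, d_max, tol = tolerance_config()) {
  if (!is.finite(d_max) || d_max <= 0) stop("d_max must be > 0")
  gradients <= tol$gradient_threshold_fraction * d_max * 1000
}

#' Per-field verification record
#'
#' @param planned,measured doses in Gy (equal length).
#' @param gradient gradients in mGy/mm.
#' @param active logical active flags.
#' @param d_max whole-field maximum dose in Gy (from the grid, not the
#'   chamber subset).
#' @return object of class `verification_record`.
#' @export
verification_record <- function(planned, measured, gradient, active, d_max) {
  n <- length(planned)
  stopifnot(n >= 1L, length(measured) == n, length(gradient) == n,
            length(active) == n)
  if (!is.finite(d_max) || d_max <= 0) stop("d_max must be > 0")
  structure(
    list(planned = planned, measured = measured, gradient = gradient,
         active = as.logical(active), d_max = d_max),
    class = "verification_record"
  )
}

#' Normalized deviation summary of a verification record
#'
#' Per-chamber deviations are 100 * (measured - planned) / D_max in percent
#' of the whole-field maximum dose; mean, sample SD (0 when a single chamber
#' is active), minimum and maximum are computed over the active chambers
#' only.
#'
#' @param record a `verification_record`.
#' @return object of class `deviation_summary` with `deviations` (all
#'   chambers, % of D_max), `active`, `mean`, `sd`, `min`, `max`,
#'   `n_active`.
#' @export
compute_deviation_summary <- function(record) {
  stopifnot(inherits(record, "verification_record"))
  if (!any(record$active)) {
    stop("no evaluable chambers: all chambers are deactivated")
  }
  dev <- 100 * (record$measured - record$planned) / record$d_max
  act <- dev[record$active]
  structure(
    list(
      deviations = dev,
      active = record$active,
      mean = mean(act),
      sd = if (length(act) > 1L) stats::sd(act) else 0,
      min = min(act),
      max = max(act),
      n_active = length(act)
    ),
    class = "deviation_summary"
  )
}

# Vectorized tolerance rule shared by classify() and the cohort generators:
# pass iff |mean| <= mean_tol AND min >= min_tol AND max <= max_tol,
# boundaries inclusive.
#' Apply the tolerance rule to summary triples
#'
#' @param mean,min,max numeric vectors of per-field summary deviations in %
#'   of D_max.
#' @param tol a [tolerance_config()].
#' @return logical vector of pass flags.
#' @export
tolerances_passed <- function(mean, min, max, tol = tolerance_config()) {
  abs(mean) <= tol$mean_tol & min >= tol$min_tol & max <= tol$max_tol
}

#' Classify a deviation summary against the tolerances
#'
#' @param summary a `deviation_summary`.
#' @param tol a [tolerance_config()].
#' @return object of class `verification_result`: `summary`, `passed`,
#'   `violated_criteria` (subset of `"mean"`, `"minimum"`, `"maximum"`) and
#'   `chamber_class`, a factor over `active_within_5`, `active_5_to_7`,
#'   `active_beyond_7`, `deactivated`.
#' @export
classify <- function(summary, tol = tolerance_config()) {
  stopifnot(inherits(summary, "deviation_summary"))
  violated <- character(0)
  if (abs(summary$mean) > tol$mean_tol) violated <- c(violated, "mean")
  if (summary$min < tol$min_tol) violated <- c(violated, "minimum")
  if (summary$max > tol$max_tol) violated <- c(violated, "maximum")
  ad <- abs(summary$deviations)
  cls <- ifelse(!summary$active, "deactivated",
                ifelse(ad <= 5, "active_within_5",
                       ifelse(ad <= 7, "active_5_to_7", "active_beyond_7")))
  structure(
    list(
      summary = summary,
      passed = length(violated) == 0L,
      violated_criteria = violated,
      chamber_class = factor(cls, levels = c("active_within_5",
                                             "active_5_to_7",
                                             "active_beyond_7",
                                             "deactivated"))
    ),
    class = "verification_result"
  )
}

#' @export
print.verification_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<verification_result> %s | mean %.2f%%, sd %.2f%%, min %.2f%%, max %.2f%% (n_active = %d)\n",
    if (x$passed) "PASSED" else
      paste("FAILED:", paste(x$violated_criteria, collapse = ", ")),
    s$mean, s$sd, s$min, s$max, s$n_active))
  invisible(x)
}

#' Verify a treatment field against a measured chamber set
#'
#' Full scoring pipeline: planned doses at the chamber effective points,
#' local gradients, gradient-based activation, normalized deviations and
#' tolerance classification.
#'
#' @param grid the TPS-side `dose_grid` of the field.
#' @param layout an `ic_stack_layout`.
#' @param session the `measurement_session` used.
#' @param measured a `measured_set`.
#' @param tol a [tolerance_config()].
#' @return a `verification_result` additionally carrying the
#'   `verification_record` as element `record`.
#' @export
verify_field <- function(grid, layout, session, measured,
                         tol = tolerance_config()) {
  stopifnot(inherits(measured, "measured_set"))
  planned <- planned_doses_at_chambers(grid, layout, session)
  pos <- chamber_positions(layout, session)
  grad <- estimate_gradient(grid, pos, metric = tol$gradient_metric)
  active <- select_active_chambers(grad, grid$d_max, tol)
  record <- verification_record(planned, measured$doses, grad, active,
                                grid$d_max)
  res <- classify(compute_deviation_summary(record), tol)
  res$record <- record
  res
}

#' Decide the follow-up action after a verification
#'
#' Institutional repeat policy: a passed verification is accepted; a first
#' failure triggers a repeat measurement; a failure after a repeat is
#' accepted with justification when at most `k` active chambers lie beyond
#' +/-7% and all of them sit in the steepest-gradient positions (gradient at
#' or above the configured quantile of the field's chamber gradients);
#' otherwise the plan is adapted.
#'
#' @param result a `verification_result` (with `record`, as returned by
#'   [verify_field()]).
#' @param history list of prior `verification_result`s for the same field.
#' @param policy list with `k` (max justifiable chambers, default 2) and
#'   `justification_quantile` (default 0.75).
#' @return one of `"accept"`, `"repeat_measurement"`,
#'   `"accept_with_justification"`, `"adapt_plan"`.
#' @export
repeat_policy <- function(result, history = list(),
                          policy = list(k = 2, justification_quantile = 0.75)) {
  stopifnot(inherits(result, "verification_result"))
  if (result$passed) return("accept")
  if (length(history) == 0L) return("repeat_measurement")
  rec <- result$record
  if (is.null(rec)) stop("result carries no verification record")
  beyond <- rec$active & abs(result$summary$deviations) > 7
  if (!any(beyond)) return("adapt_plan")
  qg <- stats::quantile(rec$gradient, policy$justification_quantile,
                        names = FALSE)
  if (sum(beyond) <= policy$k && all(rec$gradient[beyond] >= qg)) {
    return("accept_with_justification")
  }
  "adapt_plan"
}
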
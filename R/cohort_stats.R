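# Cohort-level analysis of verified fields: exclusion filtering, category
# aggregation, the statistical test battery (one-sample t / Wilcoxon,
# Levene-gated two-sample t, ANOVA + Tukey HSD, Pearson correlation),
# gradient-threshold sensitivity and QA time accounting.
#
# A field-record table is a data.frame with one row per verified field and
# (at least) the columns:
#   field_id, room ("Hx"/"Ga"), ion ("p"/"He"/"C"), tps ("Syngo"/
#   "RayStation"), rashi (logical), indication, year, pos_a, pos_b, pos_c
#   (stack position, mm), volume_cm3, dev_mean, dev_sd, dev_min, dev_max
#   (% of D_max), n_active, time_s, passed (logical), repeat_index,
#   human_error_flag (logical).

.SIG_ALPHA <- 0.01

new_test_result <- function(test, statistic, p_value, groups = NULL,
                            effect = NA_real_, extra = NULL) {
  res <- list(test = test, statistic = unname(statistic),
              p_value = unname(p_value),
              significant = unname(p_value) < .SIG_ALPHA,
              groups = groups, effect = unname(effect))
  structure(c(res, extra), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p %.3g (%ssignificant at 0.01)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' Drop records flagged as human operating errors
#'
#' Measurements with retrospectively identified human operating errors
#' (wrong phantom positioning or operation, wrongly computed air gaps,
#' wrong chamber calibration factors) are excluded before any analysis.
#'
#' @param records field-record data.frame.
#' @return the retained records, with attribute `n_excluded`.
#' @export
exclude_flagged <- function(records) {
  if (nrow(records) == 0L) {
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  drop <- isTRUE_vec(records$human_error_flag)
  kept <- records[!drop, , drop = FALSE]
  attr(kept, "n_excluded") <- sum(drop)
  kept
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Aggregate field records into a cohort summary
#'
#' Per group: number of fields, mean and sample SD of the per-field mean
#' deviations, the global minimum of the per-field minima and maximum of the
#' per-field maxima, pass/fail counts and pass rate, and mean +/- SD of the
#' irradiation time and the number of activated chambers. With `group_by =
#' NULL` a single "all" row is returned. Groups with no records are omitted
#' with a warning.
#'
#' @param records field-record data.frame.
#' @param group_by character vector of grouping column names, or `NULL`.
#' @return data.frame of class `cohort_summary`, one row per group.
#' @export
aggregate_cohort <- function(records, group_by = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records to aggregate")
  if (is.null(group_by)) {
    grp <- factor(rep("all", nrow(records)))
  } else {
    missing_cols <- setdiff(group_by, names(records))
    if (length(missing_cols)) {
      stop("unknown grouping columns: ", paste(missing_cols, collapse = ", "))
    }
    grp <- interaction(records[group_by], sep = ":", drop = TRUE)
  }
  rows <- lapply(levels(grp), function(g) {
    r <- records[grp == g, , drop = FALSE]
    n <- nrow(r)
    data.frame(
      group = g,
      n = n,
      mean = mean(r$dev_mean),
      sd = if (n > 1L) stats::sd(r$dev_mean) else 0,
      single = n == 1L,
      min = min(r$dev_min),
      max = max(r$dev_max),
      n_passed = sum(r$passed),
      n_failed = sum(!r$passed),
      pass_rate = 100 * mean(r$passed),
      time_mean_s = mean(r$time_s),
      time_sd_s = if (n > 1L) stats::sd(r$time_s) else 0,
      n_active_mean = mean(r$n_active),
      n_active_sd = if (n > 1L) stats::sd(r$n_active) else 0
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' One-sample t-test of the mean deviation against zero
#'
#' @param values per-field mean deviations (% of D_max), n >= 3.
#' @return a `test_result`.
#' @export
test_mean_shift <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values")
  tt <- stats::t.test(values, mu = 0)
  # normality is reported alongside but never gates the t-test: for large,
  # symmetric samples the t-test is robust to non-normality
  sw <- if (length(values) <= 5000L) values else
    values[round(seq(1L, length(values), length.out = 5000L))]
  shapiro_p <- tryCatch(stats::shapiro.test(sw)$p.value,
                        error = function(e) NA_real_)
  new_test_result("one-sample t", tt$statistic, tt$p.value,
                  effect = mean(values),
                  extra = list(shapiro_p = shapiro_p))
}

#' One-sample Wilcoxon signed-rank test of the median against zero
#'
#' Used for the strongly asymmetric minimum/maximum deviation
#' distributions.
#'
#' @param values per-field minimum or maximum deviations, n >= 3.
#' @return a `test_result`.
#' @export
test_median_shift <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values")
  if (all(values == values[1L])) {
    stop("Wilcoxon signed-rank test undefined for all-identical values")
  }
  wt <- suppressWarnings(stats::wilcox.test(values, mu = 0))
  new_test_result("one-sample Wilcoxon signed-rank", wt$statistic,
                  wt$p.value, effect = stats::median(values))
}

#' Two-group comparison with a Levene variance gate
#'
#' Levene's test (centered on the mean) at alpha = 0.01 decides between the
#' pooled-variance two-sample t-test (variances compatible) and Welch's
#' t-test (variances unequal).
#'
#' @param a,b numeric vectors, each n >= 3.
#' @param labels optional group labels.
#' @return a `test_result`; its `test` field names the chosen variant and
#'   `levene_p` carries the gate's p-value.
#' @export
compare_groups <- function(a, b, labels = c("a", "b")) {
  if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate comparison: both groups have zero variance")
  }
  values <- c(a, b)
  g <- factor(rep(labels, c(length(a), length(b))))
  lev <- car::leveneTest(values ~ g, center = "mean")
  lev_p <- lev[["Pr(>F)"]][1L]
  equal_var <- lev_p >= .SIG_ALPHA
  tt <- stats::t.test(a, b, var.equal = equal_var)
  new_test_result(
    if (equal_var) "two-sample t (pooled)" else "Welch t",
    tt$statistic, tt$p.value, groups = labels,
    effect = mean(a) - mean(b),
    extra = list(levene_p = lev_p)
  )
}

#' Multi-group comparison: one-way ANOVA with Tukey HSD post hoc
#'
#' Tukey's HSD pairwise comparisons are run only when the ANOVA is
#' significant at alpha = 0.01.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3).
#' @return a `test_result` with element `pairwise` (the Tukey table, or
#'   `NULL` when the ANOVA is not significant).
#' @export
compare_multi <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 3L)) {
    stop("each group needs n >= 3")
  }
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("degenerate comparison: all groups have zero variance")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  p <- an[["Pr(>F)"]][1L]
  pairwise <- NULL
  if (p < .SIG_ALPHA) {
    tk <- stats::TukeyHSD(fit)$g
    pairwise <- data.frame(
      pair = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < .SIG_ALPHA,
      row.names = NULL
    )
  }
  new_test_result("one-way ANOVA", an[["F value"]][1L], p,
                  groups = names(groups),
                  extra = list(pairwise = pairwise))
}

#' Pearson correlation of deviations with a covariate
#'
#' Used for the mean deviation versus the stack position along each phantom
#' axis and versus the target volume.
#'
#' @param values per-field mean deviations.
#' @param covariate paired covariate (position in mm, volume in cm^3, ...).
#' @return a `test_result` with `effect` = r.
#' @export
correlate <- function(values, covariate) {
  if (length(values) != length(covariate)) stop("inputs must be paired")
  if (length(values) < 3L) stop("need at least 3 pairs")
  if (stats::var(covariate) == 0) stop("covariate has zero variance")
  ct <- stats::cor.test(values, covariate, method = "pearson")
  new_test_result("Pearson correlation", ct$statistic, ct$p.value,
                  effect = unname(ct$estimate))
}

#' Pass-rate sensitivity to the gradient deactivation threshold
#'
#' Re-runs chamber activation and tolerance classification of every field at
#' each candidate threshold (per-mm fraction of D_max) using the retained
#' per-chamber data, and reports the pass rate and mean number of active
#' chambers per threshold. Because activation is `gradient <= threshold *
#' D_max`, the active set shrinks monotonically (by set inclusion) as the
#' threshold gets stricter; this is asserted.
#'
#' @param details list of per-field data.frames with columns `planned`,
#'   `measured`, `gradient` and attribute-like column `d_max` (constant per
#'   field), e.g. the `details` element of [generate_mechanistic_cohort()].
#' @param thresholds numeric vector of threshold fractions (e.g.
#'   `c(0.05, 0.04)`).
#' @param tol base [tolerance_config()]; its mean/min/max limits are kept.
#' @return data.frame with `threshold`, `pass_rate` (%), `mean_n_active`,
#'   `n_unscorable` (fields with no active chamber at that threshold; these
#'   are excluded from the pass rate).
#' @export
threshold_sensitivity <- function(details, thresholds,
                                  tol = tolerance_config()) {
  stopifnot(length(details) >= 1L)
  ord <- order(thresholds, decreasing = TRUE)
  prev_active <- NULL
  out <- lapply(thresholds[ord], function(th) {
    tol_th <- tol
    tol_th$gradient_threshold_fraction <- th
    act_list <- vector("list", length(details))
    passed <- rep(NA, length(details))
    n_active <- numeric(length(details))
    for (i in seq_along(details)) {
      d <- details[[i]]
      active <- select_active_chambers(d$gradient, d$d_max[1L], tol_th)
      act_list[[i]] <- active
      n_active[i] <- sum(active)
      if (any(active)) {
        rec <- verification_record(d$planned, d$measured, d$gradient,
                                   active, d$d_max[1L])
        passed[i] <- classify(compute_deviation_summary(rec), tol_th)$passed
      }
    }
    if (!is.null(prev_active)) {
      incl <- mapply(function(a, b) all(!a | b), act_list, prev_active)
      stopifnot(all(incl))  # set inclusion under stricter thresholds
    }
    prev_active <<- act_list
    data.frame(threshold = th,
               pass_rate = 100 * mean(passed, na.rm = TRUE),
               mean_n_active = mean(n_active),
               n_unscorable = sum(is.na(passed)))
  })
  res <- do.call(rbind, out)
  res[match(thresholds, res$threshold), , drop = FALSE]
}

#' Per-step QA time configuration
#'
#' Defaults reflect routine practice: about 15 min of planning-system
#' preparation and 10 min of analysis per verification, and about 30 min of
#' phantom setup plus 5 min of pre-irradiation checks per irradiation
#' session.
#'
#' @param prep_min,analysis_min minutes per verification.
#' @param setup_min,preirradiation_min minutes per session.
#' @return list of per-step times (minutes).
#' @export
qa_time_config <- function(prep_min = 15, analysis_min = 10,
                           setup_min = 30, preirradiation_min = 5) {
  list(prep_min = prep_min, analysis_min = analysis_min,
       setup_min = setup_min, preirradiation_min = preirradiation_min)
}

#' QA workflow time accounting
#'
#' Beam time is the sum of the recorded per-field irradiation times;
#' overhead is `n_verifications * (prep + analysis) + n_sessions * (setup +
#' pre-irradiation)`. Either component can be supplied directly in hours
#' (e.g. from bookkeeping totals), in which case it overrides the computed
#' value.
#'
#' @param records field-record data.frame with `time_s` (or `NULL`).
#' @param n_verifications,n_sessions counts for the overhead terms.
#' @param times a [qa_time_config()].
#' @param beam_hours,overhead_hours optional direct totals in hours.
#' @return list with `beam_h`, `overhead_h`, `total_h`.
#' @export
time_accounting <- function(records = NULL, n_verifications = 0,
                            n_sessions = 0, times = qa_time_config(),
                            beam_hours = NULL, overhead_hours = NULL) {
  beam_h <- if (!is.null(beam_hours)) {
    beam_hours
  } else if (!is.null(records) && nrow(records) > 0L) {
    sum(records$time_s) / 3600
  } else {
    0
  }
  overhead_h <- if (!is.null(overhead_hours)) {
    overhead_hours
  } else {
    (n_verifications * (times$prep_min + times$analysis_min) +
       n_sessions * (times$setup_min + times$preirradiation_min)) / 60
  }
  list(beam_h = beam_h, overhead_h = overhead_h,
       total_h = beam_h + overhead_h)
}

#' Pass rate from counts
#'
#' @param n_passed,n_total counts.
#' @return pass rate in percent.
#' @export
pass_rate <- function(n_passed, n_total) {
  if (n_total <= 0) stop("total count must be > 0")
  100 * n_passed / n_total
}
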
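# Readers/writers for the package's plain-text schemas. Every writer embeds
# a versioned schema tag; readers check it. JSON via jsonlite, tabular data
# as headered CSV with a single `# ionpsqa <kind> v1` comment line.

.SCHEMA_VERSION <- "1"

.write_csv_with_header <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ionpsqa %s v%s", kind, .SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE)
}

.read_csv_with_header <- function(path, kind) {
  first <- readLines(path, n = 1L)
  expect <- sprintf("# ionpsqa %s v%s", kind, .SCHEMA_VERSION)
  if (!identical(first, expect)) {
    stop(sprintf("'%s' is not a '%s' file (missing header '%s')",
                 path, kind, expect))
  }
  utils::read.csv(path, comment.char = "#")
}

#' Write / read a treatment plan (JSON)
#'
#' Plan schema: `schema`, `ion`, `layers` (list of `range_mm`), `spots`
#' (`layer`, `y_mm`, `z_mm`, `n_particles`, `fwhm_mm`), `range_shifter`
#' (`present`, `wet_mm`), `room`, `fraction_dose_Gy`.
#'
#' @param field a `treatment_field`.
#' @param path output path.
#' @return `write_plan`: the path, invisibly. `read_plan`: a
#'   `treatment_field`.
#' @export
write_plan <- function(field, path) {
  stopifnot(inherits(field, "treatment_field"))
  obj <- list(
    schema = paste0("ionpsqa-plan-v", .SCHEMA_VERSION),
    ion = field$ion_species,
    layers = lapply(field$layer_ranges, function(r) list(range_mm = r)),
    spots = field$spots,
    range_shifter = field$range_shifter,
    room = field$room,
    fraction_dose_Gy = field$fraction_dose
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, paste0("ionpsqa-plan-v", .SCHEMA_VERSION))) {
    stop("'", path, "' is not an ionpsqa plan file")
  }
  treatment_field(
    ion_species = obj$ion,
    layer_ranges = obj$layers$range_mm,
    spots = as.data.frame(obj$spots),
    range_shifter = list(present = isTRUE(obj$range_shifter$present),
                         wet_mm = obj$range_shifter$wet_mm),
    room = obj$room,
    fraction_dose = obj$fraction_dose_Gy
  )
}

#' Write / read a chamber stack layout (CSV)
#'
#' Columns: `chamber_id`, `dx_mm`, `dy_mm`, `dz_mm`, `volume_mm3`.
#'
#' @param layout an `ic_stack_layout`.
#' @param path file path.
#' @export
write_layout <- function(layout, path) {
  .write_csv_with_header(as.data.frame(layout), path, "layout")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  layout <- .read_csv_with_header(path, "layout")
  class(layout) <- c("ic_stack_layout", "data.frame")
  validate_stack_layout(layout)
  layout
}

#' Write / read a measured chamber set (CSV)
#'
#' Columns: `chamber_id`, `dose_Gy`; the human-error flag travels in the
#' header-adjacent `human_error_suspected` column (constant).
#'
#' @param measured a `measured_set`.
#' @param path file path.
#' @export
write_measured <- function(measured, path) {
  stopifnot(inherits(measured, "measured_set"))
  df <- data.frame(chamber_id = seq_along(measured$doses),
                   dose_Gy = measured$doses,
                   human_error_suspected = measured$human_error_suspected)
  .write_csv_with_header(df, path, "measured")
  invisible(path)
}

#' @rdname write_measured
#' @export
read_measured <- function(path) {
  df <- .read_csv_with_header(path, "measured")
  if (anyNA(df$dose_Gy)) {
    stop("truncated measured-set file: missing dose in row ",
         which(is.na(df$dose_Gy))[1L])
  }
  structure(
    list(doses = df$dose_Gy,
         human_error_suspected = isTRUE(df$human_error_suspected[1L])),
    class = "measured_set"
  )
}

#' Write / read a field-record table (CSV)
#'
#' @param records field-record data.frame.
#' @param path file path.
#' @export
write_records <- function(records, path) {
  .write_csv_with_header(records, path, "records")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- .read_csv_with_header(path, "records")
  needed <- c("field_id", "dev_mean", "dev_min", "dev_max", "n_active",
              "time_s", "passed")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("records file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(df$dev_mean)) {
    stop("truncated records file: missing dev_mean in row ",
         which(is.na(df$dev_mean))[1L])
  }
  df
}

# seconds -> "mm:ss"
format_mmss <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d", s %/% 60, s %% 60)
}

#' Render a cohort summary as report files
#'
#' Writes the aggregated summary both as CSV and as a markdown table with
#' the conventional report columns: fields, mean +/- SD (one decimal),
#' min--max range, mean +/- SD time (mm:ss), passed/failed counts with
#' integer percentages, and activated chambers.
#'
#' @param summary a `cohort_summary` from [aggregate_cohort()].
#' @param csv_path,md_path output paths (either may be `NULL` to skip).
#' @return the rendered markdown lines, invisibly.
#' @export
write_cohort_report <- function(summary, csv_path = NULL, md_path = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (!is.null(csv_path)) {
    .write_csv_with_header(as.data.frame(summary), csv_path, "summary")
  }
  header <- paste(
    "| Category | Fields | Mean ± SD [%] | Range [Min–Max] [%] |",
    "Mean ± SD time [mm:ss] | Passed | Failed | Activated ICs |")
  sep <- paste(c("|", rep(" --- |", 8)), collapse = "")
  rows <- vapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    sprintf(
      "| %s | %d | %.1f ± %.1f | %.1f – %.1f | %s ± %s | %d (%d%%) | %d (%d%%) | %.0f ± %.0f |",
      s$group, s$n, s$mean, s$sd, s$min, s$max,
      format_mmss(s$time_mean_s), format_mmss(s$time_sd_s),
      s$n_passed, round(s$pass_rate), s$n_failed, round(100 - s$pass_rate),
      s$n_active_mean, s$n_active_sd)
  }, character(1))
  md <- c(header, sep, rows)
  if (!is.null(md_path)) writeLines(md, md_path)
  invisible(md)
}
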
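# Rule engines: (a) deciding whether an adapted treatment plan may skip
# re-measurement, (b) the plan data-integrity check after transfer to the
# treatment machine.

#' Plan summary for adapted-plan comparison
#'
#' @param ion_species ion species.
#' @param fraction_dose Gy per fraction.
#' @param n_fields number of fields contributing to the target volume.
#' @param couch_angles,gantry_angles per-field angles in degrees.
#' @param modifiers named numeric vector of modifier positions in mm
#'   (e.g. `c(rifi = 0, rashi = 20)`); absent modifiers omitted.
#' @param energy_levels sorted numeric vector of energy levels (layer
#'   ranges).
#' @param total_particles total particle number over all fields.
#' @param opt_meta named numeric vector of optimization metadata
#'   (`layer_spacing`, `spot_spacing`, `grid_size`, ... in consistent
#'   units).
#' @return object of class `plan_summary`.
#' @export
plan_summary <- function(ion_species, fraction_dose, n_fields,
                         couch_angles, gantry_angles,
                         modifiers = numeric(0), energy_levels,
                         total_particles,
                         opt_meta = c(layer_spacing = 2.5, spot_spacing = 4,
                                      grid_size = 2)) {
  ion_species <- match.arg(ion_species, c("proton", "helium", "carbon"))
  if (n_fields < 1L) stop("a plan must have at least one field")
  if (total_particles <= 0) stop("total particle number must be > 0")
  stopifnot(length(couch_angles) == n_fields,
            length(gantry_angles) == n_fields)
  structure(
    list(ion_species = ion_species, fraction_dose = fraction_dose,
         n_fields = n_fields, couch_angles = couch_angles,
         gantry_angles = gantry_angles, modifiers = modifiers,
         energy_levels = sort(unique(energy_levels)),
         total_particles = total_particles, opt_meta = opt_meta),
    class = "plan_summary"
  )
}

#' Default adapted-plan comparison tolerances
#'
#' Institutional criteria for omitting re-measurement of an adapted plan:
#' same ion species, same fraction dose, same number of fields, comparable
#' field contributions (optimization metadata within a relative tolerance),
#' couch and gantry angles within +/-10 degrees, beam modifiers unchanged
#' and within +/-10 cm of their original positions, the energy range
#' expanded by at most ~20 new levels, and the total particle number within
#' +/-20%.
#'
#' @param angle_tol_deg angle tolerance (default 10).
#' @param modifier_tol_mm modifier position tolerance (default 100).
#' @param energy_expansion_max maximum number of new energy levels
#'   (default 20).
#' @param particle_tol relative total-particle tolerance (default 0.20).
#' @param fraction_dose_tol absolute Gy tolerance for dose equality
#'   (default 1e-6).
#' @param opt_meta_rel_tol relative tolerance for "comparable field
#'   contributions" (default 0.10).
#' @return list of rule tolerances.
#' @export
atp_rules <- function(angle_tol_deg = 10, modifier_tol_mm = 100,
                      energy_expansion_max = 20, particle_tol = 0.20,
                      fraction_dose_tol = 1e-6, opt_meta_rel_tol = 0.10) {
  list(angle_tol_deg = angle_tol_deg, modifier_tol_mm = modifier_tol_mm,
       energy_expansion_max = energy_expansion_max,
       particle_tol = particle_tol, fraction_dose_tol = fraction_dose_tol,
       opt_meta_rel_tol = opt_meta_rel_tol)
}

# shortest arc between two angles in degrees
.angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Decide whether an adapted plan may skip re-measurement
#'
#' Compares an adapted plan against its verified original under the rules of
#' [atp_rules()]. The measurement is omitted only when every rule holds;
#' otherwise the violated rules are enumerated. A differing ion species
#' short-circuits the comparison.
#'
#' @param original,adapted `plan_summary` objects.
#' @param rules tolerances from [atp_rules()].
#' @return object of class `atp_decision`: `omit_measurement` flag and
#'   `violated_rules` character vector (subset of `"ion_species"`,
#'   `"fraction_dose"`, `"n_fields"`, `"angles"`, `"modifiers"`,
#'   `"energy_levels"`, `"particle_number"`, `"field_contributions"`).
#' @export
check_atp <- function(original, adapted, rules = atp_rules()) {
  stopifnot(inherits(original, "plan_summary"),
            inherits(adapted, "plan_summary"))
  if (original$ion_species != adapted$ion_species) {
    return(structure(list(omit_measurement = FALSE,
                          violated_rules = "ion_species"),
                     class = "atp_decision"))
  }
  violated <- character(0)
  if (abs(original$fraction_dose - adapted$fraction_dose) >
        rules$fraction_dose_tol) {
    violated <- c(violated, "fraction_dose")
  }
  if (original$n_fields != adapted$n_fields) {
    violated <- c(violated, "n_fields")
  } else {
    dc <- .angle_diff(original$couch_angles, adapted$couch_angles)
    dg <- .angle_diff(original$gantry_angles, adapted$gantry_angles)
    if (any(c(dc, dg) > rules$angle_tol_deg)) {
      violated <- c(violated, "angles")
    }
  }
  mod_ok <- setequal(names(original$modifiers), names(adapted$modifiers))
  if (mod_ok && length(original$modifiers)) {
    shared <- names(original$modifiers)
    mod_ok <- all(abs(original$modifiers[shared] -
                        adapted$modifiers[shared]) <= rules$modifier_tol_mm)
  }
  if (!mod_ok) violated <- c(violated, "modifiers")
  new_levels <- setdiff(adapted$energy_levels, original$energy_levels)
  if (length(new_levels) > rules$energy_expansion_max) {
    violated <- c(violated, "energy_levels")
  }
  # symmetric relative difference (denominator = smaller total) so the
  # comparison does not depend on which plan is called "original"
  if (abs(adapted$total_particles - original$total_particles) >
        rules$particle_tol * min(original$total_particles,
                                 adapted$total_particles)) {
    violated <- c(violated, "particle_number")
  }
  shared_meta <- intersect(names(original$opt_meta), names(adapted$opt_meta))
  meta_ok <- setequal(names(original$opt_meta), names(adapted$opt_meta)) &&
    all(abs(original$opt_meta[shared_meta] - adapted$opt_meta[shared_meta]) <=
          rules$opt_meta_rel_tol * abs(original$opt_meta[shared_meta]))
  if (!meta_ok) violated <- c(violated, "field_contributions")
  structure(
    list(omit_measurement = length(violated) == 0L,
         violated_rules = violated),
    class = "atp_decision"
  )
}

#' @export
print.atp_decision <- function(x, ...) {
  if (x$omit_measurement) {
    cat("<atp_decision> omit re-measurement (all rules hold)\n")
  } else {
    cat("<atp_decision> re-measure; violated:",
        paste(x$violated_rules, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plan record for the data-integrity check
#'
#' Snapshot of the plan tags compared after transfer from the planning
#' system to the treatment machine.
#'
#' @param approval_status,plan_label,review_timestamp,patient_name,patient_id
#'   character scalars.
#' @param field_names character vector.
#' @param n_spots total number of scan spots.
#' @param particle_tuples data.frame with columns `position`, `focus`,
#'   `energy` (one row per spot); `nrow` must equal `n_spots`.
#' @param modifiers character vector of modifier identities.
#' @param modifier_positions numeric vector (mm), same length as
#'   `modifiers`.
#' @param isocenter numeric length-3 (mm).
#' @return object of class `plan_record`.
#' @export
plan_record <- function(approval_status, plan_label, review_timestamp,
                        patient_name, patient_id, field_names, n_spots,
                        particle_tuples, modifiers = character(0),
                        modifier_positions = numeric(0),
                        isocenter = c(0, 0, 0)) {
  if (nrow(particle_tuples) != n_spots) {
    stop("spot count does not equal the length of the particle-number list")
  }
  structure(
    list(approval_status = approval_status, plan_label = plan_label,
         review_timestamp = review_timestamp, patient_name = patient_name,
         patient_id = patient_id, field_names = field_names,
         n_spots = n_spots, particle_tuples = particle_tuples,
         modifiers = modifiers, modifier_positions = modifier_positions,
         isocenter = isocenter),
    class = "plan_record"
  )
}

#' Data-integrity check of a transferred plan
#'
#' Tag-by-tag comparison of the plan as exported by the planning system and
#' as present on the treatment machine. Numeric tuples are compared exactly;
#' a missing mandatory tag is reported as a mismatch of kind `"absent"`.
#'
#' @param planned,transferred `plan_record` objects (or compatible lists).
#' @return data.frame with columns `tag` and `kind` (`"differs"` or
#'   `"absent"`); zero rows iff all compared tags agree.
#' @export
integrity_check <- function(planned, transferred) {
  tags <- c("approval_status", "plan_label", "review_timestamp",
            "patient_name", "patient_id", "field_names", "n_spots",
            "particle_tuples", "modifiers", "modifier_positions",
            "isocenter")
  out <- lapply(tags, function(tag) {
    a <- planned[[tag]]
    b <- transferred[[tag]]
    if (is.null(a) || is.null(b)) {
      return(data.frame(tag = tag, kind = "absent"))
    }
    if (!isTRUE(all.equal(a, b, tolerance = 0, check.attributes = FALSE))) {
      return(data.frame(tag = tag, kind = "differs"))
    }
    NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(tag = character(0), kind = character(0))
  }
  out
}
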
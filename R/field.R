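# Treatment fields, phantom geometry and plan-level operations.
#
# Coordinate convention (used consistently across the package): phantom frame
# with origin at the center of the water-phantom entrance window placed at the
# isocenter. Axis A = x = depth (beam direction), axis B = y = vertical,
# axis C = z = lateral; all lengths in mm. The beam enters perpendicular to
# the entrance window, so a spot's lateral position is its (y, z) at
# isocenter and its depth dose is laid down along +x.

#' Minimum pencil-beam spot FWHM per ion species (mm)
#' @keywords internal
.min_fwhm <- c(proton = 8, helium = 6, carbon = 6)

#' Water phantom geometry
#'
#' @param extent_a depth extent along the beam axis (mm).
#' @param extent_b vertical extent (mm), centered on the beam axis.
#' @param extent_c lateral extent (mm), centered on the beam axis.
#' @return object of class `water_phantom`.
#' @export
water_phantom <- function(extent_a = 200, extent_b = 120, extent_c = 120) {
  if (any(c(extent_a, extent_b, extent_c) <= 0)) {
    stop("phantom extents must be positive")
  }
  structure(
    list(extent_a = extent_a, extent_b = extent_b, extent_c = extent_c),
    class = "water_phantom"
  )
}

#' Scanned-beam treatment field
#'
#' A field is an ordered list of energy layers (given by their residual range
#' in mm of water) plus the pencil-beam spots addressing them.
#'
#' @param ion_species `"proton"`, `"helium"` or `"carbon"`.
#' @param layer_ranges numeric vector of layer ranges (mm water), one per
#'   energy layer.
#' @param spots data.frame with columns `layer` (index into `layer_ranges`),
#'   `y_mm`, `z_mm` (lateral position at isocenter), `n_particles`,
#'   `fwhm_mm`.
#' @param range_shifter list with `present` flag and water-equivalent
#'   thickness `wet_mm`.
#' @param room treatment room, `"Hx"` (horizontal) or `"Ga"` (gantry).
#' @param fraction_dose prescribed dose per fraction in Gy.
#' @return object of class `treatment_field`.
#' @export
treatment_field <- function(ion_species, layer_ranges, spots,
                            range_shifter = list(present = FALSE, wet_mm = 0),
                            room = c("Hx", "Ga"), fraction_dose = 2) {
  ion_species <- match.arg(ion_species, c("proton", "helium", "carbon"))
  room <- match.arg(room)
  if (length(layer_ranges) < 1L) stop("field needs at least one energy layer")
  if (!is.data.frame(spots) || nrow(spots) < 1L) {
    stop("field needs at least one spot")
  }
  needed <- c("layer", "y_mm", "z_mm", "n_particles", "fwhm_mm")
  missing_cols <- setdiff(needed, names(spots))
  if (length(missing_cols)) {
    stop("spots is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(spots$layer < 1L | spots$layer > length(layer_ranges))) {
    stop("spot layer index outside the field's energy layers")
  }
  if (any(spots$n_particles < 0)) stop("spot particle numbers must be >= 0")
  if (any(spots$fwhm_mm < .min_fwhm[[ion_species]])) {
    stop(sprintf("spot FWHM below the %g mm minimum for %s beams",
                 .min_fwhm[[ion_species]], ion_species))
  }
  structure(
    list(
      ion_species = ion_species,
      layer_ranges = as.numeric(layer_ranges),
      spots = spots,
      range_shifter = range_shifter,
      room = room,
      fraction_dose = fraction_dose
    ),
    class = "treatment_field"
  )
}

#' @export
print.treatment_field <- function(x, ...) {
  cat(sprintf(
    "<treatment_field> %s, %d layers (%.1f-%.1f mm), %d spots, %.2g particles%s\n",
    x$ion_species, length(x$layer_ranges), min(x$layer_ranges),
    max(x$layer_ranges), nrow(x$spots), sum(x$spots$n_particles),
    if (isTRUE(x$range_shifter$present))
      sprintf(", RaShi %.0f mm WET", x$range_shifter$wet_mm) else ""))
  invisible(x)
}

#' Effective layer ranges after the range shifter
#' @keywords internal
effective_ranges <- function(field) {
  wet <- if (isTRUE(field$range_shifter$present)) field$range_shifter$wet_mm else 0
  field$layer_ranges - wet
}

#' Insert a range shifter into a field
#'
#' Reduces every layer's effective range by the water-equivalent thickness of
#' the shifter. An optional linear FWHM broadening term models the extra
#' lateral scattering in the shifter; it is off by default because lateral
#' scattering physics is outside the model's scope.
#'
#' @param field a `treatment_field`.
#' @param thickness_mm water-equivalent thickness in mm (>= 0).
#' @param broaden_per_mm FWHM inflation in mm per mm of shifter (default 0).
#' @return the modified `treatment_field`.
#' @export
apply_range_shifter <- function(field, thickness_mm, broaden_per_mm = 0) {
  stopifnot(inherits(field, "treatment_field"))
  if (thickness_mm < 0) stop("range-shifter thickness must be >= 0")
  if (thickness_mm == 0) return(field)
  if (any(field$layer_ranges - thickness_mm <= 0)) {
    stop("range shifter would reduce a layer's effective range to <= 0 mm")
  }
  field$range_shifter <- list(present = TRUE, wet_mm = thickness_mm)
  if (broaden_per_mm > 0) {
    field$spots$fwhm_mm <- field$spots$fwhm_mm + broaden_per_mm * thickness_mm
  }
  field
}

#' Build an unweighted SOBP field template
#'
#' Lays out energy layers spanning a target depth interval at a fixed
#' layer-to-layer range step and a square lateral spot grid covering the
#' target radius plus one FWHM margin, with unit relative spot weights
#' (1e6 particles each). [optimize_sobp()] then scales the per-layer weights.
#'
#' @param ion_species ion species.
#' @param depth_range numeric length-2, proximal and distal edge of the
#'   target in mm depth.
#' @param radius lateral target radius in mm.
#' @param center lateral target center `(y, z)` in mm.
#' @param layer_spacing layer-to-layer range step in mm. The default scales
#'   with the ion's Bragg-peak width (2.5 proton, 2 helium, 1.5 carbon),
#'   giving roughly 20--35 layers for a 5 cm modulation, in line with
#'   typical scanned-beam plans; heavier ions need finer steps (or ripple
#'   filters, which are outside this model) to keep the plateau ripple
#'   small.
#' @param distal_margin extra range beyond the distal target edge in mm
#'   (default 3) so the deepest pristine peak sits past the edge and the
#'   plateau stays flat up to it.
#' @param spot_spacing lateral spot grid step in mm; default half the FWHM.
#' @param fwhm spot FWHM in mm; default the ion's minimum.
#' @param fraction_dose,room passed to [treatment_field()].
#' @return a `treatment_field` template.
#' @export
sobp_field_template <- function(ion_species, depth_range, radius,
                                center = c(0, 0), layer_spacing = NULL,
                                spot_spacing = NULL, fwhm = NULL,
                                distal_margin = 3,
                                fraction_dose = 2, room = "Hx") {
  ion_species <- match.arg(ion_species, c("proton", "helium", "carbon"))
  stopifnot(length(depth_range) == 2L, depth_range[1] < depth_range[2])
  if (is.null(layer_spacing)) {
    layer_spacing <- c(proton = 2.5, helium = 2, carbon = 1.5)[[ion_species]]
  }
  if (is.null(fwhm)) fwhm <- .min_fwhm[[ion_species]]
  if (is.null(spot_spacing)) spot_spacing <- fwhm / 2
  layer_ranges <- rev(seq(depth_range[1], depth_range[2] + distal_margin,
                          by = layer_spacing))
  if (length(layer_ranges) < 1L) stop("empty layer sequence")
  k <- ceiling((radius + fwhm) / spot_spacing)
  offsets <- (-k:k) * spot_spacing
  lattice <- expand.grid(y = offsets + center[1], z = offsets + center[2])
  spots <- do.call(rbind, lapply(seq_along(layer_ranges), function(l) {
    data.frame(layer = l, y_mm = lattice$y, z_mm = lattice$z,
               n_particles = 1e6, fwhm_mm = fwhm)
  }))
  treatment_field(ion_species, layer_ranges, spots,
                  fraction_dose = fraction_dose, room = room)
}

#' Optimize layer weights for a flat spread-out Bragg peak
#'
#' Iterative multiplicative layer-weight scaling: the central-axis dose is
#' evaluated at each layer's pristine-peak depth and every layer weight is
#' multiplied by (prescribed / current dose at its own peak) until the axis
#' dose at all peak depths is flat to 0.01% or the iteration cap is reached.
#' A final global rescale sets the mean dose over the target region of the
#' computed grid exactly to the prescription. Fully deterministic.
#'
#' @param field_template a `treatment_field`, e.g. from
#'   [sobp_field_template()]; spot particle numbers act as relative
#'   within-layer weights.
#' @param target_region list with `depth_range` (length 2, mm), `center`
#'   (lateral `(y, z)` mm) and `radius` (mm).
#' @param prescribed_dose target dose in Gy; 0 returns an all-zero field.
#' @param phantom a `water_phantom`.
#' @param spacing dose-grid spacing (mm) used for the final normalization.
#' @param max_iter iteration cap for the weight loop.
#' @return a `treatment_field` with scaled particle numbers.
#' @export
optimize_sobp <- function(field_template, target_region, prescribed_dose,
                          phantom = water_phantom(), spacing = 2,
                          max_iter = 80) {
  stopifnot(inherits(field_template, "treatment_field"))
  dr <- target_region$depth_range
  ctr <- if (is.null(target_region$center)) c(0, 0) else target_region$center
  stopifnot(length(dr) == 2L, dr[1] < dr[2])
  if (prescribed_dose < 0) stop("prescribed dose must be >= 0")
  field <- field_template
  if (prescribed_dose == 0) {
    field$spots$n_particles <- 0
    return(field)
  }
  eff <- effective_ranges(field)
  if (max(eff) < dr[2]) {
    stop(sprintf(
      "infeasible target: distal edge %.1f mm deeper than maximum layer range %.1f mm",
      dr[2], max(eff)))
  }
  nl <- length(field$layer_ranges)
  curves <- lapply(eff, function(r) make_depth_dose(field$ion_species, r))
  peak_depths <- vapply(curves, function(cv) cv$depth[which.max(cv$dose)],
                        numeric(1))
  # lateral fluence factor of each layer at the target center
  lat <- vapply(seq_len(nl), function(l) {
    sp <- field$spots[field$spots$layer == l, ]
    sigma <- sp$fwhm_mm / (2 * sqrt(2 * log(2)))
    sum(sp$n_particles * stats::dnorm(ctr[1], sp$y_mm, sigma) *
          stats::dnorm(ctr[2], sp$z_mm, sigma))
  }, numeric(1))
  if (any(lat <= 0)) stop("a layer contributes no fluence at the target center")
  # A[l, m]: axis dose at layer l's peak depth per unit weight of layer m
  A <- vapply(seq_len(nl), function(m) {
    depth_dose_at(curves[[m]], peak_depths) * lat[m]
  }, numeric(nl))
  A <- matrix(A, nrow = nl)
  w <- rep(1, nl)
  for (it in seq_len(max_iter)) {
    d_axis <- as.numeric(A %*% w)
    if (max(abs(d_axis - prescribed_dose)) < 1e-4 * prescribed_dose) break
    w <- w * prescribed_dose / d_axis
  }
  field$spots$n_particles <- field$spots$n_particles * w[field$spots$layer]
  # global rescale so that the mean target dose equals the prescription
  grid <- compute_dose_grid(field, phantom, spacing)
  mean_target <- mean_dose_in_target(grid, target_region)
  if (!is.finite(mean_target) || mean_target <= 0) {
    stop("target region received no dose; check the template geometry")
  }
  field$spots$n_particles <- field$spots$n_particles *
    prescribed_dose / mean_target
  field
}

#' Mean dose in a cylindrical target region
#'
#' @param grid a `dose_grid`.
#' @param target_region as in [optimize_sobp()].
#' @return mean dose (Gy) over voxels inside the region.
#' @export
mean_dose_in_target <- function(grid, target_region) {
  dr <- target_region$depth_range
  ctr <- if (is.null(target_region$center)) c(0, 0) else target_region$center
  in_x <- grid$x >= dr[1] & grid$x <= dr[2]
  r2 <- outer((grid$y - ctr[1])^2, (grid$z - ctr[2])^2, `+`)
  in_yz <- r2 <= target_region$radius^2
  vals <- grid$values[in_x, , , drop = FALSE]
  mask <- aperm(array(in_yz, dim = c(length(grid$y), length(grid$z),
                                     sum(in_x))), c(3, 1, 2))
  mean(vals[mask])
}
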
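# 3D dose grids in the water phantom.
#
# Voxel centers: x_i = (i - 0.5) * spacing (depth, from the entrance window),
# y_j = -extent_b/2 + (j - 0.5) * spacing, z_k likewise. `origin` is the
# coordinate of the grid corner (entrance window, lower-left), so voxel
# centers sit at origin + (index - 0.5) * spacing on every axis.

#' Construct a dose grid object
#'
#' @param values 3D array of doses in Gy, dimensions (depth, vertical,
#'   lateral).
#' @param spacing isotropic voxel spacing in mm.
#' @param origin grid-corner coordinate `(x, y, z)` in the phantom frame.
#' @return object of class `dose_grid` with voxel-center axes `x`, `y`, `z`
#'   and the whole-field maximum `d_max`.
#' @export
dose_grid <- function(values, spacing, origin) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (any(values < 0)) stop("dose values must be >= 0")
  dm <- dim(values)
  structure(
    list(
      values = values,
      spacing = spacing,
      origin = origin,
      x = origin[1] + (seq_len(dm[1]) - 0.5) * spacing,
      y = origin[2] + (seq_len(dm[2]) - 0.5) * spacing,
      z = origin[3] + (seq_len(dm[3]) - 0.5) * spacing,
      d_max = max(values)
    ),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels at %g mm, d_max = %.4g Gy\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$spacing, x$d_max))
  invisible(x)
}

#' Compute the 3D dose grid of a treatment field
#'
#' Superposes, for every spot, the ion's tabulated depth-dose curve along the
#' beam axis with a normalized 2D lateral Gaussian of the spot's FWHM:
#' dose(x, y, z) = sum over spots of N * d_layer(x) * G(y - y0, z - z0).
#' The sum is exactly linear in each spot's particle number. Layers whose
#' effective range (after the range shifter) would leave the phantom, or
#' spots whose Gaussian footprint extends beyond the lateral extents, are
#' rejected with an error naming the offender.
#'
#' @param field a `treatment_field`.
#' @param phantom a `water_phantom`.
#' @param spacing isotropic grid spacing in mm, 1 or 2 by default
#'   (other positive values are accepted for testing).
#' @return a `dose_grid`.
#' @export
compute_dose_grid <- function(field, phantom = water_phantom(), spacing = 2) {
  stopifnot(inherits(field, "treatment_field"),
            inherits(phantom, "water_phantom"))
  if (spacing <= 0) stop("grid spacing must be positive")
  nx <- floor(phantom$extent_a / spacing)
  ny <- floor(phantom$extent_b / spacing)
  nz <- floor(phantom$extent_c / spacing)
  origin <- c(0, -phantom$extent_b / 2, -phantom$extent_c / 2)
  xax <- origin[1] + (seq_len(nx) - 0.5) * spacing
  yax <- origin[2] + (seq_len(ny) - 0.5) * spacing
  zax <- origin[3] + (seq_len(nz) - 0.5) * spacing

  eff <- effective_ranges(field)
  if (any(eff <= 0)) stop("a layer's effective range is <= 0 mm")
  if (max(eff) > phantom$extent_a) {
    stop(sprintf("layer range %.1f mm exceeds phantom depth %.1f mm",
                 max(eff), phantom$extent_a))
  }
  sp <- field$spots
  bad_y <- abs(sp$y_mm) + sp$fwhm_mm > phantom$extent_b / 2
  bad_z <- abs(sp$z_mm) + sp$fwhm_mm > phantom$extent_c / 2
  if (any(bad_y | bad_z)) {
    stop(sprintf("spot %d footprint exceeds the phantom lateral extents",
                 which(bad_y | bad_z)[1]))
  }

  flat <- matrix(0, nrow = nx, ncol = ny * nz)
  for (l in seq_along(field$layer_ranges)) {
    sl <- sp[sp$layer == l & sp$n_particles > 0, , drop = FALSE]
    if (nrow(sl) == 0L) next
    curve <- make_depth_dose(field$ion_species, eff[l])
    dvec <- depth_dose_at(curve, xax)
    lat <- matrix(0, nrow = ny, ncol = nz)
    sigma <- sl$fwhm_mm / (2 * sqrt(2 * log(2)))
    for (s in seq_len(nrow(sl))) {
      lat <- lat + sl$n_particles[s] *
        (stats::dnorm(yax, sl$y_mm[s], sigma[s]) %o%
           stats::dnorm(zax, sl$z_mm[s], sigma[s]))
    }
    flat <- flat + dvec %o% as.vector(lat)
  }
  dose_grid(array(flat, dim = c(nx, ny, nz)), spacing, origin)
}

#' Trilinear interpolation of a dose grid
#'
#' @param grid a `dose_grid`.
#' @param points numeric matrix (n x 3) or length-3 vector of phantom-frame
#'   coordinates in mm.
#' @return interpolated doses in Gy.
#' @export
interp_dose <- function(grid, points) {
  stopifnot(inherits(grid, "dose_grid"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  dm <- dim(grid$values)
  ax <- list(grid$x, grid$y, grid$z)
  idx0 <- frac <- matrix(0, nrow = nrow(points), ncol = 3)
  for (a in 1:3) {
    f <- (points[, a] - ax[[a]][1]) / grid$spacing + 1
    out <- f < 1 - 1e-9 | f > dm[a] + 1e-9
    if (any(out)) {
      stop(sprintf("point %d lies outside the dose grid on axis %d",
                   which(out)[1], a))
    }
    f <- pmin(pmax(f, 1), dm[a])
    i0 <- pmin(floor(f), dm[a] - 1)
    idx0[, a] <- i0
    frac[, a] <- f - i0
  }
  v <- grid$values
  val <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) frac[, 1] else 1 - frac[, 1]) *
      (if (dy) frac[, 2] else 1 - frac[, 2]) *
      (if (dz) frac[, 3] else 1 - frac[, 3])
    val <- val + w * v[cbind(idx0[, 1] + dx, idx0[, 2] + dy, idx0[, 3] + dz)]
  }
  val
}

#' Export a depth slice of a dose grid as a data.frame
#'
#' Convenience inspection export: the (y, z) dose plane closest to a given
#' depth, in long format.
#'
#' @param grid a `dose_grid`.
#' @param depth depth in mm.
#' @return data.frame with `y_mm`, `z_mm`, `dose_Gy`.
#' @export
grid_slice <- function(grid, depth) {
  i <- which.min(abs(grid$x - depth))
  sl <- grid$values[i, , ]
  data.frame(
    y_mm = rep(grid$y, times = length(grid$z)),
    z_mm = rep(grid$z, each = length(grid$y)),
    dose_Gy = as.vector(sl)
  )
}
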
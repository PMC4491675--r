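# Pencil-beam dose engine: superpose per-spot IDD x lateral kernel in a
# water phantom.  Coordinates: right-handed, x/y in mm at isocenter; plane
# "depth" is water-equivalent distance from the phantom surface (g/cm^2);
# grids are corner-origin, row-major, with y increasing upward (rows = y).

#' Machine configuration
#'
#' @param energies data.frame with columns \code{energy_mev} (ascending) and
#'   \code{range_gcm2} (ascending with energy): the synchrotron's discrete
#'   energy list and nominal ranges in water.
#' @param max_field_cm lateral field limit at isocenter (square field,
#'   half-width \code{max_field_cm/2}), cm.
#' @param rs_wet water-equivalent thickness of the range shifter, g/cm^2.
#' @param rs_physical_cm physical range-shifter thickness, cm (metadata).
#' @param grid_spacing_mm default dose-grid pitch, mm.
#' @return object of class \code{machine_config}.
#' @export
machine_config <- function(energies, max_field_cm = 30, rs_wet = 3.7,
                           rs_physical_cm = 6.7, grid_spacing_mm = 2) {
  stopifnot(is.data.frame(energies),
            all(c("energy_mev", "range_gcm2") %in% names(energies)))
  if (any(diff(energies$energy_mev) <= 0)) stop("machine_config: energies must ascend")
  if (any(diff(energies$range_gcm2) <= 0)) stop("machine_config: ranges must ascend with energy")
  if (max_field_cm <= 0) stop("machine_config: max_field_cm must be > 0")
  if (rs_wet < 0) stop("machine_config: rs_wet must be >= 0")
  structure(list(energies = energies, max_field_cm = max_field_cm,
                 rs_wet = rs_wet, rs_physical_cm = rs_physical_cm,
                 grid_spacing_mm = grid_spacing_mm),
            class = "machine_config")
}

#' Phantom geometry (water)
#'
#' @param range_shifter logical: is the upstream degrader inserted?
#' @param rs_wet water-equivalent thickness added by the range shifter when
#'   inserted, g/cm^2.
#' @return object of class \code{phantom_geometry}.
#' @export
phantom_geometry <- function(range_shifter = FALSE, rs_wet = 3.7) {
  if (rs_wet < 0) stop("phantom_geometry: rs_wet must be >= 0")
  structure(list(medium = "water", surface_z = 0,
                 range_shifter = isTRUE(range_shifter), rs_wet = rs_wet),
            class = "phantom_geometry")
}

#' Effective water-equivalent depth for beam-model lookup
#'
#' @param depth physical water depth in the phantom, g/cm^2.
#' @param phantom a \code{\link{phantom_geometry}}.
#' @return \code{depth + rs_wet} when the range shifter is active, else
#'   \code{depth}.
#' @export
effective_depth <- function(depth, phantom) {
  stopifnot(all(depth >= 0))
  if (phantom$range_shifter) depth + phantom$rs_wet else depth
}

#' Spot-scanning treatment field
#'
#' @param spots data.frame with columns \code{layer} (energy-layer index,
#'   deepest first), \code{spot} (index within layer), \code{energy_index}
#'   (row into the machine energy table), \code{x}, \code{y} (mm at
#'   isocenter) and \code{mu} (monitor units, >= 0).
#' @param field_id label.
#' @param gantry_angle degrees (metadata).
#' @param range_shifter logical.
#' @param machine optional \code{\link{machine_config}} used to validate spot
#'   positions against the field limits.
#' @return object of class \code{pqa_field}.
#' @export
pqa_field <- function(spots, field_id = "field", gantry_angle = 0,
                      range_shifter = FALSE, machine = NULL) {
  req <- c("layer", "spot", "energy_index", "x", "y", "mu")
  stopifnot(is.data.frame(spots), all(req %in% names(spots)))
  if (nrow(spots) == 0L) stop("pqa_field: field must contain at least one spot")
  if (any(spots$mu < 0)) stop("pqa_field: spot MU must be >= 0")
  if (!is.null(machine)) {
    half <- machine$max_field_cm * 10 / 2
    if (any(abs(spots$x) > half | abs(spots$y) > half))
      stop("pqa_field: spot outside the machine's lateral field limits")
    if (any(spots$energy_index < 1 | spots$energy_index > nrow(machine$energies)))
      stop("pqa_field: energy_index outside the machine energy table")
  }
  structure(list(spots = spots, field_id = field_id,
                 gantry_angle = gantry_angle,
                 range_shifter = isTRUE(range_shifter)),
            class = "pqa_field")
}

#' @export
print.pqa_field <- function(x, ...) {
  cat(sprintf("Spot-scanning field '%s': %d spots in %d energy layers%s\n",
              x$field_id, nrow(x$spots), length(unique(x$spots$layer)),
              if (x$range_shifter) " (range shifter)" else ""))
  invisible(x)
}

#' 2D dose plane
#'
#' @param values numeric matrix [ny, nx]; rows index y (increasing upward
#'   from the origin), columns index x.
#' @param origin_x,origin_y position of the grid corner (first column /
#'   first row), mm in the isocenter frame.
#' @param spacing grid pitch, mm (> 0, isotropic).
#' @param depth water-equivalent depth of the plane, g/cm^2.
#' @param meta named list of provenance labels.
#' @return object of class \code{dose_plane}.
#' @export
dose_plane <- function(values, origin_x, origin_y, spacing, depth, meta = list()) {
  stopifnot(is.matrix(values), spacing > 0)
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose_plane: values must be finite and >= 0")
  structure(list(values = values, origin_x = origin_x, origin_y = origin_y,
                 spacing = spacing, depth = depth, meta = meta),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("Dose plane %dx%d, spacing %.2f mm, depth %.3f g/cm^2, max %.4g\n",
              nrow(x$values), ncol(x$values), x$spacing, x$depth, max(x$values)))
  invisible(x)
}

plane_x <- function(plane) plane$origin_x + (seq_len(ncol(plane$values)) - 1L) * plane$spacing
plane_y <- function(plane) plane$origin_y + (seq_len(nrow(plane$values)) - 1L) * plane$spacing

# per-spot lateral dose on a separable grid; truncated at
# rmax = 8 sigma2 + 5 s with the truncated mass renormalized
.spot_lateral <- function(xs, ys, x0, y0, z, kparams) {
  ks <- .kernel_sigma(kparams, z)
  rmax <- 8 * ks$sigma2 + 5 * ks$s
  mass <- .kernel_mass_within(rmax, z, kparams)
  dx2 <- (xs - x0)^2
  dy2 <- (ys - y0)^2
  r <- sqrt(outer(dy2, dx2, `+`))
  w1 <- 1 - kparams$w2 - kparams$wcl
  k <- w1 * .gauss2d(r, ks$sigma1) + kparams$w2 * .gauss2d(r, ks$sigma2) +
    kparams$wcl * .lorentz2d(r, ks$s)
  k[r > rmax] <- 0
  k / mass
}

#' Compute a planar dose distribution
#'
#' Superposes every spot's contribution
#' \eqn{D(x,y) = \sum_i MU_i\, IDD(E_i, z_{eff})\, K(\|(x,y)-(x_i,y_i)\|; z_{eff}, E_i)}
#' on a regular grid at one water-equivalent depth.  Exactly linear in each
#' spot's MU and deterministic.
#'
#' @param field a \code{\link{pqa_field}}.
#' @param library a beam library from \code{\link{make_beam_library}} (or any
#'   list with \code{machine}, \code{bortfeld}, \code{kernels} per energy).
#' @param phantom a \code{\link{phantom_geometry}}; when \code{NULL} one is
#'   derived from the field's range-shifter flag and the machine rs_wet.
#' @param depth plane depth, g/cm^2 (>= 0).
#' @param grid list with \code{origin} (c(x, y), mm), \code{spacing} (mm) and
#'   \code{shape} (c(nx, ny)).
#' @return a \code{\link{dose_plane}}.  If \code{depth} exceeds the deepest
#'   configured range plus margin the plane is valid but ~zero and carries
#'   \code{meta$beyond_range = TRUE}.
#' @export
compute_dose_plane <- function(field, library, phantom = NULL, depth,
                               grid = list(origin = c(-50, -50), spacing = 2,
                                           shape = c(51, 51))) {
  stopifnot(inherits(field, "pqa_field"))
  if (depth < 0) stop("compute_dose_plane: depth must be >= 0")
  if (is.null(phantom))
    phantom <- phantom_geometry(field$range_shifter, library$machine$rs_wet)
  zeff <- effective_depth(depth, phantom)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  xs <- grid$origin[1] + (seq_len(nx) - 1L) * grid$spacing
  ys <- grid$origin[2] + (seq_len(ny) - 1L) * grid$spacing
  vals <- matrix(0, nrow = ny, ncol = nx)
  spots <- field$spots
  beyond <- zeff > max(vapply(library$bortfeld, `[[`, numeric(1), "R0")) + 2
  for (ei in unique(spots$energy_index)) {
    bp <- library$bortfeld[[ei]]
    kp <- library$kernels[[ei]]
    idd <- bortfeld_idd(zeff, bp)
    if (idd <= 0) next
    sub <- spots[spots$energy_index == ei & spots$mu > 0, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      # mu multiplies last so dose is bit-exactly linear in each spot's MU
      vals <- vals + sub$mu[i] *
        (idd * .spot_lateral(xs, ys, sub$x[i], sub$y[i], zeff, kp))
    }
  }
  dose_plane(vals, grid$origin[1], grid$origin[2], grid$spacing, depth,
             meta = list(field_id = field$field_id, beyond_range = beyond,
                         range_shifter = phantom$range_shifter))
}

#' Compute a central- or off-axis depth-dose curve
#'
#' Evaluates the engine's dose at a fixed lateral point for a list of depths
#' by direct superposition (no planar grid), consistent with
#' \code{\link{compute_dose_plane}} interpolated at the same point.
#'
#' @inheritParams compute_dose_plane
#' @param x,y query point, mm.
#' @param depths ascending depths, g/cm^2.
#' @return a \code{\link{depth_dose_curve}} (values in engine dose units).
#' @export
compute_depth_dose <- function(field, library, phantom = NULL, x, y, depths) {
  stopifnot(inherits(field, "pqa_field"))
  if (length(depths) == 0L) stop("compute_depth_dose: empty depth list")
  if (any(diff(depths) <= 0) && length(depths) > 1L)
    stop("compute_depth_dose: depths must be strictly increasing")
  if (is.null(phantom))
    phantom <- phantom_geometry(field$range_shifter, library$machine$rs_wet)
  spots <- field$spots[field$spots$mu > 0, , drop = FALSE]
  vals <- vapply(depths, function(d) {
    zeff <- effective_depth(d, phantom)
    tot <- 0
    for (ei in unique(spots$energy_index)) {
      bp <- library$bortfeld[[ei]]; kp <- library$kernels[[ei]]
      idd <- bortfeld_idd(zeff, bp)
      if (idd <= 0) next
      sub <- spots[spots$energy_index == ei, , drop = FALSE]
      ks <- .kernel_sigma(kp, zeff)
      rmax <- 8 * ks$sigma2 + 5 * ks$s
      mass <- .kernel_mass_within(rmax, zeff, kp)
      r <- sqrt((sub$x - x)^2 + (sub$y - y)^2)
      w1 <- 1 - kp$w2 - kp$wcl
      k <- w1 * .gauss2d(r, ks$sigma1) + kp$w2 * .gauss2d(r, ks$sigma2) +
        kp$wcl * .lorentz2d(r, ks$s)
      k[r > rmax] <- 0
      tot <- tot + idd * sum(sub$mu * k / mass)
    }
    tot
  }, numeric(1))
  depth_dose_curve(depths, vals, energy_label = NA_real_)
}
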
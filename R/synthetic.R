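# Synthetic-data generators: beam libraries, fields, QA patterns, simulated
# "measurements" and delivery logs, all pure functions of (parameters, seed)
# with ground truth emitted alongside.

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Measurement noise model
#'
#' Stands in for detector noise and setup error of planar measurements:
#' an optional depth offset (re-computation at a shifted depth), a lateral
#' shift (resampling), then multiplicative and additive Gaussian noise.
#'
#' @param multiplicative_sd fractional SD of multiplicative noise (default
#'   0.01: 1% dose noise).
#' @param additive_sd additive SD in dose units.
#' @param lateral_shift c(dx, dy), mm.
#' @param depth_offset_mm depth setup error, mm of water.
#' @param seed RNG seed.
#' @return object of class \code{noise_model}.
#' @export
noise_model <- function(multiplicative_sd = 0.01, additive_sd = 0,
                        lateral_shift = c(0, 0), depth_offset_mm = 0,
                        seed = 1L) {
  if (multiplicative_sd < 0 || additive_sd < 0)
    stop("noise_model: noise SDs must be >= 0")
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd,
                 lateral_shift = lateral_shift,
                 depth_offset_mm = depth_offset_mm, seed = as.integer(seed)),
            class = "noise_model")
}

#' Delivery jitter model
#'
#' Emulates the spot-position monitor record: per fraction, recorded =
#' planned + systematic + N(0, random_sd) per axis and recorded MU =
#' planned * (1 + N(0, mu_sd)).  Defaults reflect the clinically observed
#' scales (random spot-position reproducibility ~0.2 mm).
#'
#' @param systematic c(dx, dy), mm.
#' @param random_sd per-axis random SD, mm (default 0.2).
#' @param mu_sd fractional MU noise SD (default 0.005).
#' @param n_fractions number of fractions (default 33).
#' @param seed RNG seed.
#' @return object of class \code{jitter_model}.
#' @export
jitter_model <- function(systematic = c(0, 0), random_sd = 0.2, mu_sd = 0.005,
                         n_fractions = 33L, seed = 1L) {
  if (random_sd < 0 || mu_sd < 0) stop("jitter_model: SDs must be >= 0")
  if (n_fractions < 1L) stop("jitter_model: n_fractions must be >= 1")
  structure(list(systematic = systematic, random_sd = random_sd,
                 mu_sd = mu_sd, n_fractions = as.integer(n_fractions),
                 seed = as.integer(seed)),
            class = "jitter_model")
}

#' Generate a synthetic beam library
#'
#' Builds a full machine model: nominal ranges evenly spaced over the span,
#' energies from the two-point range-energy calibration of the machine's
#' endpoints (72.5 MeV -> 4.0 g/cm^2, 221.8 MeV -> 30.6 g/cm^2), Bortfeld
#' parameters per energy (straggling width from the ~1.2% x R0^0.935
#' empirical rule), and depth-growing lateral kernels whose surface widths
#' shrink with energy, as in-air spot sizes do.
#'
#' @param n_energies number of energies (default 94).
#' @param range_span c(min, max) nominal ranges, g/cm^2, within (0, 40]
#'   (default c(4.0, 30.6)).
#' @param max_field_cm lateral field limit, cm (default 30).
#' @param rs_wet range-shifter water-equivalent thickness, g/cm^2; default
#'   maps the shallowest configured range to 0.3 g/cm^2.
#' @return list with \code{machine} (\code{\link{machine_config}}),
#'   \code{bortfeld} (list of \code{\link{bortfeld_params}}), \code{kernels}
#'   (list of \code{\link{lateral_kernel_params}}), \code{alpha}, \code{p}.
#' @export
make_beam_library <- function(n_energies = 94L, range_span = c(4.0, 30.6),
                              max_field_cm = 30, rs_wet = NULL) {
  if (n_energies < 2L) stop("make_beam_library: n_energies must be >= 2")
  if (range_span[1] <= 0 || range_span[2] > 40 || range_span[1] >= range_span[2])
    stop("make_beam_library: range span must lie within (0, 40] g/cm^2")
  cal <- calibrate_range_energy()
  ranges <- seq(range_span[1], range_span[2], length.out = n_energies)
  energies <- energy_from_range(ranges, cal$alpha, cal$p)
  if (is.null(rs_wet)) rs_wet <- max(range_span[1] - 0.3, 0)
  machine <- machine_config(
    data.frame(energy_mev = energies, range_gcm2 = ranges),
    max_field_cm = max_field_cm, rs_wet = rs_wet)
  emin <- energies[1]; emax <- energies[n_energies]
  bortfeld <- vector("list", n_energies)
  kernels <- vector("list", n_energies)
  for (i in seq_len(n_energies)) {
    R0 <- ranges[i]
    bortfeld[[i]] <- bortfeld_params(
      R0 = R0, sigma = 0.012 * R0^0.935, epsilon = 0.1, phi = 1,
      p = cal$p, alpha = cal$alpha, energy = energies[i])
    # in-air spot size shrinks with energy (6 -> 3 mm); in-water MCS growth
    # reaches ~2.1% of range at the range, 40/60 linear/quadratic split
    frac <- if (n_energies > 1L) (energies[i] - emin) / (emax - emin) else 0
    sa1 <- 6 - 3 * frac
    gR <- 0.21 * R0          # mm at z = R0 (2.1% of range, R0 in g/cm^2 ~ cm)
    kernels[[i]] <- lateral_kernel_params(
      sigma_air1 = sa1, sigma_air2 = 1.8 * sa1, w_air = 0.05,
      growth1 = c(0.4 * gR / R0, 0.6 * gR / R0^2),
      growth2 = c(0.6 * gR / R0, 0.9 * gR / R0^2),
      w2 = 0.05, wcl = 0.03, s0 = 10, s1 = 0.3, R0 = R0)
  }
  list(machine = machine, bortfeld = bortfeld, kernels = kernels,
       alpha = cal$alpha, p = cal$p)
}

#' Synthetic Bragg curves sampled from a beam library
#'
#' @param library a beam library from \code{\link{make_beam_library}}.
#' @param energy_indices which energies to sample.
#' @param dz depth step, g/cm^2 (default 0.05).
#' @param noise_sd multiplicative Gaussian noise SD (e.g. 0.01 for 1%).
#' @param seed RNG seed (used only when \code{noise_sd > 0}).
#' @return list of \code{\link{depth_dose_curve}} objects.
#' @export
make_bragg_curves <- function(library, energy_indices, dz = 0.05,
                              noise_sd = 0, seed = 1L) {
  curves <- lapply(energy_indices, function(i) {
    bp <- library$bortfeld[[i]]
    depths <- seq(dz, bp$R0 + 12 * bp$sigma, by = dz)
    vals <- bortfeld_idd(depths, bp)
    depth_dose_curve(depths, vals, energy_label = bp$energy)
  })
  if (noise_sd > 0) {
    curves <- .with_seed(seed, lapply(curves, function(cu) {
      cu$values <- pmax(cu$values * (1 + stats::rnorm(length(cu$values), 0, noise_sd)), 0)
      cu
    }))
  }
  curves
}

# Lawson-Hanson nonnegative least squares: min ||A w - b||, w >= 0
.nnls <- function(A, b, tol = 1e-10, maxit = 10 * ncol(A)) {
  n <- ncol(A)
  P <- logical(n)
  w <- numeric(n)
  resid <- b
  for (it in seq_len(maxit)) {
    grad <- drop(crossprod(A, resid))
    grad[P] <- -Inf
    j <- which.max(grad)
    if (grad[j] <= tol) break
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, P, drop = FALSE]
      s[P] <- drop(solve(crossprod(Ap), crossprod(Ap, b)))
      if (all(s[P] > tol)) { w <- s; break }
      neg <- P & s <= tol
      a <- min(w[neg] / (w[neg] - s[neg]))
      w <- w + a * (s - w)
      P[P & w <= tol] <- FALSE
      w[!P] <- 0
    }
    resid <- b - drop(A %*% w)
  }
  w
}

#' Generate a single-field uniform-dose (SFUD-style) field
#'
#' Lays spots on a square lattice per energy layer and solves a nonnegative
#' least-squares problem for the layer weights that flatten the central-axis
#' depth dose over the modulated span (a spread-out Bragg peak).  The layer
#' basis is the engine's own central-axis depth dose of each layer, so the
#' reported flatness is measured on exactly what the engine delivers.
#'
#' @param library a beam library.
#' @param target_range distal edge of the flat span, g/cm^2.
#' @param modulation width of the flat span, g/cm^2 (0 = single layer).
#' @param field_size_mm lateral lattice extent (square, centered), mm.
#' @param spot_pitch_mm lattice pitch, mm.
#' @param range_shifter logical.
#' @return list with \code{field} (a \code{\link{pqa_field}}),
#'   \code{layer_weights} (data.frame energy_index, weight),
#'   \code{flatness_pct} (max |deviation| from the mean over the span, %),
#'   \code{span} (c(proximal, distal) g/cm^2).
#' @export
make_uniform_field <- function(library, target_range, modulation = 0,
                               field_size_mm = 100, spot_pitch_mm = 5,
                               range_shifter = FALSE) {
  if (modulation > target_range)
    stop("make_uniform_field: modulation must not exceed target_range")
  if (spot_pitch_mm <= 0) stop("make_uniform_field: spot pitch must be > 0")
  ranges <- library$machine$energies$range_gcm2
  phantom <- phantom_geometry(range_shifter, library$machine$rs_wet)
  shift <- if (range_shifter) library$machine$rs_wet else 0
  # layer selection against effective (WET-corrected) ranges; the window
  # extends ~2 straggling widths beyond the distal edge so a Bragg peak sits
  # just past the target and the declared span stays flattenable (dose right
  # at the deepest selected peak cannot be held flat otherwise)
  lo <- target_range - modulation + shift
  hi <- target_range + shift
  distal_margin <- if (modulation > 0) 2 * 0.012 * (target_range + shift)^0.935 else 0
  sel <- which(ranges >= lo - 1e-9 & ranges <= hi + distal_margin + 1e-9)
  if (length(sel) == 0L) sel <- which.min(abs(ranges - hi))
  if (abs(ranges[max(sel)] - hi) > abs(min(diff(ranges))) + distal_margin)
    warning("make_uniform_field: no layer close to the requested distal edge")
  sel <- rev(sel)                      # deepest layer first
  half <- floor(field_size_mm / 2 / spot_pitch_mm) * spot_pitch_mm
  pos <- seq(-half, half, by = spot_pitch_mm)
  lattice <- expand.grid(x = pos, y = pos)
  spots <- do.call(rbind, lapply(seq_along(sel), function(li) {
    data.frame(layer = li - 1L, spot = seq_len(nrow(lattice)) - 1L,
               energy_index = sel[li], x = lattice$x, y = lattice$y, mu = 1)
  }))

  if (modulation <= 0 || length(sel) == 1L) {
    w <- rep(1, length(sel))
    fl <- 0
    span <- c(target_range, target_range)
  } else {
    span <- c(target_range - modulation, target_range)
    zg <- seq(span[1], span[2], length.out = max(25L, length(sel) * 3L))
    basis <- vapply(seq_along(sel), function(li) {
      sub <- pqa_field(spots[spots$layer == li - 1L, ], "layer")
      compute_depth_dose(sub, library, phantom, 0, 0, zg)$values
    }, numeric(length(zg)))
    w <- .nnls(basis, rep(1, length(zg)))
    w <- w / max(w)
    spots$mu <- w[spots$layer + 1L]
    fld <- pqa_field(spots, "sfud", range_shifter = range_shifter,
                     machine = library$machine)
    cax <- compute_depth_dose(fld, library, phantom, 0, 0, zg)$values
    fl <- 100 * max(abs(cax - mean(cax))) / mean(cax)
  }
  spots$mu <- w[spots$layer + 1L]
  field <- pqa_field(spots, "sfud", range_shifter = range_shifter,
                     machine = library$machine)
  list(field = field,
       layer_weights = data.frame(energy_index = sel, weight = w),
       flatness_pct = fl, span = span)
}

#' Modulated (IMPT-like) test field
#'
#' Multiplies a uniform field's spot MUs by a smooth log-normal random field
#' (Gaussian-smoothed white noise on the spot lattice) to emulate the
#' heterogeneous per-field dose of intensity-modulated plans with known
#' structure.
#'
#' @param uniform output of \code{\link{make_uniform_field}} (or a
#'   \code{pqa_field}).
#' @param log_sd SD of the log-modulation (default 0.3).
#' @param corr_mm correlation length of the modulation, mm (default 20).
#' @param seed RNG seed.
#' @return a \code{\link{pqa_field}}.
#' @export
make_modulated_field <- function(uniform, log_sd = 0.3, corr_mm = 20, seed = 1L) {
  field <- if (inherits(uniform, "pqa_field")) uniform else uniform$field
  spots <- field$spots
  mod <- .with_seed(seed, {
    eps <- stats::rnorm(nrow(spots))
    # Gaussian kernel smoothing over spot positions (per layer)
    sm <- numeric(nrow(spots))
    for (l in unique(spots$layer)) {
      idx <- which(spots$layer == l)
      d2 <- outer(spots$x[idx], spots$x[idx], `-`)^2 +
        outer(spots$y[idx], spots$y[idx], `-`)^2
      W <- exp(-d2 / (2 * corr_mm^2))
      sm[idx] <- drop(W %*% eps[idx]) / drop(W %*% rep(1, length(idx)))
    }
    sm / max(stats::sd(sm), 1e-12)
  })
  spots$mu <- spots$mu * exp(log_sd * mod)
  pqa_field(spots, paste0(field$field_id, "_modulated"),
            gantry_angle = field$gantry_angle,
            range_shifter = field$range_shifter)
}

#' QA pattern specification
#'
#' @param kind \code{"square"} (full lattice) or \code{"diagonal"} (spots on
#'   y = x).
#' @param pitch_mm lattice pitch, mm.
#' @param extent_mm full lattice extent, mm.
#' @param perturbations data.frame with columns \code{spot} (0-based index
#'   into the pattern), \code{dx_mm}, \code{dy_mm}; default none.  The
#'   conventional periodic-QA magnitudes are 1, 2 and 3 mm.
#' @return object of class \code{pattern_spec}.
#' @export
pattern_spec <- function(kind = c("square", "diagonal"), pitch_mm = 10,
                         extent_mm = 100, perturbations = NULL) {
  kind <- match.arg(kind)
  if (pitch_mm <= 0) stop("pattern_spec: pitch must be > 0")
  if (is.null(perturbations))
    perturbations <- data.frame(spot = integer(0), dx_mm = numeric(0),
                                dy_mm = numeric(0))
  stopifnot(all(c("spot", "dx_mm", "dy_mm") %in% names(perturbations)))
  structure(list(kind = kind, pitch_mm = pitch_mm, extent_mm = extent_mm,
                 perturbations = perturbations),
            class = "pattern_spec")
}

.pattern_n_spots <- function(spec) {
  n_side <- floor(spec$extent_mm / spec$pitch_mm) + 1L
  if (spec$kind == "square") n_side^2 else n_side
}

#' Generate a QA pattern field with ground-truth perturbations
#'
#' Spots on a square or diagonal lattice; the listed perturbations describe
#' how the machine will (mis)deliver those spots, so logs simulated from the
#' ground-truth table carry known offsets while the field itself holds the
#' ideal planned lattice.
#'
#' @param spec a \code{\link{pattern_spec}}.
#' @param library a beam library (the pattern is delivered at one energy).
#' @param energy_index energy to use (default: middle of the list).
#' @return list with \code{field} (planned lattice), \code{truth}
#'   (data.frame layer, spot, dx_mm, dy_mm, magnitude_mm).
#' @export
make_pattern_field <- function(spec, library, energy_index = NULL) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (is.null(energy_index))
    energy_index <- ceiling(length(library$bortfeld) / 2)
  half <- spec$extent_mm / 2
  pos <- seq(-half, half, by = spec$pitch_mm)
  if (spec$kind == "square") {
    g <- expand.grid(x = pos, y = pos)
  } else {
    g <- data.frame(x = pos, y = pos)
  }
  n <- nrow(g)
  pert <- spec$perturbations
  if (nrow(pert) && any(pert$spot < 0 | pert$spot >= n))
    stop("make_pattern_field: perturbation spot index out of range")
  spots <- data.frame(layer = 0L, spot = seq_len(n) - 1L,
                      energy_index = energy_index, x = g$x, y = g$y, mu = 1)
  truth <- data.frame(layer = 0L, spot = spots$spot, dx_mm = 0, dy_mm = 0)
  if (nrow(pert)) {
    truth$dx_mm[match(pert$spot, truth$spot)] <- pert$dx_mm
    truth$dy_mm[match(pert$spot, truth$spot)] <- pert$dy_mm
  }
  truth$magnitude_mm <- sqrt(truth$dx_mm^2 + truth$dy_mm^2)
  list(field = pqa_field(spots, paste0("pattern_", spec$kind)), truth = truth)
}

# shift plane content by (dx, dy) via bilinear resampling (features move by
# +dx, +dy); cells whose source falls outside the grid become 0
.shift_plane <- function(plane, dx, dy) {
  nx <- ncol(plane$values); ny <- nrow(plane$values)
  ext_x <- (nx - 1) * plane$spacing; ext_y <- (ny - 1) * plane$spacing
  if (abs(dx) >= ext_x || abs(dy) >= ext_y)
    stop("simulate_measurement: lateral shift larger than the grid extent")
  xs <- plane_x(plane); ys <- plane_y(plane)
  X <- matrix(xs, nrow = ny, ncol = nx, byrow = TRUE)
  Y <- matrix(ys, nrow = ny, ncol = nx)
  v <- .interp_plane(plane, as.numeric(X) - dx, as.numeric(Y) - dy)
  v[is.na(v)] <- 0
  plane$values <- matrix(v, nrow = ny, ncol = nx)
  plane
}

#' Simulate a planar dose "measurement"
#'
#' Applies, in order: a depth setup offset (the plane is recomputed at the
#' shifted depth when an engine context is supplied), a lateral shift
#' (bilinear resampling), then multiplicative and additive Gaussian noise
#' under the model's fixed seed.  Provenance is recorded in \code{meta}.
#'
#' @param plane the calculated \code{\link{dose_plane}} being "measured".
#' @param noise a \code{\link{noise_model}}.
#' @param engine_context optional list(field, library, phantom) enabling
#'   depth-offset recomputation.
#' @return a \code{\link{dose_plane}}.
#' @export
simulate_measurement <- function(plane, noise, engine_context = NULL) {
  stopifnot(inherits(plane, "dose_plane"), inherits(noise, "noise_model"))
  out <- plane
  if (noise$depth_offset_mm != 0) {
    if (is.null(engine_context))
      stop("simulate_measurement: depth_offset_mm requires an engine context")
    d <- plane$depth + noise$depth_offset_mm / 10
    if (d < 0) stop("simulate_measurement: depth offset puts the plane above the surface")
    out <- compute_dose_plane(engine_context$field, engine_context$library,
                              engine_context$phantom, d,
                              grid = list(origin = c(plane$origin_x, plane$origin_y),
                                          spacing = plane$spacing,
                                          shape = c(ncol(plane$values), nrow(plane$values))))
    out$depth <- plane$depth           # the detector believes the nominal depth
  }
  if (any(noise$lateral_shift != 0))
    out <- .shift_plane(out, noise$lateral_shift[1], noise$lateral_shift[2])
  if (noise$multiplicative_sd > 0 || noise$additive_sd > 0) {
    out$values <- .with_seed(noise$seed, {
      v <- out$values
      if (noise$multiplicative_sd > 0)
        v <- v * (1 + matrix(stats::rnorm(length(v), 0, noise$multiplicative_sd),
                             nrow = nrow(v)))
      if (noise$additive_sd > 0)
        v <- v + matrix(stats::rnorm(length(v), 0, noise$additive_sd), nrow = nrow(v))
      pmax(v, 0)
    })
  }
  out$meta <- c(out$meta, list(simulated_measurement = TRUE,
                               noise = unclass(noise)))
  out
}

#' Simulate a spot-delivery log
#'
#' Per fraction, recorded = planned + per-spot offset + systematic +
#' N(0, random_sd) per axis; recorded MU = planned MU * (1 + N(0, mu_sd)).
#' Reproducible under the model's seed.
#'
#' @param field the planned \code{\link{pqa_field}}.
#' @param jitter a \code{\link{jitter_model}}.
#' @param spot_offsets optional ground-truth table (layer, spot, dx_mm,
#'   dy_mm), e.g. from \code{\link{make_pattern_field}}: deterministic
#'   per-spot delivery offsets.
#' @return spot-log data.frame (see \code{\link{parse_spot_log}}).
#' @export
simulate_log <- function(field, jitter, spot_offsets = NULL) {
  stopifnot(inherits(field, "pqa_field"), inherits(jitter, "jitter_model"))
  spots <- field$spots
  off_x <- rep(0, nrow(spots)); off_y <- rep(0, nrow(spots))
  if (!is.null(spot_offsets)) {
    idx <- match(paste(spots$layer, spots$spot),
                 paste(spot_offsets$layer, spot_offsets$spot))
    off_x <- ifelse(is.na(idx), 0, spot_offsets$dx_mm[idx])
    off_y <- ifelse(is.na(idx), 0, spot_offsets$dy_mm[idx])
  }
  .with_seed(jitter$seed, {
    recs <- lapply(seq_len(jitter$n_fractions), function(fx) {
      n <- nrow(spots)
      data.frame(fraction = fx, layer = spots$layer, spot = spots$spot,
                 planned_x = spots$x, planned_y = spots$y,
                 recorded_x = spots$x + off_x + jitter$systematic[1] +
                   stats::rnorm(n, 0, jitter$random_sd),
                 recorded_y = spots$y + off_y + jitter$systematic[2] +
                   stats::rnorm(n, 0, jitter$random_sd),
                 planned_mu = spots$mu,
                 recorded_mu = pmax(spots$mu * (1 + stats::rnorm(n, 0, jitter$mu_sd)), 0))
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}
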
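# Analytical beam data: Bragg-curve (IDD) model, range-energy calibration,
# and the lateral pencil-beam kernel.

# Bortfeld shape constants for water (beta: slope of the fluence reduction
# per cm, gamma_b: fraction of locally absorbed dose from nuclear events).
.BORTFELD_BETA <- 0.012
.BORTFELD_GAMMA <- 0.6

#' Bortfeld Bragg-curve parameters for one beam energy
#'
#' Bundles the parameters of the analytical Bragg curve used as the integral
#' depth dose (IDD) of a monoenergetic proton pencil beam in water.
#'
#' @param R0 range in water (g/cm^2): depth at which the power-law primary
#'   dose model terminates; the Bragg peak sits just proximal to it.
#' @param sigma range-straggling width (g/cm^2) of the Gaussian the pristine
#'   curve is convolved with.
#' @param epsilon low-energy tail fraction (dimensionless, in [0, 1)):
#'   weight of the additive tail term fed by the low-energy contamination of
#'   the beam spectrum.
#' @param phi fluence/dose scale (dose * cm^2 per MU).
#' @param p range-energy exponent (dimensionless, in (1.5, 2.1)).
#' @param alpha range-energy coefficient (g/cm^2 / MeV^p).
#' @param energy nominal beam energy label in MeV (optional metadata).
#' @return An object of class \code{bortfeld_params}.
#' @export
bortfeld_params <- function(R0, sigma, epsilon = 0.1, phi = 1,
                            p = 1.77, alpha = 0.0022, energy = NA_real_) {
  obj <- structure(
    list(R0 = R0, sigma = sigma, epsilon = epsilon, phi = phi,
         p = p, alpha = alpha, energy = energy),
    class = "bortfeld_params")
  validate_bortfeld_params(obj)
  obj
}

validate_bortfeld_params <- function(x) {
  stopifnot(inherits(x, "bortfeld_params"))
  if (!is.finite(x$R0) || x$R0 <= 0) stop("bortfeld_params: R0 must be > 0")
  if (!is.finite(x$sigma) || x$sigma <= 0) stop("bortfeld_params: sigma must be > 0")
  if (!is.finite(x$epsilon) || x$epsilon < 0 || x$epsilon >= 1)
    stop("bortfeld_params: epsilon must be in [0, 1)")
  if (!is.finite(x$phi) || x$phi <= 0) stop("bortfeld_params: phi must be > 0")
  if (!is.finite(x$p) || x$p <= 1.5 || x$p >= 2.1)
    stop("bortfeld_params: p must be in (1.5, 2.1)")
  if (!is.finite(x$alpha) || x$alpha <= 0) stop("bortfeld_params: alpha must be > 0")
  invisible(x)
}

#' @export
print.bortfeld_params <- function(x, ...) {
  cat(sprintf(
    "Bortfeld Bragg-curve parameters%s\n  R0 = %.4f g/cm^2, sigma = %.4f g/cm^2\n  epsilon = %.4f, phi = %.4g, p = %.4f, alpha = %.6g\n",
    if (is.finite(x$energy)) sprintf(" (%.1f MeV)", x$energy) else "",
    x$R0, x$sigma, x$epsilon, x$phi, x$p, x$alpha))
  invisible(x)
}

# Pristine (zero-straggling) Bortfeld depth-dose terms, expressed after the
# substitution v = (R0 - u)^(1/p) which removes the integrable (R0-u)^(1/p-1)
# singularity at the range.  With u = R0 - v^p:
#   a1 (R0-u)^(1/p-1) du -> a1 p dv          (stopping term)
#   a2 (R0-u)^(1/p)   du -> a2 p v^p dv      (fluence-reduction + tail term)
# so D(z) = phi * int_0^{R0^(1/p)} (a1 p + a2 p v^p) N(z - (R0 - v^p); sigma) dv.
.bortfeld_coeffs <- function(params) {
  with(params, {
    scale <- 1 / (p * alpha^(1 / p))
    list(a1 = scale,
         a2 = scale * (.BORTFELD_BETA + .BORTFELD_GAMMA * .BORTFELD_BETA * p +
                         epsilon * p / R0))
  })
}

#' Analytical Bragg curve (integral depth dose) in water
#'
#' Evaluates the Bortfeld analytical Bragg curve: a power-law stopping term
#' plus a fluence-reduction/low-energy-tail term, both convolved with a
#' Gaussian range-straggling kernel of width \code{sigma}.  The convolution
#' is performed by deterministic quadrature on a singularity-removing
#' substitution, so the value is smooth through the Bragg peak and decays as
#' the Gaussian tail beyond the range.
#'
#' @param z water-equivalent depth(s), g/cm^2 (>= 0); vectorized.
#' @param params a \code{\link{bortfeld_params}} object.
#' @return IDD value(s), dose * cm^2 per MU; same length as \code{z}.
#' @export
bortfeld_idd <- function(z, params) {
  validate_bortfeld_params(params)
  if (any(!is.finite(z)) || any(z < 0)) stop("bortfeld_idd: z must be finite and >= 0")
  if (length(z) == 0L) return(numeric(0))
  basis <- .bortfeld_basis(z, params$R0, params$sigma, params$p, params$alpha)
  unname(params$phi * (basis[, 1L] + params$epsilon * basis[, 2L]))
}

#' Calibrate the range-energy power law from two (energy, range) points
#'
#' Solves R = alpha * E^p exactly through two calibration points, e.g. the
#' machine's lowest and highest energies with their nominal ranges in water.
#'
#' @param energies two energies (MeV).
#' @param ranges the corresponding ranges (g/cm^2).
#' @return list with \code{alpha} and \code{p}.
#' @export
calibrate_range_energy <- function(energies = c(72.5, 221.8),
                                   ranges = c(4.0, 30.6)) {
  stopifnot(length(energies) == 2L, length(ranges) == 2L,
            all(energies > 0), all(ranges > 0), energies[1] != energies[2])
  p <- log(ranges[2] / ranges[1]) / log(energies[2] / energies[1])
  alpha <- ranges[1] / energies[1]^p
  list(alpha = alpha, p = p)
}

#' Range in water from beam energy (power law)
#'
#' @param E energy in MeV (vectorized).
#' @param alpha,p power-law coefficients (see \code{\link{calibrate_range_energy}}).
#' @param span optional machine energy span c(min, max); energies outside it
#'   raise a warning but are still computed.
#' @return range(s) in g/cm^2.
#' @export
range_from_energy <- function(E, alpha, p, span = NULL) {
  stopifnot(all(E > 0), alpha > 0, p > 0)
  if (!is.null(span) && any(E < span[1] | E > span[2]))
    warning("range_from_energy: energy outside configured machine span")
  alpha * E^p
}

#' Beam energy from range in water (inverse power law)
#'
#' @param R range(s) in g/cm^2.
#' @inheritParams range_from_energy
#' @return energy/energies in MeV.
#' @export
energy_from_range <- function(R, alpha, p) {
  stopifnot(all(R > 0), alpha > 0, p > 0)
  (R / alpha)^(1 / p)
}

# distal depth at which a sampled curve falls to `frac` of its maximum,
# linearly interpolated on the falling edge; used for fit initialization
.distal_frac_depth <- function(depths, values, frac = 0.8) {
  imax <- which.max(values)
  thr <- frac * values[imax]
  post <- seq(imax, length(values))
  below <- post[values[post] < thr]
  if (length(below) == 0L) return(depths[length(depths)])
  j <- below[1L]
  # interpolate between j-1 (>= thr) and j (< thr)
  d0 <- depths[j - 1L]; d1 <- depths[j]
  v0 <- values[j - 1L]; v1 <- values[j]
  d0 + (v0 - thr) / (v0 - v1) * (d1 - d0)
}

# model basis: columns A (phi-term) and B (phi*epsilon-term) evaluated with
# unit phi, so the linear coefficients can be profiled out in fitting.
# Quadrature on the substitution v = (R0-u)^(1/p); the Gaussian window is
# truncated at +/- 7 sigma around each query depth (relative error < 1e-11).
.bortfeld_basis <- function(z, R0, sigma, p, alpha) {
  scale <- 1 / (p * alpha^(1 / p))
  a1 <- scale
  a2_base <- scale * (.BORTFELD_BETA + .BORTFELD_GAMMA * .BORTFELD_BETA * p)
  a2_eps <- scale * p / R0
  V <- R0^(1 / p)
  dv <- sigma / (6 * p * V^(p - 1))
  n <- max(200L, min(20000L, ceiling(V / dv)))
  v <- seq(0, V, length.out = n + 1L)
  u <- R0 - v^p                       # descending from R0 to 0
  tw <- rep(V / n, n + 1L); tw[c(1L, n + 1L)] <- tw[1L] / 2
  wA <- (a1 + a2_base * v^p) * p * tw
  wB <- (a2_eps * v^p) * p * tw
  ur <- rev(u)                        # ascending for findInterval
  nA <- numeric(length(z)); nB <- numeric(length(z))
  m <- length(u)
  for (j in seq_along(z)) {
    lo_u <- z[j] - 7 * sigma; hi_u <- z[j] + 7 * sigma
    i1r <- findInterval(lo_u, ur) + 1L          # first ascending index >= lo_u
    i2r <- findInterval(hi_u, ur)               # last ascending index <= hi_u
    if (i2r < i1r) next
    idx <- (m - i2r + 1L):(m - i1r + 1L)        # back to descending order
    g <- stats::dnorm(z[j] - u[idx], sd = sigma)
    nA[j] <- sum(wA[idx] * g)
    nB[j] <- sum(wB[idx] * g)
  }
  cbind(A = nA, B = nB)
}

# profile the linear coefficients (c1 = phi, c2 = phi*epsilon) of one curve,
# honouring 0 <= c2 < c1 (i.e. epsilon in [0,1)) by clamping
.profile_linear <- function(basis, y) {
  A <- basis[, 1L]; B <- basis[, 2L]
  M <- crossprod(basis)
  rhs <- crossprod(basis, y)
  co <- tryCatch(drop(solve(M, rhs)), error = function(e) c(NA_real_, NA_real_))
  if (any(!is.finite(co)) || co[1] <= 0 || co[2] < 0 || co[2] >= co[1]) {
    # fall back to the constrained boundary solutions
    c1a <- sum(A * y) / sum(A * A)                 # epsilon = 0
    AB <- A + B                                    # epsilon -> 1 boundary excluded
    cands <- list(c(max(c1a, 1e-12), 0))
    if (all(is.finite(co)) && co[1] > 0) {
      cands <- c(cands, list(c(co[1], min(max(co[2], 0), co[1] * 0.999))))
    }
    sse <- vapply(cands, function(cc) sum((cc[1] * A + cc[2] * B - y)^2), numeric(1))
    co <- cands[[which.min(sse)]]
  }
  list(phi = co[1], epsilon = co[2] / co[1],
       resid = y - (co[1] * basis[, 1L] + co[2] * basis[, 2L]))
}

#' Simultaneously fit Bortfeld Bragg curves across energies
#'
#' Fits the analytical Bragg-curve model to a set of measured (or synthetic)
#' integral depth-dose curves.  With \code{share = "range_energy"} (the
#' default) the range-energy law couples the curves: the shared exponent
#' \code{p} and coefficient \code{alpha} determine every curve's range via
#' R0 = alpha * E^p, while straggling width, tail fraction and fluence scale
#' stay per-curve.  The fluence scale \code{phi} and tail fraction
#' \code{epsilon} enter linearly and are profiled out analytically at every
#' objective evaluation, leaving a small, well-conditioned nonlinear problem
#' solved deterministically from a data-driven initialization (distal-80%
#' depth for the range; no randomness).
#'
#' @param curves list of depth-dose curves from \code{\link{depth_dose_curve}};
#'   each must carry an \code{energy_label} when \code{share = "range_energy"}.
#' @param share \code{"range_energy"} (p, alpha shared; >= 2 curves required)
#'   or \code{"none"} (independent fits; alpha pinned to its initial value,
#'   since without the cross-energy coupling it is degenerate with phi).
#' @return list with \code{params} (list of \code{bortfeld_params}),
#'   \code{alpha}, \code{p}, \code{diagnostics} (per-curve residual norm,
#'   relative RMS, convergence flag).
#' @export
fit_bortfeld <- function(curves, share = c("range_energy", "none")) {
  share <- match.arg(share)
  if (!is.list(curves) || length(curves) < 1L) stop("fit_bortfeld: need at least one curve")
  lapply(curves, validate_depth_dose_curve)
  if (share == "range_energy" && length(curves) < 2L)
    stop("fit_bortfeld: shared-parameter (range-energy coupled) fit requires >= 2 curves")
  nC <- length(curves)
  E <- vapply(curves, function(cu) cu$energy_label, numeric(1))
  if (share == "range_energy" && any(!is.finite(E)))
    stop("fit_bortfeld: energy_label required on every curve for the coupled fit")
  # deterministic initialization
  R0_init <- vapply(curves, function(cu) .distal_frac_depth(cu$depths, cu$values, 0.8),
                    numeric(1))
  sg_init <- pmax(0.01 * R0_init, 1e-3)
  peak <- vapply(curves, function(cu) max(cu$values), numeric(1))

  if (share == "range_energy") {
    # parameterize the shared law as (log R0 at the geometric-mean energy, p):
    # near-orthogonal axes, unlike (log alpha, p) whose valley is extremely
    # narrow and curved
    Eref <- exp(mean(log(E)))
    cal <- stats::lm(log(R0_init) ~ log(E / Eref))
    r0 <- unname(stats::coef(cal)[1])
    p0 <- min(max(unname(stats::coef(cal)[2]), 1.55), 2.05)
    theta0 <- c(r0, p0, log(sg_init))
    lower <- c(r0 - 1, 1.51, rep(log(1e-3), nC))
    upper <- c(r0 + 1, 2.09, rep(log(5), nC))
    ps <- c(1e-3, 1e-3, rep(1e-2, nC))
    obj <- function(th) {
      p <- th[2]; R0ref <- exp(th[1]); alpha <- R0ref / Eref^p
      sg <- exp(th[2 + seq_len(nC)])
      sse <- 0
      for (i in seq_len(nC)) {
        R0 <- R0ref * (E[i] / Eref)^p
        if (R0 < min(curves[[i]]$depths) + 1e-6) return(1e10)
        basis <- .bortfeld_basis(curves[[i]]$depths, R0, sg[i], p, alpha)
        pr <- .profile_linear(basis, curves[[i]]$values)
        sse <- sse + sum((pr$resid / peak[i])^2)
      }
      sse
    }
    fit <- stats::optim(theta0, obj, method = "L-BFGS-B", lower = lower,
                        upper = upper,
                        control = list(maxit = 300, factr = 1e3, parscale = ps))
    # polish from the optimum with tighter steps (L-BFGS-B can stall early)
    fit2 <- stats::optim(fit$par, obj, method = "L-BFGS-B", lower = lower,
                         upper = upper,
                         control = list(maxit = 300, factr = 1, parscale = ps / 10))
    if (fit2$value <= fit$value) fit <- fit2
    p <- fit$par[2]
    alpha <- exp(fit$par[1]) / Eref^p
    sg <- exp(fit$par[2 + seq_len(nC)])
    R0 <- alpha * E^p
    converged <- fit$convergence == 0
  } else {
    cal <- calibrate_range_energy()
    alpha <- cal$alpha
    params_each <- vector("list", nC); sg <- numeric(nC); R0 <- numeric(nC)
    pvec <- numeric(nC); converged <- TRUE
    for (i in seq_len(nC)) {
      th0 <- c(R0_init[i], 1.77, log(sg_init[i]))
      obj1 <- function(th) {
        basis <- .bortfeld_basis(curves[[i]]$depths, th[1], exp(th[3]), th[2], alpha)
        pr <- .profile_linear(basis, curves[[i]]$values)
        sum((pr$resid / peak[i])^2)
      }
      f <- stats::optim(th0, obj1, method = "L-BFGS-B",
                        lower = c(0.5 * R0_init[i], 1.51, log(1e-3)),
                        upper = c(1.5 * R0_init[i], 2.09, log(5)),
                        control = list(maxit = 300, factr = 1e2))
      R0[i] <- f$par[1]; pvec[i] <- f$par[2]; sg[i] <- exp(f$par[3])
      converged <- converged && f$convergence == 0
    }
    p <- pvec
  }

  params <- vector("list", nC)
  resid_norm <- numeric(nC); rel_rms <- numeric(nC)
  for (i in seq_len(nC)) {
    pi_ <- if (length(p) == 1L) p else p[i]
    basis <- .bortfeld_basis(curves[[i]]$depths, R0[i], sg[i], pi_, alpha)
    pr <- .profile_linear(basis, curves[[i]]$values)
    params[[i]] <- bortfeld_params(R0 = R0[i], sigma = sg[i],
                                   epsilon = pr$epsilon, phi = pr$phi,
                                   p = pi_, alpha = alpha, energy = E[i])
    resid_norm[i] <- sqrt(sum(pr$resid^2))
    rel_rms[i] <- sqrt(mean((pr$resid / peak[i])^2))
  }
  list(params = params, alpha = alpha, p = p,
       diagnostics = data.frame(energy = E, R0 = R0, sigma = sg,
                                resid_norm = resid_norm, rel_rms = rel_rms,
                                converged = converged))
}

#' Depth-dose curve container
#'
#' @param depths ascending water-equivalent depths (g/cm^2).
#' @param values integral depth dose per MU at each depth (>= 0).
#' @param energy_label nominal energy in MeV (metadata; required for coupled
#'   fitting).
#' @return object of class \code{depth_dose_curve}.
#' @export
depth_dose_curve <- function(depths, values, energy_label = NA_real_) {
  obj <- structure(list(depths = as.numeric(depths), values = as.numeric(values),
                        energy_label = energy_label),
                   class = "depth_dose_curve")
  validate_depth_dose_curve(obj)
  obj
}

validate_depth_dose_curve <- function(x) {
  stopifnot(inherits(x, "depth_dose_curve"))
  if (length(x$depths) != length(x$values))
    stop("depth_dose_curve: depths and values must have equal length")
  if (any(diff(x$depths) <= 0)) stop("depth_dose_curve: depths must be strictly increasing")
  if (any(x$values < 0)) stop("depth_dose_curve: values must be >= 0")
  invisible(x)
}
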
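# Lateral pencil-beam kernel: Moliere core as two Gaussians plus a
# heavy-tailed (normalizable radial Lorentzian) large-angle component.

#' Depth-dependent lateral pencil-beam kernel parameters
#'
#' The in-water lateral spread of a spot is modelled as a weighted sum of two
#' Gaussians (multiple Coulomb scattering core) and a normalizable radial
#' Cauchy-Lorentz component (large-angle single scattering / nuclear halo).
#' Each Gaussian width grows with depth and is tied in quadrature to the
#' in-air spot fluence double Gaussian at the phantom surface:
#' \deqn{\sigma_k(z) = \sqrt{\sigma_{air,k}^2 + (a_{k1} z + a_{k2} z^2)^2}}
#' The Lorentzian scale grows linearly, s(z) = s0 + s1 z.
#'
#' @param sigma_air1,sigma_air2 surface (in-air) double-Gaussian widths, mm;
#'   \code{sigma_air2 >= sigma_air1}.
#' @param w_air weight of the second (wide) surface Gaussian, in [0, 1].
#' @param growth1,growth2 length-2 numeric: linear and quadratic in-water
#'   scattering growth coefficients (mm per g/cm^2 and mm per (g/cm^2)^2) for
#'   the narrow and wide Gaussian respectively.
#' @param w2 weight of the second Gaussian (constant in depth; defaults to
#'   \code{w_air}).
#' @param wcl weight of the Cauchy-Lorentz component, in [0, 1).
#' @param s0,s1 Lorentzian scale at the surface (mm) and its linear growth
#'   with depth (mm per g/cm^2).
#' @param R0 range of the associated energy (g/cm^2), the depth span over
#'   which the parameterization must stay valid.
#' @return object of class \code{lateral_kernel_params}.
#' @export
lateral_kernel_params <- function(sigma_air1, sigma_air2, w_air = 0.05,
                                  growth1 = c(0.4, 0.02),
                                  growth2 = c(0.6, 0.03),
                                  w2 = w_air, wcl = 0.03,
                                  s0 = 10, s1 = 0.3, R0 = 30) {
  obj <- structure(
    list(sigma_air1 = sigma_air1, sigma_air2 = sigma_air2, w_air = w_air,
         growth1 = growth1, growth2 = growth2, w2 = w2, wcl = wcl,
         s0 = s0, s1 = s1, R0 = R0),
    class = "lateral_kernel_params")
  validate_lateral_kernel_params(obj)
  obj
}

validate_lateral_kernel_params <- function(x) {
  stopifnot(inherits(x, "lateral_kernel_params"))
  with(x, {
    if (sigma_air1 <= 0 || sigma_air2 <= 0) stop("kernel: surface sigmas must be > 0")
    if (sigma_air2 < sigma_air1) stop("kernel: sigma_air2 must be >= sigma_air1")
    if (w_air < 0 || w_air > 1 || w2 < 0 || w2 > 1 || wcl < 0 || wcl >= 1)
      stop("kernel: weights must lie in [0, 1] (wcl < 1)")
    if (w2 + wcl > 1) stop("kernel: w2 + wcl must not exceed 1")
    if (s0 <= 0 || s1 < 0) stop("kernel: Lorentzian scale must be positive")
    if (any(growth1 < 0) || any(growth2 < 0)) stop("kernel: growth coefficients must be >= 0")
    if (any(.kernel_sigma(x, c(0, R0))$sigma2 < .kernel_sigma(x, c(0, R0))$sigma1 - 1e-12))
      stop("kernel: sigma2(z) must dominate sigma1(z)")
  })
  invisible(x)
}

# widths and scale at depth z (vectorized)
.kernel_sigma <- function(params, z) {
  g1 <- params$growth1[1] * z + params$growth1[2] * z^2
  g2 <- params$growth2[1] * z + params$growth2[2] * z^2
  list(sigma1 = sqrt(params$sigma_air1^2 + g1^2),
       sigma2 = sqrt(params$sigma_air2^2 + g2^2),
       s = params$s0 + params$s1 * z)
}

# unit-integral radial components (areal density, mm^-2)
.gauss2d <- function(r, sigma) exp(-r^2 / (2 * sigma^2)) / (2 * pi * sigma^2)
.lorentz2d <- function(r, s) (1 / (pi * s^2)) / (1 + (r / s)^2)^2

#' Evaluate the lateral pencil-beam kernel
#'
#' Areal density (mm^-2) of the lateral dose spread at radial distance
#' \code{r} from the spot axis and water-equivalent depth \code{z}.  The
#' kernel is radially symmetric and its 2D plane integral is 1 at every
#' depth (each component is individually normalized).
#'
#' @param r radial distance(s), mm (>= 0); vectorized.
#' @param z water-equivalent depth, g/cm^2 (scalar).
#' @param params a \code{\link{lateral_kernel_params}} object.
#' @return kernel value(s), mm^-2.
#' @export
lateral_kernel <- function(r, z, params) {
  validate_lateral_kernel_params(params)
  if (any(r < 0)) stop("lateral_kernel: r must be >= 0")
  if (length(z) != 1L || z < 0) stop("lateral_kernel: z must be a scalar >= 0")
  ks <- .kernel_sigma(params, z)
  w1 <- 1 - params$w2 - params$wcl
  w1 * .gauss2d(r, ks$sigma1) + params$w2 * .gauss2d(r, ks$sigma2) +
    params$wcl * .lorentz2d(r, ks$s)
}

# analytic mass of the kernel inside radius rmax (for truncation
# renormalization in the dose engine)
.kernel_mass_within <- function(rmax, z, params) {
  ks <- .kernel_sigma(params, z)
  w1 <- 1 - params$w2 - params$wcl
  gmass <- function(sigma) 1 - exp(-rmax^2 / (2 * sigma^2))
  lmass <- 1 - 1 / (1 + (rmax / ks$s)^2)
  w1 * gmass(ks$sigma1) + params$w2 * gmass(ks$sigma2) + params$wcl * lmass
}
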
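# Shared fixtures, all generated in code.

# small machine model: 10 energies over the clinical range span
test_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- make_beam_library(n_energies = 10L)
    lib
  }
})

# dense library (2.5 mm layer spacing) for SOBP layer-weight tests
sobp_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- make_beam_library(n_energies = 41L,
                                                range_span = c(8, 18))
    lib
  }
})

# single unit-MU spot at the origin for a mid-range energy
single_spot_field <- function(energy_index = 5L, mu = 1, x = 0, y = 0) {
  pqa_field(data.frame(layer = 0L, spot = 0L, energy_index = energy_index,
                       x = x, y = y, mu = mu))
}

uniform_plane <- function(value = 1, n = 15L, spacing = 1, origin = -7,
                          depth = 5) {
  dose_plane(matrix(value, n, n), origin, origin, spacing, depth)
}

# smooth random dose-like plane: normalized sum of Gaussian bumps
random_smooth_plane <- function(n, spacing = 2, depth = 5) {
  v <- matrix(0, n, n)
  xs <- seq_len(n)
  for (k in 1:6) {
    cx <- stats::runif(1, 3, n - 2); cy <- stats::runif(1, 3, n - 2)
    a <- stats::runif(1, 0.3, 1); s <- stats::runif(1, 3, 8)
    v <- v + a * outer(xs, xs, function(y, x)
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)))
  }
  dose_plane(v / max(v), 0, 0, spacing, depth)
}

# perturbed partner for oracle-equivalence checks: mild noise + structure
perturbed_partner <- function(plane) {
  n <- nrow(plane$values)
  v2 <- plane$values * (1 + 0.02 * matrix(stats::rnorm(n * n), n))
  extra <- random_smooth_plane(n, plane$spacing, plane$depth)$values
  plane$values <- pmax((v2 + 0.15 * extra) / 1.1, 0)
  plane
}
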
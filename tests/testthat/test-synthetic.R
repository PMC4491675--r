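test_that("make_beam_library spans and orders the machine model", {
  lib <- make_beam_library(n_energies = 94)
  ranges <- lib$machine$energies$range_gcm2
  expect_identical(length(ranges), 94L)
  expect_identical(ranges[1], 4.0)
  expect_identical(ranges[94], 30.6)
  expect_true(all(diff(lib$machine$energies$energy_mev) > 0))
  lib2 <- make_beam_library(n_energies = 2, range_span = c(5, 10))
  expect_identical(length(lib2$bortfeld), 2L)
  expect_lt(lib2$bortfeld[[1]]$R0, lib2$bortfeld[[2]]$R0)
  expect_error(make_beam_library(n_energies = 1), ">= 2")
  expect_error(make_beam_library(range_span = c(0, 50)), "span")
  # kernels normalize at sampled depths
  k <- lib$kernels[[40]]
  R0 <- lib$bortfeld[[40]]$R0
  for (z in seq(0, R0, length.out = 5)) {
    ig <- stats::integrate(function(r) 2 * pi * r * lateral_kernel(r, z, k),
                           0, Inf, rel.tol = 1e-9)
    expect_lt(abs(ig$value - 1), 1e-4)
  }
})

test_that("make_uniform_field flattens the modulated span", {
  lib <- sobp_library()                # 2.5 mm layer spacing
  uf <- make_uniform_field(lib, 15, 5, field_size_mm = 60, spot_pitch_mm = 6)
  expect_lte(uf$flatness_pct, 3)
  # flatness verified against the engine itself
  zg <- seq(uf$span[1], uf$span[2], length.out = 30)
  cax <- compute_depth_dose(uf$field, lib, NULL, 0, 0, zg)$values
  expect_lte(100 * max(abs(cax - mean(cax))) / mean(cax), 3)
  # scale invariance of flatness
  f2 <- uf$field; f2$spots$mu <- 2 * f2$spots$mu
  cax2 <- compute_depth_dose(f2, lib, NULL, 0, 0, zg)$values
  expect_equal(cax2 / cax, rep(2, length(cax)), tolerance = 1e-12)
  # modulation 0: single deepest layer
  uf0 <- make_uniform_field(lib, 15, 0, field_size_mm = 30, spot_pitch_mm = 10)
  expect_identical(length(unique(uf0$field$spots$layer)), 1L)
  expect_identical(uf0$flatness_pct, 0)
  expect_error(make_uniform_field(lib, 5, 10), "modulation")
})

test_that("make_pattern_field lattices and ground truth", {
  lib <- test_library()
  sq <- make_pattern_field(pattern_spec("square", 10, 100), lib)
  expect_identical(nrow(sq$field$spots), 121L)
  dg <- make_pattern_field(pattern_spec("diagonal", 10, 100), lib)
  expect_identical(nrow(dg$field$spots), 11L)
  expect_identical(dg$field$spots$x, dg$field$spots$y)
  pert <- data.frame(spot = c(0L, 5L, 9L), dx_mm = c(1, 0, 3),
                     dy_mm = c(0, 2, 0))
  dgp <- make_pattern_field(pattern_spec("diagonal", 10, 100, pert), lib)
  expect_identical(sort(dgp$truth$magnitude_mm[dgp$truth$magnitude_mm > 0]),
                   c(1, 2, 3))
  bad <- data.frame(spot = 999L, dx_mm = 1, dy_mm = 0)
  expect_error(make_pattern_field(pattern_spec("diagonal", 10, 100, bad), lib),
               "out of range")
})

test_that("simulate_measurement: identity, determinism, depth closed loop", {
  lib <- test_library()
  uf <- make_uniform_field(lib, 16, 4, field_size_mm = 50, spot_pitch_mm = 5)
  grid <- list(origin = c(-20, -20), spacing = 2, shape = c(21, 21))
  nominal <- 16.2
  pl <- compute_dose_plane(uf$field, lib, NULL, nominal, grid)
  # all-zero noise model is the identity
  m0 <- simulate_measurement(pl, noise_model(0, 0))
  expect_identical(m0$values, pl$values)
  # fixed seed: bit-identical twice
  nm <- noise_model(0.02, 0, seed = 42)
  expect_identical(simulate_measurement(pl, nm)$values,
                   simulate_measurement(pl, nm)$values)
  # depth offset closes the loop with the 2.5D search
  ctx <- list(field = uf$field, library = lib, phantom = NULL)
  meas <- simulate_measurement(pl, noise_model(0, 0, depth_offset_mm = -2), ctx)
  res <- gamma_2p5d(meas, function(d) compute_dose_plane(uf$field, lib, NULL, d, grid),
                    nominal, gamma_criteria(3, 3, 10))
  expect_identical(res$best_offset_mm, -2)
  expect_error(simulate_measurement(pl, noise_model(0, 0, lateral_shift = c(500, 0))),
               "shift")
  expect_error(simulate_measurement(pl, noise_model(0, 0, depth_offset_mm = 1)),
               "engine context")
})

test_that("simulate_log closed loops with deviation_stats", {
  lib <- test_library()
  f <- make_uniform_field(lib, 12, 2, field_size_mm = 30, spot_pitch_mm = 10)$field
  # zero jitter: recorded == planned everywhere
  l0 <- simulate_log(f, jitter_model(random_sd = 0, mu_sd = 0, n_fractions = 3L))
  expect_identical(l0$recorded_x, l0$planned_x)
  expect_identical(l0$recorded_mu, l0$planned_mu)
  # pure systematic: mean deviation echoes it exactly
  ls <- simulate_log(f, jitter_model(systematic = c(1, 0), random_sd = 0,
                                     mu_sd = 0, n_fractions = 5L))
  st <- deviation_stats(ls)
  expect_identical(unname(st$overall["dx", "mean"]), 1)
  expect_identical(unname(st$overall["dy", "mean"]), 0)
  # determinism under seed
  j <- jitter_model(random_sd = 0.2, n_fractions = 2L, seed = 99)
  expect_identical(simulate_log(f, j), simulate_log(f, j))
})

test_that("reproducibility estimator is unbiased over many seeds", {
  lib <- test_library()
  f <- make_uniform_field(lib, 12, 2, field_size_mm = 40, spot_pitch_mm = 10)$field
  sigma <- 0.2
  est <- vapply(1:100, function(s) {
    recs <- simulate_log(f, jitter_model(random_sd = sigma, n_fractions = 5L,
                                         seed = s))
    st <- deviation_stats(recs)
    mean(c(st$reproducibility$pooled_sd_x, st$reproducibility$pooled_sd_y))
  }, numeric(1))
  expect_lt(abs(mean(est) / sigma - 1), 0.02)
})

test_that("modulated field preserves structure deterministically", {
  lib <- test_library()
  uf <- make_uniform_field(lib, 15, 3, field_size_mm = 40, spot_pitch_mm = 8)
  m1 <- make_modulated_field(uf, seed = 4)
  m2 <- make_modulated_field(uf, seed = 4)
  expect_identical(m1$spots$mu, m2$spots$mu)
  expect_false(identical(m1$spots$mu, uf$field$spots$mu))
  expect_true(all(m1$spots$mu > 0))
})
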
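test_that("dose plane: superposition, linearity, translation equivariance", {
  lib <- test_library()
  grid <- list(origin = c(-40, -40), spacing = 2, shape = c(41, 41))
  f1 <- single_spot_field(mu = 1)
  p1 <- compute_dose_plane(f1, lib, NULL, 8, grid)
  # two identical spots = exactly twice one spot
  f2 <- pqa_field(rbind(f1$spots, transform(f1$spots, spot = 1L)))
  p2 <- compute_dose_plane(f2, lib, NULL, 8, grid)
  expect_identical(p2$values, p1$values + p1$values)
  # machine-precision MU linearity
  f3 <- single_spot_field(mu = 3.7)
  p3 <- compute_dose_plane(f3, lib, NULL, 8, grid)
  expect_identical(p3$values, 3.7 * p1$values)
  # all-zero MU -> all-zero plane
  f0 <- single_spot_field(mu = 0)
  expect_true(all(compute_dose_plane(f0, lib, NULL, 8, grid)$values == 0))
  # translation equivariance: shift spots and grid origin together
  dxy <- c(6, -4)
  fs <- single_spot_field(x = dxy[1], y = dxy[2])
  gs <- list(origin = grid$origin + dxy, spacing = 2, shape = c(41, 41))
  ps <- compute_dose_plane(fs, lib, NULL, 8, gs)
  expect_identical(ps$values, p1$values)
})

test_that("single-spot plane integral matches MU x IDD (quadrature oracle)", {
  lib <- test_library()
  ei <- 5L
  bp <- lib$bortfeld[[ei]]
  f <- single_spot_field(energy_index = ei, mu = 2)
  # grid wide enough to capture >= 99.9% of the kernel
  grid <- list(origin = c(-150, -150), spacing = 2, shape = c(151, 151))
  for (d in c(2, 8, bp$R0 * 0.95)) {
    pl <- compute_dose_plane(f, lib, NULL, d, grid)
    integral <- sum(pl$values) * pl$spacing^2
    expect_lt(abs(integral / (2 * bortfeld_idd(d, bp)) - 1), 0.005)
  }
})

test_that("resolution stability: halving the spacing preserves the integral", {
  lib <- test_library()
  f <- single_spot_field(energy_index = 5L)
  g1 <- list(origin = c(-120, -120), spacing = 4, shape = c(61, 61))
  g2 <- list(origin = c(-120, -120), spacing = 2, shape = c(121, 121))
  i1 <- sum(compute_dose_plane(f, lib, NULL, 8, g1)$values) * 16
  i2 <- sum(compute_dose_plane(f, lib, NULL, 8, g2)$values) * 4
  expect_lt(abs(i1 / i2 - 1), 0.002)
})

test_that("compute_depth_dose agrees with planes and closed form", {
  lib <- test_library()
  ei <- 5L
  f <- single_spot_field(energy_index = ei, mu = 1.5)
  depths <- c(3, 8, 12)
  cdd <- compute_depth_dose(f, lib, NULL, 0, 0, depths)
  # closed-form product oracle at the spot axis (truncation-renormalized
  # kernel, as the engine applies it)
  kp <- lib$kernels[[ei]]
  for (k in seq_along(depths)) {
    z <- depths[k]
    ks <- protonQA:::.kernel_sigma(kp, z)
    rmax <- 8 * ks$sigma2 + 5 * ks$s
    expected <- 1.5 * bortfeld_idd(z, lib$bortfeld[[ei]]) *
      lateral_kernel(0, z, kp) / protonQA:::.kernel_mass_within(rmax, z, kp)
    expect_equal(cdd$values[k], expected, tolerance = 1e-12)
  }
  # consistency with a plane, bilinear-interpolated off-grid (grid fine
  # enough that interpolation error is below the 0.1% contract)
  grid <- list(origin = c(-2, -8), spacing = 0.25, shape = c(41, 41))
  pl <- compute_dose_plane(f, lib, NULL, 8, grid)
  off <- compute_depth_dose(f, lib, NULL, 3.3, -2.7, 8)$values
  interp <- protonQA:::.interp_plane(pl, 3.3, -2.7)
  expect_lt(abs(off / interp - 1), 1e-3)
  # locality: far outside the field the dose vanishes
  far <- compute_depth_dose(f, lib, NULL, 500, 500, depths)
  expect_true(all(far$values < 1e-6 * max(pl$values)))
  expect_error(compute_depth_dose(f, lib, NULL, 0, 0, numeric(0)), "empty")
})

test_that("range shifter shifts the Bragg peak by its WET", {
  lib <- test_library()
  ei <- 3L
  R0 <- lib$bortfeld[[ei]]$R0
  rs_wet <- lib$machine$rs_wet
  f <- single_spot_field(energy_index = ei)
  ph <- phantom_geometry(TRUE, rs_wet)
  expect_identical(effective_depth(2, phantom_geometry(FALSE)), 2)
  expect_identical(effective_depth(2, ph), 2 + rs_wet)
  # grid-search oracle: peak of the computed curve sits at R0 - rs_wet
  z <- seq(0.05, R0, by = 0.01)
  cdd <- compute_depth_dose(f, lib, ph, 0, 0, z)
  zpk <- z[which.max(cdd$values)]
  expect_lt(abs(zpk - (R0 - rs_wet)), 0.1)
})

test_that("plane and field files round-trip", {
  lib <- test_library()
  f <- single_spot_field()
  pl <- compute_dose_plane(f, lib, NULL, 8,
                           list(origin = c(-10, -12), spacing = 2.5,
                                shape = c(9, 11)))
  tmp <- tempfile(fileext = ".txt")
  write_dose_plane(pl, tmp)
  pl2 <- read_dose_plane(tmp)
  expect_identical(pl2$values, pl$values)
  expect_identical(pl2$spacing, pl$spacing)
  expect_identical(pl2$depth, pl$depth)
  expect_identical(c(pl2$origin_x, pl2$origin_y), c(pl$origin_x, pl$origin_y))

  uf <- make_uniform_field(lib, 15, 3, field_size_mm = 40, spot_pitch_mm = 10)
  tmp2 <- tempfile(fileext = ".csv")
  write_field_csv(uf$field, lib, tmp2)
  f2 <- read_field_csv(tmp2, lib)
  expect_equal(f2$spots$x, uf$field$spots$x)
  expect_equal(f2$spots$mu, uf$field$spots$mu)
  expect_identical(f2$spots$energy_index, uf$field$spots$energy_index)

  bl <- tempfile(fileext = ".json")
  write_beam_library(lib, bl)
  lib2 <- read_beam_library(bl)
  expect_equal(lib2$machine$energies, lib$machine$energies)
  expect_equal(lib2$bortfeld[[4]]$R0, lib$bortfeld[[4]]$R0)
  expect_equal(lib2$kernels[[4]]$growth1, lib$kernels[[4]]$growth1)
})

test_that("field validation enforces machine limits", {
  lib <- test_library()
  bad <- data.frame(layer = 0L, spot = 0L, energy_index = 1L,
                    x = 200, y = 0, mu = 1)
  expect_error(pqa_field(bad, machine = lib$machine), "field limits")
  expect_error(pqa_field(bad[0, ]), "at least one spot")
})
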
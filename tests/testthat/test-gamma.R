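crit33 <- gamma_criteria(3, 3, 10)

test_that("point_dose_difference arithmetic and validation", {
  expect_identical(point_dose_difference(1, 1, 1), 0)
  expect_equal(point_dose_difference(1.03, 1, 1), 3)
  expect_equal(point_dose_difference(0.97, 1, 2), -1.5)
  expect_error(point_dose_difference(1, 1, 0), "normalization")
})

test_that("gamma_2d closed forms: identity, uniform offsets, boundary", {
  r <- uniform_plane(1)
  expect_identical(gamma_2d(r, r, crit33)$pass_rate, 100)
  expect_identical(max(gamma_2d(r, r, crit33)$gamma_map), 0)
  # uniform +3% at the 3% criterion: gamma = 1 everywhere, passes (boundary)
  g1 <- gamma_2d(r, uniform_plane(1.03), crit33)
  expect_equal(max(abs(g1$gamma_map - 1)), 0, tolerance = 1e-9)
  expect_identical(g1$pass_rate, 100)
  # uniform +4.5%: gamma = 1.5, DTA cannot help in a uniform field
  g2 <- gamma_2d(r, uniform_plane(1.045), crit33)
  expect_equal(max(abs(g2$gamma_map - 1.5)), 0, tolerance = 1e-9)
  expect_identical(g2$pass_rate, 0)
  # rescaling both planes and the normalization leaves gamma invariant
  ca <- gamma_criteria(3, 3, 10, normalization = 1)
  cb <- gamma_criteria(3, 3, 10, normalization = 7)
  ga <- gamma_2d(r, uniform_plane(1.02), ca)
  gb <- gamma_2d(uniform_plane(7), uniform_plane(7 * 1.02), cb)
  expect_equal(ga$gamma_map, gb$gamma_map, tolerance = 1e-12)
})

test_that("gamma_2d: threshold exclusion and degenerate cases", {
  v <- matrix(0.05, 11, 11); v[6, 6] <- 1        # one hot pixel
  r <- dose_plane(v, -5, -5, 1, 5)
  g <- gamma_2d(r, r, crit33)
  expect_identical(g$n_evaluated, 1L)            # 5% points excluded
  expect_identical(sum(!is.na(g$gamma_map)), 1L)
  low <- dose_plane(matrix(0.05, 5, 5), -2, -2, 1, 5)
  expect_warning(g0 <- gamma_2d(low, low, gamma_criteria(3, 3, 10, normalization = 1)),
                 "threshold")
  expect_identical(g0$n_evaluated, 0L)
  expect_true(is.na(g0$pass_rate))
  far <- dose_plane(matrix(1, 5, 5), 1000, 1000, 1, 5)
  expect_error(gamma_2d(uniform_plane(1), far, crit33), "overlap")
})

test_that("2-mm shifted Gaussian bump passes 3%/3 mm with gamma <= 2/3", {
  xs <- seq(-40, 40, by = 1)
  bump <- function(cx) outer(xs, xs, function(y, x)
    exp(-((x - cx)^2 + y^2) / (2 * 100)))
  r <- dose_plane(bump(0), -40, -40, 1, 5)
  e <- dose_plane(bump(2), -40, -40, 1, 5)
  g <- gamma_2d(r, e, crit33)
  expect_identical(g$pass_rate, 100)
  expect_lte(max(g$gamma_map, na.rm = TRUE), 2 / 3 + 0.02)
})

test_that("fast gamma agrees with the brute-force oracle", {
  for (s in 1:4) {
    set.seed(s)
    r <- random_smooth_plane(sample(20:30, 1))
    e <- perturbed_partner(r)
    gf <- gamma_2d(r, e, crit33)
    gb <- gamma_2d_bruteforce(r, e, crit33)
    expect_lt(max(abs(gf$gamma_map - gb$gamma_map), na.rm = TRUE), 0.02)
  }
  big <- dose_plane(matrix(1, 201, 201), 0, 0, 1, 5)
  expect_error(gamma_2d_bruteforce(big, big, crit33), "200")
})

test_that("loosening criteria never lowers the pass rate", {
  set.seed(7)
  for (s in 1:5) {
    r <- random_smooth_plane(20)
    e <- perturbed_partner(r)
    p_tight <- gamma_2d(r, e, gamma_criteria(2, 2, 10))$pass_rate
    p_mid <- gamma_2d(r, e, gamma_criteria(3, 2, 10))$pass_rate
    p_loose <- gamma_2d(r, e, gamma_criteria(3, 3, 10))$pass_rate
    expect_gte(p_mid, p_tight)
    expect_gte(p_loose, p_mid)
  }
})

test_that("gamma_2p5d recovers injected depth offsets on a distal gradient", {
  lib <- test_library()
  uf <- make_uniform_field(lib, 16, 4, field_size_mm = 50, spot_pitch_mm = 5)
  grid <- list(origin = c(-20, -20), spacing = 2, shape = c(21, 21))
  src <- function(d) compute_dose_plane(uf$field, lib, NULL, d, grid)
  nominal <- 16.2                      # on the distal falloff
  for (k in c(-1L, 0L, 1L)) {
    meas <- src(nominal + k / 10)
    meas$depth <- nominal
    res <- gamma_2p5d(meas, src, nominal, crit33, search_mm = 3, step_mm = 1)
    expect_identical(res$best_offset_mm, as.numeric(k))
    expect_identical(res$best_pass_rate, 100)
    if (k != 0L) {
      nom_rate <- res$table$pass_rate[res$table$offset_mm == 0]
      expect_lt(nom_rate, 100)
    }
  }
  # degenerate search range = plain 2D at nominal
  meas <- src(nominal)
  res0 <- gamma_2p5d(meas, src, nominal, crit33, search_mm = 0)
  expect_identical(nrow(res0$table), 1L)
  expect_identical(res0$best_pass_rate, gamma_2d(meas, src(nominal), crit33)$pass_rate)
})

test_that("gamma_3d: depth-slice shift absorbed, superset of 2D", {
  set.seed(11)
  base <- lapply(seq(5, 5.8, by = 0.2), function(d) {
    p <- random_smooth_plane(15); p$depth <- d; p
  })
  # identical stacks
  expect_identical(gamma_3d(base, base, crit33)$pass_rate, 100)
  # one-slice (2 mm) shift: depth search absorbs it (gamma = 2/3 <= 1)
  shifted <- base
  for (i in seq_along(shifted)) shifted[[i]]$depth <- base[[i]]$depth + 0.2
  g <- gamma_3d(base, shifted, crit33)
  expect_identical(g$pass_rate, 100)
  # search-space inclusion: each slice's 3D gamma never exceeds the 2D
  # gamma of that slice against its own-depth partner, so the 3D pass rate
  # dominates the pooled per-slice 2D rate
  for (s in 1:5) {
    set.seed(s + 100)
    ref <- lapply(seq(5, 5.4, by = 0.2), function(d) {
      p <- random_smooth_plane(12); p$depth <- d; p
    })
    ev <- lapply(ref, perturbed_partner)
    crit_fix <- gamma_criteria(3, 3, 10, normalization = max(ref[[2]]$values))
    g3 <- gamma_3d(ref, ev, crit_fix)
    all_g2 <- numeric(0)
    for (k in seq_along(ref)) {
      g2k <- gamma_2d(ref[[k]], ev[[k]], crit_fix)
      expect_true(all(g3$gamma_map[[k]] <= g2k$gamma_map + 1e-9, na.rm = TRUE))
      all_g2 <- c(all_g2, g2k$gamma_map[!is.na(g2k$gamma_map)])
    }
    expect_gte(g3$pass_rate + 1e-9, 100 * mean(all_g2 <= 1 + 1e-9))
  }
  expect_message(g1 <- gamma_3d(base[1], base[1], crit33), "single-plane")
  expect_identical(g1$pass_rate, 100)
})

test_that("qa_disposition implements the action-level cascade", {
  expect_identical(qa_disposition(95, 99)$status, "pass")
  expect_identical(qa_disposition(95, 99)$route, "2%/2mm")
  d2 <- qa_disposition(85, 92)
  expect_identical(d2$status, "pass")
  expect_match(d2$route, "3%/3mm")
  # the clinical worked example: 80.4% at nominal, 92.1% at the best depth
  d3 <- qa_disposition(70, 80.4, 92.1)
  expect_identical(d3$status, "pass")
  expect_match(d3$route, "2.5D")
  expect_identical(qa_disposition(70, 80, 85)$status, "fail")
  d4 <- qa_disposition(70, 80)
  expect_identical(d4$status, "review")
  expect_true(d4$action_needed)
  expect_error(qa_disposition(110, 50), "rates")
})
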
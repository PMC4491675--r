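make_records <- function(field, jitter, offsets = NULL)
  simulate_log(field, jitter, spot_offsets = offsets)

test_that("spot-log CSV round-trips and rejects malformed rows", {
  lib <- test_library()
  f <- make_uniform_field(lib, 15, 2, field_size_mm = 40, spot_pitch_mm = 10)$field
  recs <- make_records(f, jitter_model(random_sd = 0.2, n_fractions = 4L, seed = 3))
  tmp <- tempfile(fileext = ".csv")
  write_spot_log(recs, tmp)
  back <- parse_spot_log(tmp)
  expect_identical(back, recs)                   # exact round trip
  # header-only file -> empty record set
  writeLines(paste(protonQA:::.SPOT_LOG_HEADER, collapse = ","), tmp)
  expect_identical(nrow(parse_spot_log(tmp)), 0L)
  # malformed row named by line number
  writeLines(c(paste(protonQA:::.SPOT_LOG_HEADER, collapse = ","),
               "1,0,0,0,0,0,0,1,1",
               "1,0,1,0,abc,0,0,1,1"), tmp)
  expect_error(parse_spot_log(tmp), "line 3")
  writeLines("a,b,c", tmp)
  expect_error(parse_spot_log(tmp), "schema")
})

test_that("deviation_stats: exact shifts and shift equivariance", {
  lib <- test_library()
  f <- make_uniform_field(lib, 12, 2, field_size_mm = 30, spot_pitch_mm = 10)$field
  # recorded == planned
  recs0 <- make_records(f, jitter_model(random_sd = 0, mu_sd = 0, n_fractions = 3L))
  st0 <- deviation_stats(recs0)
  expect_identical(unname(st0$overall["dx", ]), c(0, 0, 0))
  expect_identical(unname(st0$overall["dy", ]), c(0, 0, 0))
  # constant +1 mm in x
  recs1 <- recs0; recs1$recorded_x <- recs1$recorded_x + 1
  st1 <- deviation_stats(recs1)
  expect_identical(unname(st1$overall["dx", "mean"]), 1)
  expect_identical(unname(st1$overall["dx", "sd"]), 0)
  # shift equivariance on jittered records
  recs <- make_records(f, jitter_model(random_sd = 0.2, n_fractions = 5L, seed = 9))
  st <- deviation_stats(recs)
  recs_sh <- recs
  recs_sh$recorded_x <- recs_sh$recorded_x + 0.7
  recs_sh$recorded_y <- recs_sh$recorded_y - 0.3
  st_sh <- deviation_stats(recs_sh)
  expect_equal(st_sh$overall["dx", "mean"], st$overall["dx", "mean"] + 0.7)
  expect_equal(st_sh$overall["dy", "mean"], st$overall["dy", "mean"] - 0.3)
  expect_equal(st_sh$overall[, "sd"], st$overall[, "sd"])
  # histograms count every record
  expect_identical(sum(st$hist_dx$count), st$n_records)
  expect_identical(sum(st$hist_dy$count), st$n_records)
  expect_error(deviation_stats(recs[0, ]), "at least one")
})

test_that("cross-fraction reproducibility estimate is calibrated", {
  lib <- test_library()
  f <- make_uniform_field(lib, 15, 3, field_size_mm = 60, spot_pitch_mm = 6)$field
  sigma <- 0.2
  nf <- 33L
  recs <- make_records(f, jitter_model(random_sd = sigma, n_fractions = nf,
                                       seed = 12345))
  st <- deviation_stats(recs)
  dof <- st$reproducibility$dof
  # exact chi-square 99% interval for the pooled SD
  lo <- sigma * sqrt(stats::qchisq(0.005, dof) / dof)
  hi <- sigma * sqrt(stats::qchisq(0.995, dof) / dof)
  expect_gte(st$reproducibility$pooled_sd_x, lo)
  expect_lte(st$reproducibility$pooled_sd_x, hi)
  expect_gte(st$reproducibility$pooled_sd_y, lo)
  expect_lte(st$reproducibility$pooled_sd_y, hi)
})

test_that("multi-burst rows are MU-weighted aggregated", {
  base <- data.frame(fraction = 1L, layer = 0L, spot = 0L,
                     planned_x = 0, planned_y = 0,
                     recorded_x = c(1, 3), recorded_y = 0,
                     planned_mu = 2, recorded_mu = c(1, 3))
  st <- deviation_stats(base)
  expect_identical(st$n_records, 1L)
  # MU-weighted position: (1*1 + 3*3)/4 = 2.5
  expect_identical(unname(st$overall["dx", "mean"]), 2.5)
})

test_that("reconstruct_field_from_log: identity, locality, MU linearity", {
  lib <- test_library()
  uf <- make_uniform_field(lib, 15, 2, field_size_mm = 30, spot_pitch_mm = 10)
  f <- uf$field
  recs0 <- make_records(f, jitter_model(random_sd = 0, mu_sd = 0, n_fractions = 2L))
  r0 <- reconstruct_field_from_log(recs0, 1L, f)
  expect_identical(r0$spots$x, f$spots$x)
  expect_identical(r0$spots$mu, f$spots$mu)
  # bit-identical planned dose from a zero-deviation log
  grid <- list(origin = c(-25, -25), spacing = 2.5, shape = c(21, 21))
  expect_identical(compute_dose_plane(r0, lib, NULL, 10, grid)$values,
                   compute_dose_plane(f, lib, NULL, 10, grid)$values)
  # one spot moved: only that spot differs
  recs1 <- recs0
  recs1$recorded_x[recs1$fraction == 1][3] <- recs1$planned_x[recs1$fraction == 1][3] + 3
  r1 <- reconstruct_field_from_log(recs1, 1L, f)
  expect_identical(sum(r1$spots$x != f$spots$x), 1L)
  # MU-only deviation scales a single-spot plane by the MU ratio
  fs <- single_spot_field(mu = 2)
  rs <- make_records(fs, jitter_model(random_sd = 0, mu_sd = 0, n_fractions = 1L))
  rs$recorded_mu <- 3
  plane_rec <- compute_dose_plane(reconstruct_field_from_log(rs, 1L, fs),
                                  lib, NULL, 8, grid)
  plane_pl <- compute_dose_plane(fs, lib, NULL, 8, grid)
  expect_identical(plane_rec$values, (3 / 2) * plane_pl$values)
  expect_error(reconstruct_field_from_log(recs0, 99L, f), "not present")
})

test_that("planned_vs_delivered_dose on realistic jitter stays within 2%", {
  lib <- sobp_library()
  uf <- make_uniform_field(lib, 15, 4, field_size_mm = 60, spot_pitch_mm = 6)
  recs <- make_records(uf$field, jitter_model(random_sd = 0.2, mu_sd = 0.005,
                                              n_fractions = 1L, seed = 77))
  grid <- list(origin = c(-25, -25), spacing = 2.5, shape = c(21, 21))
  cmp <- planned_vs_delivered_dose(uf$field, recs, 1L, lib, NULL, 13, grid)
  expect_lte(cmp$max_diff_pct, 2)
  expect_identical(cmp$gamma$pass_rate, 100)
})

test_that("pattern_qa_check flags exactly the perturbed spots", {
  lib <- test_library()
  spec <- pattern_spec("square", 10, 100,
                       data.frame(spot = c(5L, 17L), dx_mm = c(1, 0),
                                  dy_mm = c(0, 3)))
  pat <- make_pattern_field(spec, lib)
  # noiseless delivery of the perturbed pattern
  recs <- make_records(pat$field, jitter_model(random_sd = 0, mu_sd = 0,
                                               n_fractions = 1L),
                       offsets = pat$truth)
  chk <- pattern_qa_check(recs, spec, tolerance_mm = 0.5)
  expect_identical(chk$spot[chk$flagged], c(5L, 17L))
  expect_equal(sort(chk$magnitude_mm[chk$flagged]), c(1, 3))
  # with jitter: same flags, magnitudes within the sampling-error bound
  nf <- 10L; sj <- 0.1
  recsj <- make_records(pat$field, jitter_model(random_sd = sj, n_fractions = nf,
                                                seed = 5),
                        offsets = pat$truth)
  chkj <- pattern_qa_check(recsj, spec, tolerance_mm = 0.5)
  expect_identical(chkj$spot[chkj$flagged], c(5L, 17L))
  bound <- 3 * sj / sqrt(nf)
  expect_lt(abs(chkj$magnitude_mm[chkj$spot == 5] - 1), bound)
  expect_lt(abs(chkj$magnitude_mm[chkj$spot == 17] - 3), bound)
  # records not covering the pattern
  expect_error(pattern_qa_check(recs[1:10, ], spec), "pattern defines")
})
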
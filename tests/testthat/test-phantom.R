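test_that("periodic resampling preserves constants, nodes and round-trips", {
  const <- sampled_curve(rep(2.5, 50), 500)
  expect_equal(upsample_curve(const, 777)$values, rep(2.5, 777))
  expect_equal(downsample_curve(const, 13)$values, rep(2.5, 13))

  set.seed(3)
  cur <- sampled_curve(rnorm(50), 500)
  up2 <- upsample_curve(cur, 100)
  expect_equal(up2$values[seq(1, 100, by = 2)], cur$values)  # nodes preserved
  up <- upsample_curve(cur, 10000)
  expect_equal(downsample_curve(up, 50)$values, cur$values, tolerance = 1e-12)
  expect_identical(downsample_curve(up, 10000), up)  # identity at same n

  expect_error(upsample_curve(cur, 20), ">=")
  expect_error(downsample_curve(cur, 7), ">= 8")
  expect_error(downsample_curve(cur, 200), "<=")
})

test_that("upsampling a triangle wave matches the analytic form", {
  n <- 50
  tri <- function(ph) 1 - 2 * abs(ph %% 1 - 0.5)
  cur <- sampled_curve(tri((0:(n - 1)) / n), 800)
  up <- upsample_curve(cur, 10000)
  # breakpoints at phases 0 and 0.5 are grid points of n = 50, so linear
  # interpolation reproduces the analytic triangle within the one-segment
  # linear interpolation bound
  analytic <- tri((0:9999) / 10000)
  expect_lt(max(abs(up$values - analytic)), 1 / n)
  expect_lt(max(abs(up$values - analytic)), 1e-12)
})

test_that("fractional circular shifts delay features by the requested time", {
  cur <- generate_waveform(waveform_params("neonate"), 1000)
  dt <- frame_duration_ms(cur)
  sh <- shift_curve(cur, 17 * dt)  # whole-frame shift is exact
  expect_equal(sh$values, circ_shift(cur$values, 17), tolerance = 1e-12)
  # shifting forth and back is the identity up to interpolation error
  back <- shift_curve(shift_curve(cur, 13.7), -13.7)
  expect_equal(back$values, cur$values, tolerance = 1e-3 * max(cur$values))
})

test_that("phantom pairs encode the construction delay and diversion factor", {
  sp <- phantom_spec(profile = "neonate", vessel_length_mm = 60)
  pair <- build_phantom_pair(sp, 4)
  expect_equal(attr(pair, "construction_delay_ms"), 15)  # 60 mm / 4 m/s
  sp25 <- phantom_spec(profile = "neonate", vessel_length_mm = 25)
  expect_equal(attr(build_phantom_pair(sp25, 10), "construction_delay_ms"),
               2.5)
  # with the phantom filter disabled the peak ratio is exactly 0.6
  raw <- phantom_spec(profile = "neonate", vessel_length_mm = 60,
                      smooth_width_frames = 0)
  praw <- build_phantom_pair(raw, 4)
  expect_equal(max(praw$descending$values) / max(praw$ascending$values),
               0.6, tolerance = 1e-9)
  # circular filtering conserves the mean, so the mean ratio stays 0.6
  expect_equal(mean(pair$descending$values) / mean(pair$ascending$values),
               0.6, tolerance = 1e-9)
  # unphysical delay: 150 mm at 0.3 m/s is 500 ms > neonatal cycle
  expect_error(build_phantom_pair(
    phantom_spec(profile = "neonate", vessel_length_mm = 150), 0.3), "cycle")
})

test_that("descending-only filtering leaves the ascending curve unmodified", {
  sp <- phantom_spec(profile = "adolescent", vessel_length_mm = 60,
                     smooth_both = FALSE)
  pair <- build_phantom_pair(sp, 6)
  base <- upsample_curve(sp$base_curve, sp$upsample_frames)
  expect_equal(pair$ascending$values, base$values)
})

test_that("the resolution experiment has the full grid shape and converges", {
  sp <- phantom_spec(profile = "neonate", vessel_length_mm = 60)
  grid <- run_resolution_experiment(sp)
  expect_identical(dim(grid$errors_pct), c(5L, 41L))
  expect_true(all(is.finite(grid$errors_pct)))
  # high-resolution limit: errors vanish without downsampling
  full <- transit_time(build_phantom_pair(sp, 6), "ttf")
  expect_lt(abs(full$pwv_m_per_s - 6) / 6 * 100, 1)
  # more timeframes, smaller error
  expect_lt(mean(abs(grid$errors_pct[, "f60"])),
            mean(abs(grid$errors_pct[, "f20"])))
  df <- as.data.frame(grid)
  expect_identical(nrow(df), 5L * 41L)
  expect_identical(names(df), c("profile", "vessel_length_mm",
                                "ref_pwv_m_per_s", "n_frames", "error_pct"))
})

test_that("higher reference PWV worsens short-vessel errors at coarse resolution", {
  sp <- phantom_spec(profile = "neonate", vessel_length_mm = 25)
  grid <- run_resolution_experiment(sp)
  coarse <- grid$errors_pct[, grid$frames_grid <= 40, drop = FALSE]
  worst <- apply(abs(coarse), 1, max)  # per reference PWV (increasing)
  frac_nondec <- mean(diff(worst) >= 0)
  expect_gte(frac_nondec, 0.8)
})

test_that("the required-frames cut-off follows its definition", {
  fake <- function(err_mat, frames) {
    structure(list(errors_pct = err_mat, frames_grid = frames,
                   ref_pwv_m_per_s = seq_len(nrow(err_mat)),
                   vessel_length_mm = 60, profile = "neonate",
                   tolerance_pct = 10),
              class = "error_grid")
  }
  frames <- 20:40
  all_good <- fake(matrix(1, 3, 21), frames)
  expect_identical(find_required_frames(all_good, 10)$cutoff_frames, 20L)

  breach <- matrix(1, 3, 21)
  breach[2, frames == 30] <- 15   # one cell at N = 30 breaches
  expect_identical(find_required_frames(fake(breach, frames), 10)$cutoff_frames,
                   31L)
  # zero tolerance can never be met by floating-point errors
  real <- run_resolution_experiment(
    phantom_spec(profile = "neonate", vessel_length_mm = 60,
                 frames_grid = seq(20, 60, by = 8)))
  res0 <- find_required_frames(real, 0)
  expect_false(res0$found)
  expect_true(is.na(res0$cutoff_frames))
  # a missing cell counts as a failure
  holed <- breach; holed[1, 21] <- NA
  expect_false(find_required_frames(fake(holed, frames), 10)$found)
})
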
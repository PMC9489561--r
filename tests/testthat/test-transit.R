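test_that("all three estimators recover whole-frame shifts and match the correlation oracle", {
  set.seed(10)
  n <- 400
  for (r in 1:10) {
    p <- random_params()
    asc <- generate_waveform(p, n)
    m <- sample(1:40, 1)
    desc <- asc
    desc$values <- circ_shift(asc$values, m)
    pair <- curve_pair(asc, desc, 60)
    dt <- frame_duration_ms(asc)
    lag <- xcorr_delay_frames(asc$values, desc$values)
    expect_identical(lag, m)
    for (meth in c("ttf", "max_upslope", "ttp")) {
      est <- transit_time(pair, meth)
      expect_lt(abs(est$delta_t_ms - lag * dt), dt)
    }
  }
})

test_that("an identical pair yields delta-t 0 and an undefined, flagged PWV", {
  asc <- generate_waveform(waveform_params("adolescent"), 300)
  pair <- curve_pair(asc, asc, 100)
  for (meth in c("ttf", "max_upslope", "ttp")) {
    est <- transit_time(pair, meth)
    expect_identical(est$delta_t_ms, 0)
    expect_false(est$pwv_defined)
    expect_true(is.na(est$pwv_m_per_s))
  }
})

test_that("transit times are invariant under common positive rescaling", {
  set.seed(20)
  for (r in 1:5) {
    p <- random_params()
    asc <- generate_waveform(p, 350)
    desc <- shift_curve(asc, 25)
    desc$values <- 0.6 * desc$values
    pair <- curve_pair(asc, desc, 80)
    for (lambda in c(0.01, 3.7, 1000)) {
      scaled <- pair
      scaled$ascending$values <- lambda * pair$ascending$values
      scaled$descending$values <- lambda * pair$descending$values
      for (meth in c("ttf", "max_upslope", "ttp")) {
        expect_equal(transit_time(scaled, meth)$delta_t_ms,
                     transit_time(pair, meth)$delta_t_ms,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("baseline correction only applies to TTF and modes agree on baseline-flat curves", {
  asc <- generate_waveform(waveform_params("neonate"), 500)
  desc <- shift_curve(asc, 12)
  desc$values <- 0.6 * desc$values
  pair <- curve_pair(asc, desc, 60)
  # non-TTF methods force baseline to none
  est <- transit_time(pair, "max_upslope", baseline_spec("automatic"))
  expect_identical(est$baseline_mode, "none")
  # flat in both windows: automatic and manual give identical delta-t
  auto <- transit_time(pair, "ttf", baseline_spec("automatic"))
  man <- transit_time(pair, "ttf", baseline_spec("manual", c(0.90, 1.00)))
  expect_equal(auto$delta_t_ms, man$delta_t_ms,
               tolerance = 1e-3 * frame_duration_ms(asc))
})

test_that("a flat curve raises an analysis error for slope-based landmarks", {
  flat <- sampled_curve(rep(1, 50), 600)
  pair <- curve_pair(flat, flat, 60)
  expect_error(transit_time(pair, "ttf", baseline_spec("none")), "upslope")
  expect_error(transit_time(pair, "max_upslope"), "upslope")
})

test_that("negative transit times are reported as-is and unwrap adds one cycle", {
  asc <- generate_waveform(waveform_params("adolescent"), 400)
  # advance instead of delay: landmark moves earlier
  desc <- shift_curve(asc, -40)
  pair <- curve_pair(asc, desc, 100)
  est <- transit_time(pair, "ttp")
  expect_lt(est$delta_t_ms, 0)
  expect_lt(est$pwv_m_per_s, 0)
  # a delta-t below minus half a cycle unwraps on request: build a pair
  # whose ascending peak sits late in the cycle so the descending landmark
  # can precede it by more than half a cycle
  late <- generate_waveform(
    waveform_params("adolescent", systolic_fraction = 0.8,
                    onset_phase = 0.35, dicrotic_amplitude_fraction = 0), 400)
  cyc <- late$cycle_duration_ms
  desc2 <- shift_curve(late, -0.55 * cyc)
  pair2 <- curve_pair(late, desc2, 100)
  raw <- transit_time(pair2, "ttp")
  expect_lt(raw$delta_t_ms, -cyc / 2)
  unw <- transit_time(pair2, "ttp", unwrap = TRUE)
  expect_equal(unw$delta_t_ms - raw$delta_t_ms, cyc)
})

test_that("PWV arithmetic follows delta-d / delta-t in mm and ms", {
  expect_identical(compute_pwv(60, 15), 4)
  expect_identical(compute_pwv(25, 12.5), 2)
  expect_identical(compute_pwv(150, -50), -3)
  expect_error(compute_pwv(60, 0), "undefined")
  expect_error(compute_pwv(-5, 10), "delta_d_mm")
})

test_that("temporal resolution reproduces scanner arithmetic and monotonicity", {
  expect_equal(temporal_resolution_ms(138, 44), 60000 / (138 * 44))
  expect_identical(temporal_resolution_ms(138, 44, rounded = TRUE), 10)
  expect_identical(temporal_resolution_ms(138, 41, rounded = TRUE), 11)
  expect_identical(temporal_resolution_ms(75, 39, rounded = TRUE), 21)
  expect_identical(temporal_resolution_ms(60, 50), 20)
  # strictly decreasing in both arguments
  hr <- seq(40, 160, by = 10)
  expect_true(all(diff(temporal_resolution_ms(hr, 35)) < 0))
  fr <- 20:60
  expect_true(all(diff(temporal_resolution_ms(75, fr)) < 0))
  expect_error(temporal_resolution_ms(0, 40), "> 0")
})
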
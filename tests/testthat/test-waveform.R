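test_that("generated waveforms honour the heart rate, peak and determinism contracts", {
  p <- waveform_params("neonate", noise_sd = 0)
  cur <- generate_waveform(p, 10000)
  expect_equal(cur$cycle_duration_ms, 60000 / 138)
  expect_equal(cur$n_frames, 10000)
  # peak equals the amplitude parameter up to one sample's interpolation error
  expect_equal(max(cur$values), p$peak_amplitude, tolerance = 1e-6)
  # peak sits inside the systolic window [0, systolic_fraction)
  peak_phase <- (which.max(cur$values) - 1) / cur$n_frames
  expect_lt(peak_phase, p$systolic_fraction)

  pn <- waveform_params("neonate", noise_sd = 2, seed = 11L)
  expect_identical(generate_waveform(pn, 500)$values,
                   generate_waveform(pn, 500)$values)
  pn2 <- waveform_params("neonate", noise_sd = 2, seed = 12L)
  expect_false(identical(generate_waveform(pn, 500)$values,
                         generate_waveform(pn2, 500)$values))
})

test_that("waveform is periodic and near-baseline in diastole", {
  for (prof in c("neonate", "adolescent")) {
    p <- waveform_params(prof, baseline_offset = 3)
    cur <- generate_waveform(p, 5000)
    # continuity across the cycle wrap
    expect_lt(abs(cur$values[1] - cur$values[5000]),
              p$peak_amplitude * 0.01)
    # late diastole sits at the baseline offset
    late <- cur$values[round(0.97 * 5000):5000]
    expect_lt(max(abs(late - 3)), p$peak_amplitude * 1e-3)
  }
})

test_that("retrograde fraction produces a contiguous negative segment after systole", {
  p <- waveform_params("neonate", retrograde_fraction = 0.3,
                       dicrotic_amplitude_fraction = 0)
  cur <- generate_waveform(p, 2000)
  neg <- which(cur$values < -1e-9)
  expect_gt(length(neg), 0)
  expect_true(all(diff(neg) == 1))  # contiguous lobe
  # located immediately after systole (onset + systolic fraction)
  sys_end <- (p$onset_phase + p$systolic_fraction) * 2000
  expect_gt(min(neg), sys_end - 2)
})

test_that("waveform parameter validation rejects unphysical settings", {
  expect_error(waveform_params("neonate", systolic_fraction = 1.2), "systolic_fraction")
  expect_error(waveform_params("neonate", heart_rate_bpm = -10), "heart_rate_bpm")
  expect_error(waveform_params("neonate", peak_amplitude = 0), "peak_amplitude")
  expect_error(waveform_params("neonate", noise_sd = -1), "noise_sd")
  expect_error(waveform_params("neonate", onset_phase = 0.3), "onset_phase")
  expect_error(generate_waveform(waveform_params("neonate"), 5), ">= 8")
})

test_that("cohorts carry the construction delay delta_d / PWV and reproduce under a seed", {
  coh <- generate_cohort(5, "neonate", c(4, 4), delta_d_mm = 60,
                         acquisition_frames = 44, seed = 3)
  expect_length(coh, 5)
  for (s in coh) {
    expect_equal(s$delay_ms, 15)          # 60 mm / 4 m/s
    expect_equal(s$true_pwv_m_per_s, 4)
    expect_equal(s$pair$delta_d_mm, 60)
  }
  c1 <- generate_cohort(8, "adolescent", c(2, 10), seed = 5)
  c2 <- generate_cohort(8, "adolescent", c(2, 10), seed = 5)
  c3 <- generate_cohort(8, "adolescent", c(2, 10), seed = 6)
  expect_identical(sapply(c1, `[[`, "true_pwv_m_per_s"),
                   sapply(c2, `[[`, "true_pwv_m_per_s"))
  expect_false(identical(sapply(c1, `[[`, "true_pwv_m_per_s"),
                         sapply(c3, `[[`, "true_pwv_m_per_s")))
})

test_that("descending/ascending peak ratio equals the diversion factor without noise", {
  coh <- generate_cohort(3, "neonate", c(3, 7), acquisition_frames = 2000,
                         noise_sd = 0, seed = 2)
  for (s in coh) {
    ratio <- max(s$pair$descending$values) / max(s$pair$ascending$values)
    # both curves sample the analytic waveform on shifted phase grids, so
    # the sampled maxima carry a discretisation error quadratic in 1/n
    expect_equal(ratio, 0.6, tolerance = 1e-5)
  }
})

test_that("cohort ground truth is recoverable by TTF at high resolution", {
  coh <- generate_cohort(6, "neonate", c(2, 10), delta_d_mm = 68,
                         acquisition_frames = 1000, noise_sd = 0, seed = 9)
  for (s in coh) {
    est <- transit_time(s$pair, "ttf")
    expect_lt(abs(est$pwv_m_per_s - s$true_pwv_m_per_s) / s$true_pwv_m_per_s,
              0.02)
    # independent cross-check: cross-correlation delay oracle
    lag <- xcorr_delay_frames(s$pair$ascending$values,
                              s$pair$descending$values)
    dt <- frame_duration_ms(s$pair$ascending)
    expect_lt(abs(lag * dt - s$delay_ms), dt)
  }
})

test_that("an unphysical cohort configuration (delay >= cycle) is rejected", {
  # 200 mm at 0.4 m/s -> 500 ms delay > 434.8 ms neonatal cycle
  expect_error(generate_cohort(2, "neonate", c(0.4, 1), delta_d_mm = 200),
               "cycle")
})
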
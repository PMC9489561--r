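#' Parametric aortic waveform parameters
#'
#' Defines a synthetic single-cycle aortic flow or velocity waveform:
#' a half-sine systolic ejection pulse starting `onset_phase` into the
#' cycle (the isovolumetric-contraction delay between the ECG trigger and
#' aortic ejection), an optional Gaussian dicrotic bump just after
#' end-systole (aortic valve closure), an optional negative
#' early-diastolic lobe (retrograde flow, e.g. valve insufficiency), a
#' flat diastolic tail at `baseline_offset`, and optional additive
#' Gaussian measurement noise.  The family reproduces the qualitative
#' features of measured aortic curves: a single dominant systolic peak, a
#' near-zero diastole, and a relatively shorter diastole in neonates due
#' to their higher heart rate.
#'
#' Profile defaults (overridable individually):
#' \tabular{lll}{
#'   \tab neonate \tab adolescent \cr
#'   heart rate (bpm) \tab 138 \tab 75 \cr
#'   systolic fraction \tab 0.45 \tab 0.33 \cr
#'   peak flow (ml/s) \tab 35 \tab 350 \cr
#'   peak velocity (cm/s) \tab 95 \tab 110 \cr
#' }
#'
#' @param profile `"neonate"` or `"adolescent"`; sets defaults below.
#' @param heart_rate_bpm heart rate in beats/min (> 0).
#' @param systolic_fraction fraction of the cycle occupied by the systolic
#'   ejection pulse, in (0, 1).
#' @param onset_phase cycle fraction between the ECG trigger (phase 0) and
#'   the start of ejection, in `[0, systolic_fraction / 2)` so the peak
#'   stays inside the systolic window (default 0.10, a typical
#'   isovolumetric-contraction delay).
#' @param peak_amplitude peak flow (ml/s) or velocity (cm/s), > 0.
#' @param dicrotic_amplitude_fraction relative height of the secondary
#'   post-systolic wave (>= 0).
#' @param retrograde_fraction relative amplitude of the negative
#'   early-diastolic lobe (>= 0; default 0 = none).
#' @param baseline_offset constant additive offset.
#' @param noise_sd SD of additive zero-mean Gaussian noise (>= 0).
#' @param kind `"flow"` or `"velocity"`.
#' @param seed integer seed used when `noise_sd > 0`.
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(profile = c("neonate", "adolescent"),
                            heart_rate_bpm = NULL,
                            systolic_fraction = NULL,
                            onset_phase = 0.10,
                            peak_amplitude = NULL,
                            dicrotic_amplitude_fraction = 0.12,
                            retrograde_fraction = 0,
                            baseline_offset = 0,
                            noise_sd = 0,
                            kind = c("flow", "velocity"),
                            seed = 1L) {
  profile <- match.arg(profile)
  kind <- match.arg(kind)
  defaults <- switch(profile,
    neonate = list(hr = 138, sf = 0.45, peak_flow = 35, peak_vel = 95),
    adolescent = list(hr = 75, sf = 0.33, peak_flow = 350, peak_vel = 110))
  if (is.null(heart_rate_bpm)) heart_rate_bpm <- defaults$hr
  if (is.null(systolic_fraction)) systolic_fraction <- defaults$sf
  if (is.null(peak_amplitude)) {
    peak_amplitude <- if (kind == "flow") defaults$peak_flow else defaults$peak_vel
  }
  check_scalar(heart_rate_bpm, "heart_rate_bpm", positive = TRUE)
  check_scalar(systolic_fraction, "systolic_fraction")
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop_param("`systolic_fraction` must be in (0, 1)")
  }
  check_scalar(onset_phase, "onset_phase", nonnegative = TRUE)
  if (onset_phase >= systolic_fraction / 2) {
    stop_param("`onset_phase` must be < systolic_fraction / 2 so the peak ",
               "stays inside the systolic window")
  }
  check_scalar(peak_amplitude, "peak_amplitude", positive = TRUE)
  check_scalar(dicrotic_amplitude_fraction, "dicrotic_amplitude_fraction",
               nonnegative = TRUE)
  check_scalar(retrograde_fraction, "retrograde_fraction", nonnegative = TRUE)
  check_scalar(baseline_offset, "baseline_offset")
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  structure(
    list(profile = profile,
         heart_rate_bpm = as.numeric(heart_rate_bpm),
         systolic_fraction = as.numeric(systolic_fraction),
         onset_phase = as.numeric(onset_phase),
         peak_amplitude = as.numeric(peak_amplitude),
         dicrotic_amplitude_fraction = as.numeric(dicrotic_amplitude_fraction),
         retrograde_fraction = as.numeric(retrograde_fraction),
         baseline_offset = as.numeric(baseline_offset),
         noise_sd = as.numeric(noise_sd),
         kind = kind,
         seed = as.integer(seed)),
    class = "waveform_params"
  )
}

# Noise-free waveform value at arbitrary cycle phases (vectorised).
# Keeping the analytic form separate from sampling lets cohorts apply
# exact fractional delays without interpolation error.
wave_value <- function(params, phase) {
  # phase relative to ejection onset (isovolumetric delay after trigger)
  ph <- (phase - params$onset_phase) - floor(phase - params$onset_phase)
  sf <- params$systolic_fraction
  A <- params$peak_amplitude
  v <- ifelse(ph < sf, A * sin(pi * ph / sf), 0)
  if (params$retrograde_fraction > 0) {
    rw <- min(0.08, (1 - sf) / 3)           # lobe width as cycle fraction
    in_lobe <- ph >= sf & ph < sf + rw
    v <- v - ifelse(in_lobe,
                    params$retrograde_fraction * A *
                      sin(pi * (ph - sf) / rw), 0)
  }
  if (params$dicrotic_amplitude_fraction > 0) {
    # dicrotic wave just after aortic valve closure (end-systole)
    center <- sf + 0.04 * (1 - sf)
    width <- 0.02
    v <- v + params$dicrotic_amplitude_fraction * A *
      exp(-0.5 * ((ph - center) / width)^2)
  }
  v + params$baseline_offset
}

#' Generate a synthetic aortic waveform
#'
#' Samples the parametric waveform of [waveform_params()] at `n_frames`
#' uniform phases over one cardiac cycle.  Deterministic for a fixed seed;
#' the cycle duration is `60000 / heart_rate_bpm` ms.
#'
#' @param params a [waveform_params()].
#' @param n_frames timeframes per cardiac cycle (>= 8).
#' @return A [sampled_curve()].
#' @examples
#' cur <- generate_waveform(waveform_params("neonate"), 44)
#' cur$cycle_duration_ms   # 60000 / 138
#' @export
generate_waveform <- function(params, n_frames) {
  stopifnot(inherits(params, "waveform_params"))
  n_frames <- as.integer(check_scalar(n_frames, "n_frames", positive = TRUE))
  if (n_frames < 8L) stop_param("n_frames must be >= 8")
  vals <- wave_value(params, (0:(n_frames - 1L)) / n_frames)
  if (params$noise_sd > 0) {
    vals <- vals + with_seed(params$seed,
                             stats::rnorm(n_frames, 0, params$noise_sd))
  }
  sampled_curve(vals, 60000 / params$heart_rate_bpm, params$kind,
                paste0(params$profile, " synthetic"))
}

#' Generate a synthetic subject cohort with known ground-truth PWV
#'
#' For each subject a true PWV is drawn uniformly from `pwv_range_m_per_s`
#' (reproducibly, given `seed`).  The descending curve is the analytic
#' ascending waveform circularly delayed by
#' `delta_d_mm / true_pwv` ms, scaled by the blood-diversion factor
#' `desc_scale` (default 0.6, mimicking outflow to the arch branches);
#' both curves are then sampled at `acquisition_frames` timeframes and
#' perturbed by independent Gaussian noise.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param profile `"neonate"` or `"adolescent"`.
#' @param pwv_range_m_per_s length-2 interval within (0, 20]; equal
#'   endpoints fix the PWV.
#' @param delta_d_mm traveling distance between flow planes in mm.
#' @param acquisition_frames timeframes per cycle of the simulated
#'   acquisition (>= 8).
#' @param noise_sd SD of the additive measurement noise (same units as the
#'   curve; 0 = noise-free).
#' @param seed integer seed driving all random draws.
#' @param desc_scale descending/ascending amplitude factor in (0, 1].
#' @param params optional [waveform_params()] overriding the profile
#'   defaults (its `noise_sd`/`seed` are ignored; cohort-level values rule).
#' @return A list of `synthetic_subject` objects, each with elements
#'   `subject_id`, `pair` (a [curve_pair()]), `true_pwv_m_per_s`,
#'   `delay_ms` (construction delay `delta_d_mm / true_pwv`) and `params`.
#' @examples
#' coh <- generate_cohort(5, "neonate", c(4, 4), delta_d_mm = 60,
#'                        acquisition_frames = 44, seed = 1)
#' coh[[1]]$delay_ms   # 60 mm / 4 m/s = 15 ms
#' @export
generate_cohort <- function(n_subjects, profile = c("neonate", "adolescent"),
                            pwv_range_m_per_s = c(2, 10),
                            delta_d_mm = 68,
                            acquisition_frames = 44,
                            noise_sd = 0,
                            seed = 1L,
                            desc_scale = 0.6,
                            params = NULL) {
  profile <- match.arg(profile)
  n_subjects <- as.integer(check_scalar(n_subjects, "n_subjects", positive = TRUE))
  if (length(pwv_range_m_per_s) != 2L || !all(is.finite(pwv_range_m_per_s)) ||
      pwv_range_m_per_s[1L] > pwv_range_m_per_s[2L] ||
      pwv_range_m_per_s[1L] <= 0 || pwv_range_m_per_s[2L] > 20) {
    stop_param("`pwv_range_m_per_s` must be an interval within (0, 20]")
  }
  check_scalar(delta_d_mm, "delta_d_mm", positive = TRUE)
  acquisition_frames <- as.integer(check_scalar(acquisition_frames,
                                                "acquisition_frames",
                                                positive = TRUE))
  if (acquisition_frames < 8L) stop_param("acquisition_frames must be >= 8")
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  check_scalar(desc_scale, "desc_scale", positive = TRUE)
  if (desc_scale > 1) stop_param("`desc_scale` must be in (0, 1]")
  if (is.null(params)) params <- waveform_params(profile)
  stopifnot(inherits(params, "waveform_params"))
  cycle_ms <- 60000 / params$heart_rate_bpm
  max_delay <- delta_d_mm / pwv_range_m_per_s[1L]
  if (max_delay >= cycle_ms) {
    stop_param("construction delay (", round(max_delay, 2),
               " ms) reaches the cycle duration (", round(cycle_ms, 2),
               " ms): unphysical configuration")
  }
  phases <- (0:(acquisition_frames - 1L)) / acquisition_frames
  with_seed(seed, {
    truth <- stats::runif(n_subjects, pwv_range_m_per_s[1L],
                          pwv_range_m_per_s[2L])
    lapply(seq_len(n_subjects), function(i) {
      delay <- delta_d_mm / truth[i]
      asc <- wave_value(params, phases)
      desc <- desc_scale * wave_value(params, phases - delay / cycle_ms)
      if (noise_sd > 0) {
        asc <- asc + stats::rnorm(acquisition_frames, 0, noise_sd)
        desc <- desc + stats::rnorm(acquisition_frames, 0, noise_sd)
      }
      lab <- sprintf("%s subject %02d", profile, i)
      pair <- curve_pair(
        sampled_curve(asc, cycle_ms, params$kind, paste(lab, "asc")),
        sampled_curve(desc, cycle_ms, params$kind, paste(lab, "desc")),
        delta_d_mm)
      structure(list(subject_id = sprintf("S%03d", i),
                     pair = pair,
                     true_pwv_m_per_s = truth[i],
                     delay_ms = delay,
                     params = params),
                class = "synthetic_subject")
    })
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s: true PWV %.3f m/s, delay %.3f ms, %d frames\n",
              x$subject_id, x$true_pwv_m_per_s, x$delay_ms,
              x$pair$ascending$n_frames))
  invisible(x)
}
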
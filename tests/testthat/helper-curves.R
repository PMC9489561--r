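# shared fixtures and independent oracles

# Circular cross-correlation delay oracle: the integer lag k maximising
# sum_i desc[i] * asc[i - k].  Independent of the landmark-based estimators
# it cross-checks.
xcorr_delay_frames <- function(asc_values, desc_values) {
  n <- length(asc_values)
  idx <- 0:(n - 1L)
  cc <- vapply(idx, function(k) {
    sum(desc_values * asc_values[(idx - k) %% n + 1L])
  }, 0)
  which.max(cc) - 1L
}

# Integer circular shift: out[i] = x[i - m] (delay by m frames).
circ_shift <- function(x, m) {
  n <- length(x)
  x[((0:(n - 1L)) - m) %% n + 1L]
}

# Random but valid waveform parameters for property tests.
random_params <- function(noise_sd = 0) {
  profile <- sample(c("neonate", "adolescent"), 1L)
  waveform_params(
    profile,
    heart_rate_bpm = stats::runif(1, 60, 150),
    systolic_fraction = stats::runif(1, 0.30, 0.50),
    peak_amplitude = stats::runif(1, 5, 400),
    dicrotic_amplitude_fraction = stats::runif(1, 0, 0.2),
    noise_sd = noise_sd)
}

# The four phantom panels of the study design: shortest aortic arch and
# thoracic aorta lengths per age group.
phantom_panels <- function() {
  list(list(profile = "neonate", length_mm = 25),
       list(profile = "neonate", length_mm = 60),
       list(profile = "adolescent", length_mm = 60),
       list(profile = "adolescent", length_mm = 150))
}
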
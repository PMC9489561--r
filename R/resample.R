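# Periodic resampling of sampled curves.  All operations treat the cycle
# as circular: the value between the last and first sample is interpolated
# across the wrap.

# Evaluate the curve at arbitrary cycle phases by periodic linear
# interpolation.  Sample k sits at phase k/n; the segment [(n-1)/n, 1)
# interpolates between the last and the first sample.
resample_phases <- function(curve, phases) {
  n <- curve$n_frames
  x <- (0:n) / n
  y <- c(curve$values, curve$values[1L])
  ph <- phases - floor(phases)
  stats::approx(x, y, xout = ph)$y
}

#' Upsample a curve by periodic linear interpolation
#'
#' Evaluates the curve at uniform phases `k / target_frames`.  When the
#' target is an integer multiple of the source resolution, the original
#' samples are reproduced exactly (interpolation through the nodes).
#'
#' @param curve a [sampled_curve()].
#' @param target_frames number of output timeframes, `>= curve$n_frames`.
#' @return A [sampled_curve()] with `target_frames` timeframes.
#' @export
upsample_curve <- function(curve, target_frames) {
  stopifnot(inherits(curve, "sampled_curve"))
  target_frames <- as.integer(check_scalar(target_frames, "target_frames",
                                           positive = TRUE))
  if (target_frames < curve$n_frames) {
    stop_param("target_frames (", target_frames,
               ") must be >= the curve's n_frames (", curve$n_frames, ")")
  }
  if (target_frames == curve$n_frames) return(curve)
  vals <- resample_phases(curve, (0:(target_frames - 1L)) / target_frames)
  sampled_curve(vals, curve$cycle_duration_ms, curve$kind, curve$label)
}

#' Downsample a curve to mimic image acquisition
#'
#' Point sampling at the acquisition phases `phase_offset + k / n_frames`
#' (periodic linear interpolation), mimicking reconstruction of discrete
#' timeframes.  `mode = "bin"` instead averages the source samples falling
#' into each output timeframe's phase bin.
#'
#' @param curve a [sampled_curve()].
#' @param n_frames target timeframes per cycle, `8 <= n_frames <=
#'   curve$n_frames`.
#' @param phase_offset phase of the first acquired timeframe (default 0).
#' @param mode `"point"` (default) or `"bin"`.
#' @return A [sampled_curve()] with `n_frames` timeframes.
#' @export
downsample_curve <- function(curve, n_frames, phase_offset = 0,
                             mode = c("point", "bin")) {
  stopifnot(inherits(curve, "sampled_curve"))
  mode <- match.arg(mode)
  n_frames <- as.integer(check_scalar(n_frames, "n_frames", positive = TRUE))
  if (n_frames < 8L) stop_param("n_frames must be >= 8")
  if (n_frames > curve$n_frames) {
    stop_param("n_frames (", n_frames, ") must be <= the curve's n_frames (",
               curve$n_frames, "); use upsample_curve() to increase resolution")
  }
  if (mode == "point") {
    vals <- resample_phases(curve, phase_offset + (0:(n_frames - 1L)) / n_frames)
  } else {
    src_phase <- ((0:(curve$n_frames - 1L)) / curve$n_frames - phase_offset) %% 1
    bin <- floor(src_phase * n_frames)
    vals <- as.numeric(tapply(curve$values, factor(bin, levels = 0:(n_frames - 1L)),
                              mean))
    if (anyNA(vals)) stop_param("empty phase bin in bin-averaged downsampling")
  }
  sampled_curve(vals, curve$cycle_duration_ms, curve$kind, curve$label)
}

#' Circularly delay a curve by a time offset
#'
#' Returns the curve delayed by `delay_ms`: a feature at time `t` in the
#' input appears at `t + delay_ms` (modulo the cycle) in the output.
#' Fractional-frame delays use periodic linear interpolation.
#'
#' @param curve a [sampled_curve()].
#' @param delay_ms delay in ms (any sign; applied modulo the cycle).
#' @return The delayed [sampled_curve()].
#' @export
shift_curve <- function(curve, delay_ms) {
  stopifnot(inherits(curve, "sampled_curve"))
  check_scalar(delay_ms, "delay_ms")
  dphase <- delay_ms / curve$cycle_duration_ms
  vals <- resample_phases(curve, (0:(curve$n_frames - 1L)) / curve$n_frames - dphase)
  sampled_curve(vals, curve$cycle_duration_ms, curve$kind, curve$label)
}
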
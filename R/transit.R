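#' Transit-time estimation between ascending and descending curves
#'
#' Estimates the transit time delta-t of the systolic wavefront between the
#' two curves of a [curve_pair()] and derives PWV = delta-d / delta-t.
#' Three landmark algorithms are available:
#' \describe{
#'   \item{`ttf` (time-to-foot)}{the intersection of the tangent through
#'     the point of maximum systolic upslope with the zero baseline,
#'     `t_foot = t_up - y(t_up) / s` where `s` is the maximum slope.  The
#'     only method that refers to the baseline, hence the only one to which
#'     baseline correction applies.}
#'   \item{`max_upslope`}{the time of the maximum discrete derivative on
#'     the systolic upslope.}
#'   \item{`ttp` (time-to-peak)}{the time of the global curve maximum.}
#' }
#'
#' Each curve is processed as: smooth, then (TTF only) baseline-correct,
#' then locate the landmark.  The maximum-upslope search is restricted to
#' the window from cycle start to the global maximum, so a steep diastolic
#' artifact cannot be selected; ties resolve to the earliest frame.  The
#' derivative is a central difference on the smoothed curve (one-sided at
#' the cycle boundary), in units per ms.  Landmark times are continuous ms:
#' the TTF foot has sub-frame precision via the tangent formula.
#'
#' `delta_t_ms = landmark(descending) - landmark(ascending)` and may be
#' negative (curves with no definitive peak can place the descending
#' landmark before the ascending one; negative PWV is reported as-is).
#' With `unwrap = TRUE`, one cycle duration is added when
#' `delta_t < -cycle/2`.
#'
#' @param pair a [curve_pair()].
#' @param method `"ttf"`, `"max_upslope"` or `"ttp"`.
#' @param baseline a [baseline_spec()]; applies to TTF only and is forced
#'   to `"none"` for the other methods.
#' @param smoothing a [smoothing_spec()] applied to both curves.
#' @param unwrap add one cycle to delta-t when it falls below minus half a
#'   cycle (default `FALSE`: report negative delta-t as-is).
#' @return An object of class `transit_estimate` with elements `method`,
#'   `baseline_mode`, `delta_t_ms`, `landmark_asc_ms`, `landmark_desc_ms`,
#'   `pwv_m_per_s` (`NA` when delta-t is exactly zero), `pwv_defined`,
#'   `n_frames`, `cycle_duration_ms`, `delta_d_mm`.
#' @examples
#' p <- waveform_params("neonate")
#' asc <- generate_waveform(p, 1000)
#' desc <- shift_curve(asc, 15)          # 15 ms construction delay
#' desc$values <- 0.6 * desc$values
#' est <- transit_time(curve_pair(asc, desc, 60), "ttf")
#' est$pwv_m_per_s                       # close to 60/15 = 4 m/s
#' @export
transit_time <- function(pair, method = c("ttf", "max_upslope", "ttp"),
                         baseline = baseline_spec("automatic"),
                         smoothing = smoothing_spec(),
                         unwrap = FALSE) {
  stopifnot(inherits(pair, "curve_pair"))
  method <- match.arg(method)
  if (method != "ttf") baseline <- baseline_spec("none")
  la <- curve_landmark(pair$ascending, method, baseline, smoothing)
  ld <- curve_landmark(pair$descending, method, baseline, smoothing)
  cyc <- pair$ascending$cycle_duration_ms
  delta_t <- ld - la
  if (isTRUE(unwrap) && delta_t < -cyc / 2) delta_t <- delta_t + cyc
  defined <- delta_t != 0
  structure(
    list(method = method,
         baseline_mode = baseline$mode,
         delta_t_ms = delta_t,
         landmark_asc_ms = la,
         landmark_desc_ms = ld,
         pwv_m_per_s = if (defined) pair$delta_d_mm / delta_t else NA_real_,
         pwv_defined = defined,
         n_frames = pair$ascending$n_frames,
         cycle_duration_ms = cyc,
         delta_d_mm = pair$delta_d_mm),
    class = "transit_estimate"
  )
}

# Landmark time (continuous ms) of a single curve for one method.
curve_landmark <- function(curve, method, baseline, smoothing) {
  sc <- smooth_curve(curve, smoothing)
  if (method == "ttf") sc <- baseline_correct(sc, baseline)
  y <- sc$values
  n <- length(y)
  dt <- sc$cycle_duration_ms / n
  if (diff(range(y)) <= 1e-12 * max(abs(y), 1)) {
    if (method != "ttp") {
      stop_param("no positive upslope found (flat curve); ", method,
                 " landmark undefined")
    }
  }
  peak <- which.max(y)                      # earliest frame on ties
  if (method == "ttp") return((peak - 1L) * dt)

  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / dt
  d[n] <- (y[n] - y[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * dt)

  iu <- which.max(d[seq_len(peak)])         # systolic upslope only
  s <- d[iu]
  if (s <= 0) {
    stop_param("no positive upslope found (flat or non-rising curve); ",
               method, " landmark undefined")
  }
  t_up <- (iu - 1L) * dt
  if (method == "max_upslope") return(t_up)
  t_up - y[iu] / s                          # tangent foot on zero baseline
}

#' @export
print.transit_estimate <- function(x, ...) {
  cat(sprintf("<transit_estimate> %s (baseline: %s)\n", x$method,
              x$baseline_mode))
  cat(sprintf("  landmarks: asc %.3f ms, desc %.3f ms -> delta-t %.3f ms\n",
              x$landmark_asc_ms, x$landmark_desc_ms, x$delta_t_ms))
  if (x$pwv_defined) {
    cat(sprintf("  PWV = %.1f mm / %.3f ms = %.3f m/s\n",
                x$delta_d_mm, x$delta_t_ms, x$pwv_m_per_s))
  } else {
    cat("  PWV undefined (delta-t = 0)\n")
  }
  invisible(x)
}

#' Pulse wave velocity from distance and transit time
#'
#' `PWV = delta_d / delta_t`; with distance in mm and time in ms the result
#' is directly in m/s.  The sign of the transit time is kept (negative PWV
#' is representable).
#'
#' @param delta_d_mm traveling distance in mm (> 0).
#' @param delta_t_ms transit time in ms; must be nonzero.
#' @return PWV in m/s, signed.
#' @examples
#' compute_pwv(60, 15)    # 4 m/s
#' compute_pwv(150, -50)  # -3 m/s
#' @export
compute_pwv <- function(delta_d_mm, delta_t_ms) {
  check_scalar(delta_d_mm, "delta_d_mm", positive = TRUE)
  check_scalar(delta_t_ms, "delta_t_ms")
  if (delta_t_ms == 0) stop_param("delta_t_ms is zero: PWV undefined")
  delta_d_mm / delta_t_ms
}

#' Temporal resolution of a gated acquisition
#'
#' Temporal resolution in ms is the cardiac cycle duration divided by the
#' number of reconstructed timeframes per cycle:
#' `60000 / (heart_rate_bpm * timeframes)`.
#'
#' @param heart_rate_bpm heart rate in beats per minute (> 0); vectorised.
#' @param timeframes timeframes per cardiac cycle (> 0); vectorised.
#' @param rounded if `TRUE`, round to the nearest integer ms (half away
#'   from zero), the form used when quoting scanner settings.
#' @return Temporal resolution in ms.
#' @examples
#' temporal_resolution_ms(138, 44)                 # 9.88...
#' temporal_resolution_ms(138, 44, rounded = TRUE) # 10
#' @export
temporal_resolution_ms <- function(heart_rate_bpm, timeframes,
                                   rounded = FALSE) {
  if (!is.numeric(heart_rate_bpm) || !all(is.finite(heart_rate_bpm)) ||
      any(heart_rate_bpm <= 0)) {
    stop_param("`heart_rate_bpm` must be > 0")
  }
  if (!is.numeric(timeframes) || !all(is.finite(timeframes)) ||
      any(timeframes <= 0)) {
    stop_param("`timeframes` must be > 0")
  }
  res <- 60000 / (heart_rate_bpm * timeframes)
  if (isTRUE(rounded)) round_half_up(res) else res
}
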
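#' Baseline-correction specification
#'
#' Leveling of the quiescent portion of a flow/velocity curve to zero so
#' that the time-to-foot tangent intersection is well defined.  Three modes:
#' \describe{
#'   \item{`none`}{no correction.}
#'   \item{`automatic`}{subtract the mean of the late-diastolic segment at
#'     80--95\% of the cycle (the samples with index `i` satisfying
#'     `0.80 <= i/n_frames < 0.95`), computed per curve independently.
#'     Late diastole sits close to the next systolic upslope, which reduces
#'     the influence of early-diastolic retrograde flow compared with
#'     windows placed earlier in diastole.}
#'   \item{`manual`}{subtract the mean over a user-chosen phase window,
#'     typically the segment immediately prior to the systolic upslope.}
#' }
#'
#' @param mode `"none"`, `"automatic"` or `"manual"`.
#' @param manual_window half-open phase interval `[a, b)` with
#'   `0 <= a < b <= 1`; required when `mode = "manual"`.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(mode = c("none", "automatic", "manual"),
                          manual_window = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(manual_window) || length(manual_window) != 2L ||
        !all(is.finite(manual_window))) {
      stop_param("`manual_window` (length-2 numeric) is required for manual baseline correction")
    }
    a <- manual_window[1L]; b <- manual_window[2L]
    if (!(a >= 0 && a < b && b <= 1)) {
      stop_param("`manual_window` must satisfy 0 <= a < b <= 1")
    }
    manual_window <- as.numeric(manual_window)
  } else {
    manual_window <- NULL
  }
  structure(list(mode = mode, manual_window = manual_window),
            class = "baseline_spec")
}

#' Samples inside a baseline phase window
#'
#' The half-open index rule used by both automatic and manual baseline
#' correction: sample `i` (0-based) belongs to window `[a, b)` iff
#' `a <= i / n_frames < b`.
#'
#' @param n_frames number of timeframes per cardiac cycle.
#' @param window length-2 numeric, phase interval `[a, b)`.
#' @return Integer vector of 0-based sample indices.
#' @examples
#' baseline_window_indices(40, c(0.80, 0.95))  # 32 33 34 35 36 37
#' @export
baseline_window_indices <- function(n_frames, window) {
  i <- 0:(n_frames - 1L)
  idx <- i[i / n_frames >= window[1L] & i / n_frames < window[2L]]
  if (length(idx) == 0L) {
    stop_param("baseline window [", window[1L], ", ", window[2L],
               ") contains no samples at n_frames = ", n_frames)
  }
  idx
}

# phase window of the automatic (late-diastolic) correction
AUTO_BASELINE_WINDOW <- c(0.80, 0.95)

#' Baseline-correct a curve
#'
#' Subtracts the mean of the defining phase window from the whole curve;
#' after correction the mean of that window is exactly zero.  Each curve of
#' a pair is corrected independently.
#'
#' @param curve a [sampled_curve()].
#' @param spec a [baseline_spec()]; mode `"none"` returns the curve
#'   unchanged.
#' @return The corrected [sampled_curve()].
#' @export
baseline_correct <- function(curve, spec = baseline_spec("automatic")) {
  stopifnot(inherits(curve, "sampled_curve"), inherits(spec, "baseline_spec"))
  if (spec$mode == "none") return(curve)
  window <- if (spec$mode == "automatic") AUTO_BASELINE_WINDOW else spec$manual_window
  idx <- baseline_window_indices(curve$n_frames, window)
  out <- curve
  out$values <- curve$values - mean(curve$values[idx + 1L])
  out
}
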
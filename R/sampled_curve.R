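#' Sampled cardiac-cycle curve
#'
#' One cardiac cycle of uniformly sampled flow (ml/s) or velocity (cm/s)
#' values.  Sample `k` (0-based) represents phase `k / n_frames` of the
#' cycle; retrospective ECG gating makes the reconstructed cycle periodic,
#' so the curve is treated as circular throughout the package.
#'
#' @param values numeric vector of flow or velocity values, one per
#'   timeframe; at least 8 timeframes, all finite.
#' @param cycle_duration_ms cardiac cycle length in ms (> 0).
#' @param kind `"flow"` (ml/s) or `"velocity"` (cm/s).
#' @param label free-text label carried through analyses.
#' @return An object of class `sampled_curve`: a list with elements
#'   `values`, `n_frames`, `cycle_duration_ms`, `kind`, `label`.
#' @examples
#' cur <- sampled_curve(sin(pi * (0:39) / 40)^2, cycle_duration_ms = 800)
#' cur
#' @export
sampled_curve <- function(values, cycle_duration_ms,
                          kind = c("flow", "velocity"), label = "") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 8L) {
    stop_param("a sampled curve needs at least 8 timeframes, got ",
               length(values))
  }
  if (!all(is.finite(values))) stop_param("curve values must all be finite")
  check_scalar(cycle_duration_ms, "cycle_duration_ms", positive = TRUE)
  structure(
    list(values = values,
         n_frames = length(values),
         cycle_duration_ms = as.numeric(cycle_duration_ms),
         kind = kind,
         label = as.character(label)[1L]),
    class = "sampled_curve"
  )
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve> %s curve%s\n", x$kind,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  cat(sprintf("  %d timeframes over %.2f ms (frame duration %.3f ms)\n",
              x$n_frames, x$cycle_duration_ms, frame_duration_ms(x)))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Duration of one timeframe in ms
#'
#' @param curve a [sampled_curve()].
#' @return `cycle_duration_ms / n_frames` in ms.
#' @export
frame_duration_ms <- function(curve) {
  stopifnot(inherits(curve, "sampled_curve"))
  curve$cycle_duration_ms / curve$n_frames
}

#' Ascending/descending curve pair
#'
#' The unit of PWV analysis: the curve measured in the ascending aorta, the
#' curve measured downstream (descending aorta / diaphragm level), and the
#' centerline traveling distance between the two flow planes.
#'
#' @param ascending,descending [sampled_curve()] objects sharing `n_frames`,
#'   `cycle_duration_ms` and `kind`.
#' @param delta_d_mm traveling distance between flow planes in mm (> 0).
#' @return An object of class `curve_pair`.
#' @export
curve_pair <- function(ascending, descending, delta_d_mm) {
  if (!inherits(ascending, "sampled_curve") ||
      !inherits(descending, "sampled_curve")) {
    stop_param("`ascending` and `descending` must be sampled_curve objects")
  }
  if (ascending$n_frames != descending$n_frames) {
    stop_param("curves in a pair must share n_frames")
  }
  if (!isTRUE(all.equal(ascending$cycle_duration_ms,
                        descending$cycle_duration_ms))) {
    stop_param("curves in a pair must share cycle_duration_ms")
  }
  if (ascending$kind != descending$kind) {
    stop_param("curves in a pair must share kind")
  }
  check_scalar(delta_d_mm, "delta_d_mm", positive = TRUE)
  structure(
    list(ascending = ascending, descending = descending,
         delta_d_mm = as.numeric(delta_d_mm)),
    class = "curve_pair"
  )
}

#' @export
print.curve_pair <- function(x, ...) {
  cat(sprintf("<curve_pair> %s, %d timeframes, cycle %.2f ms, delta-d %.1f mm\n",
              x$ascending$kind, x$ascending$n_frames,
              x$ascending$cycle_duration_ms, x$delta_d_mm))
  invisible(x)
}
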
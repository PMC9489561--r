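#' Temporal-resolution phantom specification
#'
#' Defines the computer experiment that determines how many timeframes per
#' cardiac cycle an acquisition needs for accurate PWV.  A high-resolution
#' ascending waveform is paired with a simulated descending curve (the
#' ascending curve delayed by `vessel_length / reference PWV`, scaled by
#' `desc_scale` to mimic blood diversion to the arch branches, and
#' Gaussian-smoothed).  Both curves are downsampled to each value of
#' `frames_grid` to mimic acquisition, PWV is re-estimated by time-to-foot
#' with automatic baseline correction, and the percent error against the
#' reference PWV is recorded.
#'
#' The smoothing "width" is a kernel-support parameter in upsampled frames;
#' its translation to a Gaussian SD is controlled by
#' `smooth_width_semantics`: `"six_sigma"` (default, SD = width/6, i.e. the
#' kernel's +/-3 SD span equals the width), `"sd"` (SD = width) or `"fwhm"`
#' (SD = width/2.355).  By default the filter is applied to both curves
#' (`smooth_both = TRUE`): symmetric filtering leaves the transit time
#' unbiased, whereas filtering only the descending curve shifts its
#' tangent-foot systematically.  Set `smooth_both = FALSE` to smooth the
#' descending curve only.
#'
#' @param base_curve high-resolution ascending [sampled_curve()]; defaults
#'   to the noise-free synthetic profile waveform at `upsample_frames`.
#' @param profile `"neonate"` or `"adolescent"`, used when `base_curve` is
#'   not supplied.
#' @param vessel_length_mm traveling distance delta-d in mm (study lengths:
#'   25 = neonatal arch, 60 = neonatal thoracic aorta / adolescent arch,
#'   150 = adolescent thoracic aorta).
#' @param ref_pwv_m_per_s reference PWV grid in m/s (default 2,4,6,8,10).
#' @param frames_grid downsampling targets (default 20:60).
#' @param upsample_frames phantom resolution (default 10000).
#' @param desc_scale descending amplitude factor in (0, 1] (default 0.6).
#' @param smooth_width_frames Gaussian width in upsampled frames (default
#'   2000); 0 disables the phantom smoothing step.
#' @param smooth_width_semantics how width maps to the kernel SD (above).
#' @param smooth_both apply the phantom filter to both curves (default) or
#'   to the descending curve only.
#' @param analysis_smoothing [smoothing_spec()] used by the TTF analysis.
#' @param baseline [baseline_spec()] used by the TTF analysis.
#' @param tolerance_pct cut-off tolerance on |percent error| (default 10).
#' @param phase_offset phase of the first downsampled timeframe (default 0).
#' @param downsample_mode `"point"` or `"bin"`, see [downsample_curve()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(base_curve = NULL,
                         profile = c("neonate", "adolescent"),
                         vessel_length_mm = 60,
                         ref_pwv_m_per_s = c(2, 4, 6, 8, 10),
                         frames_grid = 20:60,
                         upsample_frames = 10000,
                         desc_scale = 0.6,
                         smooth_width_frames = 2000,
                         smooth_width_semantics = c("six_sigma", "sd", "fwhm"),
                         smooth_both = TRUE,
                         analysis_smoothing = smoothing_spec(),
                         baseline = baseline_spec("automatic"),
                         tolerance_pct = 10,
                         phase_offset = 0,
                         downsample_mode = c("point", "bin")) {
  profile <- match.arg(profile)
  smooth_width_semantics <- match.arg(smooth_width_semantics)
  downsample_mode <- match.arg(downsample_mode)
  upsample_frames <- as.integer(check_scalar(upsample_frames,
                                             "upsample_frames",
                                             positive = TRUE))
  if (is.null(base_curve)) {
    base_curve <- generate_waveform(waveform_params(profile), upsample_frames)
  }
  stopifnot(inherits(base_curve, "sampled_curve"))
  if (upsample_frames < base_curve$n_frames) {
    stop_param("upsample_frames must be >= the base curve's n_frames")
  }
  check_scalar(vessel_length_mm, "vessel_length_mm", positive = TRUE)
  if (length(ref_pwv_m_per_s) < 1L || any(!is.finite(ref_pwv_m_per_s)) ||
      any(ref_pwv_m_per_s <= 0)) {
    stop_param("`ref_pwv_m_per_s` must be positive and finite")
  }
  frames_grid <- as.integer(frames_grid)
  if (length(frames_grid) < 1L || any(frames_grid < 8L)) {
    stop_param("`frames_grid` entries must be >= 8")
  }
  if (upsample_frames < max(frames_grid)) {
    stop_param("upsample_frames must be >= max(frames_grid)")
  }
  check_scalar(desc_scale, "desc_scale", positive = TRUE)
  if (desc_scale > 1) stop_param("`desc_scale` must be in (0, 1]")
  check_scalar(smooth_width_frames, "smooth_width_frames", nonnegative = TRUE)
  check_scalar(tolerance_pct, "tolerance_pct", nonnegative = TRUE)
  cycle <- base_curve$cycle_duration_ms
  max_delay <- vessel_length_mm / min(ref_pwv_m_per_s)
  if (max_delay >= cycle) {
    stop_param("construction delay (", round(max_delay, 2),
               " ms) reaches the cycle duration (", round(cycle, 2), " ms)")
  }
  structure(
    list(base_curve = base_curve, profile = profile,
         vessel_length_mm = as.numeric(vessel_length_mm),
         ref_pwv_m_per_s = as.numeric(ref_pwv_m_per_s),
         frames_grid = frames_grid,
         upsample_frames = upsample_frames,
         desc_scale = as.numeric(desc_scale),
         smooth_width_frames = as.numeric(smooth_width_frames),
         smooth_width_semantics = smooth_width_semantics,
         smooth_both = isTRUE(smooth_both),
         analysis_smoothing = analysis_smoothing,
         baseline = baseline,
         tolerance_pct = as.numeric(tolerance_pct),
         phase_offset = as.numeric(phase_offset),
         downsample_mode = downsample_mode),
    class = "phantom_spec"
  )
}

phantom_sigma_frames <- function(spec) {
  if (spec$smooth_width_frames <= 0) return(0)
  switch(spec$smooth_width_semantics,
         six_sigma = spec$smooth_width_frames / 6,
         sd = spec$smooth_width_frames,
         fwhm = spec$smooth_width_frames / (2 * sqrt(2 * log(2))))
}

#' Build one high-resolution phantom curve pair
#'
#' Upsamples the base ascending curve to `upsample_frames`, creates the
#' descending curve by circularly delaying it by
#' `vessel_length_mm / ref_pwv` ms and scaling by `desc_scale`, then
#' applies the phantom Gaussian filter (to both curves by default, see
#' [phantom_spec()]).  The construction delay is stored as attribute
#' `construction_delay_ms` for verification.
#'
#' @param spec a [phantom_spec()].
#' @param ref_pwv reference PWV in m/s.
#' @return A [curve_pair()] at `upsample_frames` timeframes with
#'   attributes `construction_delay_ms` and `ref_pwv_m_per_s`.
#' @examples
#' sp <- phantom_spec(profile = "neonate", vessel_length_mm = 60)
#' pair <- build_phantom_pair(sp, 4)
#' attr(pair, "construction_delay_ms")  # 60/4 = 15 ms
#' @export
build_phantom_pair <- function(spec, ref_pwv) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_scalar(ref_pwv, "ref_pwv", positive = TRUE)
  asc <- upsample_curve(spec$base_curve, spec$upsample_frames)
  delay <- spec$vessel_length_mm / ref_pwv
  if (delay >= asc$cycle_duration_ms) {
    stop_param("construction delay (", round(delay, 2),
               " ms) reaches the cycle duration")
  }
  desc <- shift_curve(asc, delay)
  desc$values <- spec$desc_scale * desc$values
  sigma <- phantom_sigma_frames(spec)
  if (sigma > 0) {
    desc$values <- gaussian_smooth_circular(desc$values, sigma)
    if (spec$smooth_both) {
      asc$values <- gaussian_smooth_circular(asc$values, sigma)
    }
  }
  asc$label <- sprintf("phantom asc (%s)", spec$profile)
  desc$label <- sprintf("phantom desc (%s, %.3g m/s)", spec$profile, ref_pwv)
  pair <- curve_pair(asc, desc, spec$vessel_length_mm)
  attr(pair, "construction_delay_ms") <- delay
  attr(pair, "ref_pwv_m_per_s") <- ref_pwv
  pair
}

#' Run the temporal-resolution experiment
#'
#' For every combination of reference PWV and timeframes per cardiac cycle
#' in the spec's grids: build the high-resolution pair, downsample both
#' curves, estimate PWV with time-to-foot (automatic baseline correction),
#' and record the percent error `(estimated - reference)/reference * 100`.
#' Analysis failures are recorded as missing cells (`NA`), never silent
#' zeros.  The experiment is deterministic given the base curve.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `error_grid`: `errors_pct` (matrix,
#'   reference PWV in rows, frames in columns), the grids, the tolerance,
#'   and the cut-off summary of [find_required_frames()].
#' @export
run_resolution_experiment <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  err <- matrix(NA_real_,
                nrow = length(spec$ref_pwv_m_per_s),
                ncol = length(spec$frames_grid),
                dimnames = list(paste0("pwv", spec$ref_pwv_m_per_s),
                                paste0("f", spec$frames_grid)))
  for (i in seq_along(spec$ref_pwv_m_per_s)) {
    p <- spec$ref_pwv_m_per_s[i]
    pair <- build_phantom_pair(spec, p)
    for (j in seq_along(spec$frames_grid)) {
      n <- spec$frames_grid[j]
      est <- tryCatch({
        a <- downsample_curve(pair$ascending, n, spec$phase_offset,
                              spec$downsample_mode)
        d <- downsample_curve(pair$descending, n, spec$phase_offset,
                              spec$downsample_mode)
        transit_time(curve_pair(a, d, spec$vessel_length_mm), "ttf",
                     spec$baseline, spec$analysis_smoothing)
      }, error = function(e) NULL)
      if (!is.null(est) && isTRUE(est$pwv_defined)) {
        err[i, j] <- (est$pwv_m_per_s - p) / p * 100
      }
    }
  }
  grid <- structure(
    list(errors_pct = err,
         ref_pwv_m_per_s = spec$ref_pwv_m_per_s,
         frames_grid = spec$frames_grid,
         vessel_length_mm = spec$vessel_length_mm,
         profile = spec$profile,
         tolerance_pct = spec$tolerance_pct),
    class = "error_grid")
  cut <- find_required_frames(grid, spec$tolerance_pct)
  grid$cutoff_frames <- cut$cutoff_frames
  grid$post_cutoff_error_range_pct <- cut$error_range_pct
  grid
}

#' Minimum timeframes per cardiac cycle satisfying a tolerance
#'
#' Returns the smallest `N` in the frames grid such that the absolute
#' percent error stays within `tolerance_pct` for every reference PWV at
#' every `N' >= N`, together with the (min, max) error over that region.
#' Missing cells count as failures.
#'
#' @param grid an `error_grid` from [run_resolution_experiment()].
#' @param tolerance_pct tolerance on |percent error| (default: the grid's).
#' @return A list with `found` (logical), `cutoff_frames` (`NA` when no
#'   `N` qualifies), `error_range_pct` and `tolerance_pct`.
#' @export
find_required_frames <- function(grid, tolerance_pct = grid$tolerance_pct) {
  stopifnot(inherits(grid, "error_grid"))
  check_scalar(tolerance_pct, "tolerance_pct", nonnegative = TRUE)
  m <- grid$errors_pct
  col_ok <- apply(m, 2L, function(col) {
    all(is.finite(col)) && all(abs(col) <= tolerance_pct)
  })
  suffix_ok <- rev(cumprod(rev(as.numeric(col_ok)))) == 1
  if (!any(suffix_ok)) {
    return(list(found = FALSE, cutoff_frames = NA_integer_,
                error_range_pct = c(NA_real_, NA_real_),
                tolerance_pct = tolerance_pct))
  }
  j <- which(suffix_ok)[1L]
  region <- m[, j:ncol(m), drop = FALSE]
  list(found = TRUE,
       cutoff_frames = grid$frames_grid[j],
       error_range_pct = range(region),
       tolerance_pct = tolerance_pct)
}

#' @export
print.error_grid <- function(x, ...) {
  cat(sprintf("<error_grid> %s profile, vessel length %.0f mm\n",
              x$profile, x$vessel_length_mm))
  cat(sprintf("  %d reference PWV x %d frame counts (%d-%d)\n",
              length(x$ref_pwv_m_per_s), length(x$frames_grid),
              min(x$frames_grid), max(x$frames_grid)))
  if (is.na(x$cutoff_frames)) {
    cat(sprintf("  no cut-off satisfies |error| <= %.3g%%\n", x$tolerance_pct))
  } else {
    cat(sprintf("  cut-off: %d timeframes/cycle (|error| <= %.3g%%), error range %.2f to %.2f%%\n",
                x$cutoff_frames, x$tolerance_pct,
                x$post_cutoff_error_range_pct[1L],
                x$post_cutoff_error_range_pct[2L]))
  }
  invisible(x)
}

#' @export
as.data.frame.error_grid <- function(x, ...) {
  data.frame(
    profile = x$profile,
    vessel_length_mm = x$vessel_length_mm,
    ref_pwv_m_per_s = rep(x$ref_pwv_m_per_s, times = length(x$frames_grid)),
    n_frames = rep(x$frames_grid, each = length(x$ref_pwv_m_per_s)),
    error_pct = as.vector(x$errors_pct))
}

#' Plot an error grid
#'
#' Percent PWV error against timeframes per cardiac cycle, one line per
#' reference PWV, with the cut-off marked by a vertical dashed line.
#'
#' @param x an `error_grid`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.error_grid <- function(x, ...) {
  graphics::matplot(x$frames_grid, t(x$errors_pct), type = "l", lty = 1,
                    xlab = "timeframes per cardiac cycle",
                    ylab = "PWV error (%)",
                    main = sprintf("%s, %.0f mm", x$profile,
                                   x$vessel_length_mm), ...)
  if (!is.na(x$cutoff_frames)) {
    graphics::abline(v = x$cutoff_frames, col = "red", lty = 2)
  }
  graphics::abline(h = 0, col = "grey", lty = 3)
  graphics::legend("topright", legend = paste0(x$ref_pwv_m_per_s, " m/s"),
                   col = seq_along(x$ref_pwv_m_per_s), lty = 1, cex = 0.8)
  invisible(x)
}
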
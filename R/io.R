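# Curve CSV dialect
# -----------------
# Line 1 (metadata header, required):
#   # cycle_duration_ms=<float> kind=<flow|velocity> label=<free text>
# Data: either one value per line, or two comma-separated columns
# time_ms,value with a uniformly spaced time column (an optional
# "time_ms,value" column-header line is accepted).  The writer emits the
# two-column dialect.

#' Write a curve to CSV
#'
#' Emits the two-column dialect (`time_ms,value`) with a metadata header
#' line carrying the cycle duration, kind and label.  Values are printed
#' with 17 significant digits so that [read_curve()] round-trips exactly.
#'
#' @param curve a [sampled_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sampled_curve"))
  dt <- frame_duration_ms(curve)
  lines <- c(
    sprintf("# cycle_duration_ms=%.17g kind=%s label=%s",
            curve$cycle_duration_ms, curve$kind, curve$label),
    "time_ms,value",
    sprintf("%.17g,%.17g", (seq_len(curve$n_frames) - 1) * dt, curve$values))
  writeLines(lines, path)
  invisible(path)
}

#' Read a curve from CSV
#'
#' Accepts both dialects (single value column, or `time_ms,value`).  The
#' metadata header is mandatory; the two-column time axis must be
#' uniformly spaced.
#'
#' @param path input file path.
#' @return A [sampled_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(trimws(lines[1L]), "#")) {
    stop_param("curve file format error: missing metadata header line ",
               "('# cycle_duration_ms=... kind=... label=...')")
  }
  header <- sub("^\\s*#\\s*", "", lines[1L])
  get_key <- function(key, pattern) {
    m <- regmatches(header, regexec(paste0(key, "=", pattern), header))[[1L]]
    if (length(m) < 2L) {
      stop_param("curve file format error: missing metadata key '", key, "'")
    }
    m[2L]
  }
  cycle <- as.numeric(get_key("cycle_duration_ms", "([-+0-9.eE]+)"))
  if (!is.finite(cycle)) {
    stop_param("curve file format error: unparsable cycle_duration_ms")
  }
  kind <- get_key("kind", "(flow|velocity)")
  label_match <- regmatches(header, regexec("label=(.*)$", header))[[1L]]
  label <- if (length(label_match) >= 2L) label_match[2L] else ""

  body <- lines[-1L]
  fields <- strsplit(body, ",", fixed = TRUE)
  ncols <- unique(lengths(fields))
  # tolerate a column-header line in the two-column dialect
  if (length(body) > 0L && identical(tolower(gsub("\\s", "", body[1L])),
                                     "time_ms,value")) {
    body <- body[-1L]
    fields <- fields[-1L]
    ncols <- unique(lengths(fields))
  }
  if (length(body) == 0L) stop_param("curve file format error: no data rows")
  if (length(ncols) != 1L || !ncols %in% c(1L, 2L)) {
    stop_param("curve file format error: rows must have 1 or 2 columns, ",
               "consistently")
  }
  if (ncols == 1L) {
    values <- as.numeric(vapply(fields, `[`, "", 1L))
  } else {
    times <- as.numeric(vapply(fields, `[`, "", 1L))
    values <- as.numeric(vapply(fields, `[`, "", 2L))
    if (anyNA(times)) {
      stop_param("curve file format error: unparsable time at row ",
                 which(is.na(times))[1L])
    }
    if (length(times) > 1L) {
      steps <- diff(times)
      ref <- steps[1L]
      bad <- which(abs(steps - ref) > 1e-6 * max(abs(ref), 1))
      if (ref <= 0 || length(bad) > 0L) {
        row <- if (ref <= 0) 2L else bad[1L] + 1L
        stop_param("curve file format error: non-uniform time column at row ",
                   row, " (time_ms = ", times[row], ")")
      }
    }
  }
  if (anyNA(values)) {
    stop_param("curve file format error: unparsable value at row ",
               which(is.na(values))[1L])
  }
  sampled_curve(values, cycle, kind, label)
}
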
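#' Vessel centerline
#'
#' An ordered polyline of 3D points (world-space mm) tracing the vessel
#' midline between the two flow-measurement planes, as exported from a
#' manual frame-by-frame delineation.
#'
#' @param points numeric matrix or data frame with 3 columns (x, y, z in
#'   mm) and at least 2 rows; consecutive points must be distinct.
#' @param label free text, e.g. `"aortic_arch"` or `"thoracic_aorta"`.
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, label = "") {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 3L) {
    stop_param("`points` must be numeric with 3 columns (x, y, z in mm)")
  }
  if (nrow(pts) < 2L) stop_param("a centerline needs at least 2 points")
  if (!all(is.finite(pts))) stop_param("centerline coordinates must be finite")
  seg <- diff(pts)
  if (any(rowSums(seg^2) == 0)) {
    stop_param("consecutive centerline points must be distinct")
  }
  dimnames(pts) <- list(NULL, c("x_mm", "y_mm", "z_mm"))
  structure(list(points = pts, label = as.character(label)[1L]),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline>%s %d points, length %.2f mm\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$points), centerline_length(x)))
  invisible(x)
}

#' Centerline traveling distance
#'
#' Arc length of the polyline: the sum of Euclidean distances between
#' consecutive points.  This is the blood traveling distance delta-d
#' between flow planes used in PWV = delta-d / delta-t.  The result is at
#' least the straight-line endpoint distance and is invariant under rigid
#' transforms.
#'
#' @param line a [centerline()].
#' @return Length in mm.
#' @examples
#' centerline_length(centerline(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))))
#' @export
centerline_length <- function(line) {
  stopifnot(inherits(line, "centerline"))
  sum(sqrt(rowSums(diff(line$points)^2)))
}

#' Read a centerline from CSV
#'
#' Expects columns `x_mm`, `y_mm`, `z_mm` in traversal order.
#'
#' @param path CSV file path.
#' @param label optional label (defaults to the file name).
#' @return A [centerline()].
#' @export
read_centerline <- function(path, label = NULL) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop_param("centerline CSV must have columns x_mm, y_mm, z_mm; missing: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (is.null(label)) label <- basename(path)
  centerline(df[, need], label = label)
}
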
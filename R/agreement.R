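#' Bland-Altman agreement between two measurement methods
#'
#' Paired differences are taken as first argument minus second
#' (`d = a - b`; the sign of the bias depends on this order).  The bias is
#' the mean difference, the SD is the sample SD (n-1 denominator), and the
#' 95\% limits of agreement are `bias +/- 1.96 * SD`.
#'
#' @param a,b numeric vectors of pairwise-aligned measurements, equal
#'   length, n >= 2.
#' @return An object of class `agreement_summary` with `bias`, `sd`,
#'   `loa_low`, `loa_high`, `n`, and a per-pair `data` table with columns
#'   `mean` and `difference` for plotting.
#' @examples
#' bland_altman(c(4, 5), c(3, 6))  # bias 0, sd sqrt(2)
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop_param("`a` and `b` must have equal length (got ", length(a), " and ",
               length(b), ")")
  }
  if (length(a) < 2L) stop_param("at least 2 pairs are required")
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop_param("measurements must be finite")
  }
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd = s,
         loa_low = bias - 1.96 * s,
         loa_high = bias + 1.96 * s,
         n = length(d),
         difference = "first minus second argument",
         data = data.frame(mean = (a + b) / 2, difference = d)),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> n = %d (difference = %s)\n", x$n,
              x$difference))
  cat(sprintf("  bias %.4g +/- %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$bias, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Per-pair difference against per-pair mean, with a solid bias line and
#' dashed 95\% limits of agreement.
#'
#' @param x an `agreement_summary`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agreement_summary <- function(x, ...) {
  graphics::plot(x$data$mean, x$data$difference,
                 xlab = "mean of methods", ylab = "difference", ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Summarise a tidy PWV results table by method
#'
#' Aggregates per-cell statistics of a tidy results table (one row per
#' subject x method x baseline x curve kind), the shape behind group-level
#' method comparisons: mean +/- SD per cell, or median (range) for
#' descriptive characteristics.
#'
#' @param results data frame containing the grouping columns and the value
#'   column.
#' @param value name of the value column (default `"pwv_m_per_s"`).
#' @param by grouping column names (defaults to those of `method`,
#'   `baseline`, `kind` that are present).
#' @param stat `"mean_sd"` or `"median_range"`.
#' @return A data frame with one row per group: `n`, `mean`, `sd` (or
#'   `median`, `min`, `max`).  Rows with missing values are dropped from
#'   the statistics; groups with no finite values report `NA`.
#' @export
summarize_methods <- function(results, value = "pwv_m_per_s",
                              by = intersect(c("method", "baseline", "kind"),
                                             names(results)),
                              stat = c("mean_sd", "median_range")) {
  stat <- match.arg(stat)
  if (!is.data.frame(results)) stop_param("`results` must be a data frame")
  if (!value %in% names(results)) {
    stop_param("value column '", value, "' not found")
  }
  if (length(by) == 0L || !all(by %in% names(results))) {
    stop_param("grouping columns not found in `results`")
  }
  groups <- results[by]
  v <- results[[value]]
  agg <- function(f) {
    out <- stats::aggregate(v, by = groups,
                            FUN = function(z) {
                              z <- z[is.finite(z)]
                              if (length(z) == 0L) NA_real_ else f(z)
                            })
    out$x
  }
  counts <- stats::aggregate(v, by = groups,
                             FUN = function(z) sum(is.finite(z)))
  ord <- do.call(order, unname(as.list(counts[by])))
  out <- counts[ord, , drop = FALSE]
  names(out)[names(out) == "x"] <- "n"
  if (stat == "mean_sd") {
    out$mean <- agg(mean)[ord]
    out$sd <- agg(function(z) if (length(z) > 1L) stats::sd(z) else 0)[ord]
  } else {
    out$median <- agg(stats::median)[ord]
    out$min <- agg(min)[ord]
    out$max <- agg(max)[ord]
  }
  rownames(out) <- NULL
  out
}
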
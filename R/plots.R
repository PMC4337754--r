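## Base-graphics plot methods.

#' @describeIn plotTrajectory method for Trajectory.
#' @export
setMethod("plot", signature(x = "Trajectory", y = "missing"),
  function(x, y, col = NULL, cex = 0.4, ...) {
    n <- nFixes(x)
    if (is.null(col))
      col <- grDevices::hcl.colors(n, "Spectral")
    graphics::plot(x@coords, asp = 1, pch = 16, cex = cex, col = col,
                   xlab = "x (map units)", ylab = "y (map units)", ...)
    graphics::lines(x@coords, col = grDevices::grey(0.5, 0.3))
    invisible(x)
  })

#' Plot helpers
#'
#' \code{plot} methods are provided for \code{Trajectory} (path coloured
#' by time), \code{HullSet} (hull outlines) and \code{IsoplethSet} (nested
#' isopleths, innermost level on top).
#'
#' @param x object to plot.
#' @param y unused.
#' @param col colours.
#' @param cex point size.
#' @param border hull border colour.
#' @param ... passed to the underlying graphics calls.
#' @name plotTrajectory
NULL

#' @describeIn plotTrajectory method for HullSet.
#' @export
setMethod("plot", signature(x = "HullSet", y = "missing"),
  function(x, y, border = grDevices::grey(0.2, 0.15), ...) {
    xy <- x@traj@coords
    graphics::plot(xy, asp = 1, pch = 16, cex = 0.3,
                   col = grDevices::grey(0.4),
                   xlab = "x (map units)", ylab = "y (map units)", ...)
    for (p in x@polygons)
      if (nrow(p) >= 3L) graphics::polygon(p, border = border)
    invisible(x)
  })

#' @describeIn plotTrajectory method for IsoplethSet.
#' @export
setMethod("plot", signature(x = "IsoplethSet", y = "missing"),
  function(x, y, col = NULL, ...) {
    nl <- length(x@levels)
    if (is.null(col))
      col <- grDevices::hcl.colors(nl, "YlOrRd", rev = TRUE, alpha = 0.6)
    allxy <- do.call(rbind, lapply(x@geometry, function(g)
      if (is.null(g)) NULL else do.call(rbind, lapply(g$rings, `[[`, "xy"))))
    if (is.null(allxy)) stop("isopleth set has no stored geometry")
    graphics::plot(allxy, type = "n", asp = 1,
                   xlab = "x (map units)", ylab = "y (map units)", ...)
    for (li in rev(seq_len(nl))) {
      g <- x@geometry[[li]]
      if (is.null(g)) next
      for (r in g$rings)
        graphics::polygon(r$xy, col = if (r$hole) "white" else col[li],
                          border = grDevices::grey(0.3))
    }
    graphics::legend("topright", legend = x@levels, fill = col,
                     title = paste0(x@sortMetric, " isopleth"), bty = "n",
                     cex = 0.8)
    invisible(x)
  })

#' Scatterplot of revisitation against visit duration
#'
#' One point per hull: number of separate visits (x) against mean number
#' of occurrences per visit (y).  Because both metrics are quantised, a
#' small uniform jitter (default 0.1) is added to render point density.
#'
#' @param hs a \code{\linkS4class{HullSet}} with time-use metrics (see
#'   \code{\link{addTimeUse}}).
#' @param jitterAmount half-width of the uniform jitter; 0 disables.
#' @param ... passed to \code{plot}.
#' @return Invisibly, the plotted data frame.
#' @export
plotTimeUse <- function(hs, jitterAmount = 0.1, ...) {
  met <- hullMetrics(hs)
  if (is.null(met$nsv)) stop("hull set has no time-use metrics; ",
                             "run addTimeUse() first")
  x <- met$nsv; y <- met$mnlv
  if (jitterAmount > 0) {
    x <- x + stats::runif(length(x), -jitterAmount, jitterAmount)
    y <- y + stats::runif(length(y), -jitterAmount, jitterAmount)
  }
  graphics::plot(x, y, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.2, 0.4),
                 xlab = "revisitation (separate visits)",
                 ylab = "duration (mean occurrences per visit)", ...)
  invisible(data.frame(nsv = met$nsv, mnlv = met$mnlv))
}

#' Plot a space-time parity distribution
#'
#' @param pd output of \code{\link{parityDistribution}}.
#' @param ... passed to \code{matplot}.
#' @return Invisibly, \code{pd}.
#' @export
plotParity <- function(pd, ...) {
  qcols <- grep("^q", names(pd), value = TRUE)
  graphics::matplot(pd$dt / 3600, as.matrix(pd[qcols]), type = "b",
                    pch = 16, lty = 1,
                    xlab = "time lag (h)", ylab = "parity s*", ...)
  graphics::legend("topright", legend = qcols, col = seq_along(qcols),
                   lty = 1, bty = "n")
  invisible(pd)
}
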
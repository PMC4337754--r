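## Time-use metrics (revisitation, visit duration), time-selected hull
## classification, and directional-route extraction.

#' Segment enclosed occurrence times into separate visits
#'
#' A new visit starts whenever the gap between consecutive occurrences
#' exceeds the inter-visit gap (IVG).  The IVG should normally be at least
#' several times the sampling interval and is tied to the periodicity of
#' the behaviour of interest (e.g. 24 h for a daily foraging cycle).
#'
#' @param times sorted numeric occurrence timestamps (seconds).
#' @param ivg inter-visit gap in seconds (> 0).
#' @return A list of numeric vectors, one per visit.
#' @examples
#' v <- segmentVisits(c(0, 1, 2, 30, 31) * 3600, 10 * 3600)
#' length(v)                  # 2 visits
#' mean(lengths(v))           # 2.5 occurrences per visit
#' @export
segmentVisits <- function(times, ivg) {
  stopifnot(length(times) >= 1L, ivg > 0)
  if (is.unsorted(times)) times <- sort(times)
  brk <- c(0L, which(diff(times) > ivg), length(times))
  lapply(seq_len(length(brk) - 1L), function(i)
    times[(brk[i] + 1L):brk[i + 1L]])
}

#' Add time-use metrics to a hull set
#'
#' For every hull, segments the timestamps of all enclosed fixes (not just
#' the neighbours: bypassed points represent additional visits to the hull
#' area) into separate visits using the IVG, and records the number of
#' separate visits (\code{nsv}, revisitation rate), the mean number of
#' occurrences per visit (\code{mnlv}, visit duration), and their
#' area-normalised variants (\code{NA} for zero-area hulls).  The identity
#' \code{nsv * mnlv = nEnclosed} holds exactly.
#'
#' @param hs a \code{\linkS4class{HullSet}}.
#' @param ivg inter-visit gap in seconds.  A warning is issued when ivg is
#'   less than 3 times the median sampling interval.
#' @return The \code{HullSet} with metric columns \code{nsv}, \code{mnlv},
#'   \code{nsvPerArea}, \code{mnlvPerArea} added (any previous time-use
#'   columns are replaced).
#' @examples
#' tr <- trajectory(runif(40), runif(40), (0:39) * 3600)
#' hs <- addTimeUse(buildHulls(tr, neighborRule("k", 4), s = 0),
#'                  ivg = 10 * 3600)
#' @export
addTimeUse <- function(hs, ivg) {
  stopifnot(is(hs, "HullSet"), ivg > 0)
  md <- medianDt(hs@traj)
  if (ivg < 3 * md)
    warning("ivg (", ivg, " s) is less than 3 x the median sampling ",
            "interval (", md, " s); visit metrics may be unreliable")
  tt <- hs@traj@time
  n <- nHulls(hs)
  nsv <- integer(n)
  for (i in seq_len(n)) {
    visits <- segmentVisits(tt[hs@enclosed[[i]]], ivg)
    nsv[i] <- length(visits)
  }
  met <- hs@metrics
  nEnc <- met$nEnclosed
  met$nsv <- nsv
  met$mnlv <- nEnc / nsv
  if (!is.null(met$area)) {
    met$nsvPerArea <- ifelse(met$area > 0, nsv / met$area, NA_real_)
    met$mnlvPerArea <- ifelse(met$area > 0, met$mnlv / met$area, NA_real_)
  }
  hs@metrics <- met
  hs
}

#' Time-use record of a single hull
#'
#' @param hull list as returned by \code{\link{buildHull}}.
#' @param traj the source \code{\linkS4class{Trajectory}}.
#' @param ivg inter-visit gap (seconds).
#' @return A one-row \code{data.frame} with \code{nsv}, \code{mnlv},
#'   \code{nsvPerArea} and \code{mnlvPerArea}.
#' @export
timeUseMetrics <- function(hull, traj, ivg) {
  visits <- segmentVisits(traj@time[hull$enclosed], ivg)
  nsv <- length(visits)
  nEnc <- length(hull$enclosed)
  area <- if (nrow(hull$polygon) >= 3L) abs(ringArea(hull$polygon)) else 0
  data.frame(nsv = nsv, mnlv = nEnc / nsv,
             nsvPerArea = if (area > 0) nsv / area else NA_real_,
             mnlvPerArea = if (area > 0) (nEnc / nsv) / area else NA_real_)
}

#' Classify hulls as time-selected
#'
#' A hull is time-selected when its members (parent included) form a single
#' temporally contiguous block of fix indices: the selection regime that
#' pure time-window neighbour selection (s -> infinity) produces.  The
#' proportion of time-selected hulls is the main diagnostic for choosing s.
#'
#' @param hs a \code{\linkS4class{HullSet}}, or a list of sorted neighbour
#'   index vectors.
#' @return Logical vector, one element per hull.
#' @examples
#' isTimeSelected(list(c(10L, 11L, 12L, 13L), c(10L, 11L, 40L)))
#' @export
isTimeSelected <- function(hs) {
  nbrs <- if (is(hs, "HullSet")) hs@neighbors else hs
  vapply(nbrs, function(ix) all(diff(sort(ix)) == 1L), logical(1L))
}

#' Extract directional routes from hull elongation
#'
#' Smooths the per-hull bounding-ellipse eccentricity series with a centred
#' moving average, flags hulls whose smoothed eccentricity lies strictly
#' above the upper \code{eccPercentile} quantile, and connects maximal runs
#' of temporally consecutive flagged hulls (length >= 2) into polylines
#' through their parent points.
#'
#' @param hs a \code{\linkS4class{HullSet}} with the \code{ecc} metric.
#' @param eccPercentile upper tail fraction, in (0, 1); 0.15 keeps the top
#'   15 percent.
#' @param smoothWindow half-width of the centred moving average, in steps.
#' @return A list of route matrices (columns x, y), each with attribute
#'   \code{hulls} giving the hull indices traversed.
#' @export
directionalRoutes <- function(hs, eccPercentile = 0.15, smoothWindow = 1L) {
  stopifnot(is(hs, "HullSet"), eccPercentile > 0, eccPercentile < 1)
  met <- hs@metrics
  if (is.null(met$ecc)) stop("hull set has no eccentricity metric")
  ord <- order(met$t, met$parent)
  ecc <- met$ecc[ord]
  sm <- .movingAverage(ecc, smoothWindow)
  thr <- stats::quantile(sm, 1 - eccPercentile, na.rm = TRUE, names = FALSE)
  flagged <- !is.na(sm) & sm > thr
  parents <- hs@parents[ord]
  routes <- list()
  i <- 1L
  n <- length(flagged)
  while (i <= n) {
    if (!flagged[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && flagged[j + 1L] && parents[j + 1L] == parents[j] + 1L)
      j <- j + 1L
    if (j > i) {
      idx <- ord[i:j]
      route <- cbind(x = met$x[idx], y = met$y[idx])
      attr(route, "hulls") <- idx
      routes[[length(routes) + 1L]] <- route
    }
    i <- j + 1L
  }
  routes
}

## Centred moving average with half-width w; edges use the available part
## of the window.  NAs are dropped within each window.
.movingAverage <- function(x, w) {
  if (w <= 0L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    win <- x[max(1L, i - w):min(n, i + w)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1L))
}
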
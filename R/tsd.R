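## Time-scaled distance (TSD) and the diagnostics used to choose s.

#' Estimate the maximum theoretical velocity
#'
#' The simplest usable estimate of \code{vmax}: the maximum velocity over
#' consecutive segments, after excluding temporally isolated segments whose
#' interval exceeds \code{maxDtFactor} times the median sampling interval.
#' Zero-duration segments are excluded with a warning.
#'
#' @param traj a \code{\linkS4class{Trajectory}} with n >= 2.
#' @param maxDtFactor isolation filter threshold as a multiple of the
#'   median sampling interval.
#' @return vmax in map units per second.
#' @examples
#' tr <- trajectory(c(0, 100), c(0, 0), c(0, 50))
#' estimateVmax(tr)   # 2
#' @export
estimateVmax <- function(traj, maxDtFactor = 2) {
  stopifnot(maxDtFactor > 0)
  n <- nFixes(traj)
  if (n < 2L) stop("need at least two fixes to estimate vmax")
  dt <- diff(traj@time)
  dd <- sqrt(diff(traj@coords[, 1L])^2 + diff(traj@coords[, 2L])^2)
  if (any(dt == 0)) {
    warning(sum(dt == 0), " zero-duration segment(s) excluded from vmax")
  }
  keep <- dt > 0 & dt <= maxDtFactor * medianDt(traj)
  if (!any(keep))
    stop("all segments excluded by the isolation filter; ",
         "increase maxDtFactor")
  max(dd[keep] / dt[keep])
}

#' Time-scaled distance between fixes
#'
#' \code{sqrt(dx^2 + dy^2 + (s * vmax * dt)^2)}: Euclidean distance
#' augmented with a third axis that converts the elapsed time between two
#' fixes into map units via the maximum theoretical velocity.  With
#' \code{s = 0} this is exactly the Euclidean distance.
#'
#' @param x1,y1,t1 coordinates and time of the first fix (vectorised).
#' @param x2,y2,t2 coordinates and time of the second fix (vectorised).
#' @param params a \code{\linkS4class{TSDParams}} object.
#' @return Numeric vector of TSD values (map units).
#' @examples
#' tsdDist(0, 0, 0, 3, 4, 10, tsdParams(1, 1))   # sqrt(9 + 16 + 100)
#' @export
tsdDist <- function(x1, y1, t1, x2, y2, t2, params) {
  stopifnot(is(params, "TSDParams"))
  sqrt((x2 - x1)^2 + (y2 - y1)^2 +
       (params@s * params@vmax * (t2 - t1))^2)
}

## TSD from one parent fix to every fix of the trajectory (length-n vector).
tsdToParent <- function(traj, parent, params) {
  xy <- traj@coords; tt <- traj@time
  tsdDist(xy[parent, 1L], xy[parent, 2L], tt[parent],
          xy[, 1L], xy[, 2L], tt, params)
}

#' Space-time parity value of a pair of fixes
#'
#' The value of s at which the time term of the TSD equals the Euclidean
#' distance of the pair: \code{s* = d / (vmax * dt)}.  At \code{s = s*} the
#' TSD equals \code{sqrt(2) * d}.  Pairs with \code{dt = 0} have no parity
#' value (\code{NA}); coincident pairs with \code{dt > 0} give 0.
#'
#' @param d Euclidean distance(s) between the pair(s).
#' @param dt elapsed time(s), seconds.
#' @param vmax maximum theoretical velocity.
#' @return s* (dimensionless), \code{NA} where undefined.
#' @examples
#' parityS(5, 10, 1)   # 0.5
#' @export
parityS <- function(d, dt, vmax) {
  stopifnot(vmax > 0)
  ifelse(abs(dt) > 0, d / (vmax * abs(dt)), NA_real_)
}

#' Distribution of space-time parity values per time lag
#'
#' For each requested time lag, collects the parity value s* over all fix
#' pairs whose separation falls within half a bin width of the lag, and
#' reports quantiles.  Plotting these distributions against the lag guides
#' the choice of s for a time scale of interest.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param dtGrid numeric vector of target lags (seconds).
#' @param quantiles probabilities to report; the median is always included.
#' @param vmax maximum theoretical velocity; estimated from the data when
#'   \code{NULL}.
#' @param binWidth full width of the lag bin (seconds); defaults to the
#'   median sampling interval.
#' @return A \code{data.frame} with columns \code{dt}, \code{nPairs} and
#'   one column per quantile (\code{q0.5} etc.); empty bins give \code{NA}.
#' @export
parityDistribution <- function(traj, dtGrid,
                               quantiles = c(0.25, 0.5, 0.75),
                               vmax = NULL, binWidth = NULL) {
  stopifnot(length(dtGrid) >= 1L)
  if (is.null(vmax)) vmax <- estimateVmax(traj)
  if (is.null(binWidth)) binWidth <- medianDt(traj)
  quantiles <- sort(unique(c(0.5, quantiles)))
  tt <- traj@time; xy <- traj@coords
  n <- nFixes(traj)
  out <- matrix(NA_real_, length(dtGrid), length(quantiles))
  nPairs <- integer(length(dtGrid))
  half <- binWidth / 2
  for (g in seq_along(dtGrid)) {
    lag <- dtGrid[g]
    svals <- numeric(0)
    ## for each fix, partners within [t + lag - half, t + lag + half]
    lo <- findInterval(tt + lag - half, tt) + 1L
    hi <- findInterval(tt + lag + half, tt)
    for (i in seq_len(n)) {
      if (hi[i] < lo[i]) next
      j <- lo[i]:hi[i]
      j <- j[j != i]
      if (!length(j)) next
      d <- sqrt((xy[j, 1L] - xy[i, 1L])^2 + (xy[j, 2L] - xy[i, 2L])^2)
      sv <- parityS(d, tt[j] - tt[i], vmax)
      svals <- c(svals, sv[!is.na(sv)])
    }
    nPairs[g] <- length(svals)
    if (length(svals))
      out[g, ] <- stats::quantile(svals, quantiles, names = FALSE)
  }
  res <- data.frame(dt = dtGrid, nPairs = nPairs)
  for (k in seq_along(quantiles))
    res[[paste0("q", quantiles[k])]] <- out[, k]
  res
}

#' Ratio of the time term to the TSD, per value of s
#'
#' For each s, computes the distribution of \code{(s * vmax * dt) / TSD}
#' over consecutive fix pairs: 0 everywhere at s = 0, tending to 1 for all
#' pairs as s grows.  If a neighbour rule is supplied the mean time span of
#' each fix's neighbour set is also reported, showing how time comes to
#' dominate hull construction as s increases.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param sValues numeric vector of s values.
#' @param vmax maximum theoretical velocity; estimated when \code{NULL}.
#' @param rule optional \code{\linkS4class{NeighborRule}} for the
#'   neighbour-time-span diagnostic.
#' @return A \code{data.frame} with one row per s: quantiles of the ratio
#'   and (optionally) the mean neighbour time span (seconds).
#' @export
tsdDiagnostics <- function(traj, sValues, vmax = NULL, rule = NULL) {
  stopifnot(length(sValues) >= 1L)
  if (is.null(vmax)) vmax <- estimateVmax(traj)
  dt <- diff(traj@time)
  dd <- sqrt(diff(traj@coords[, 1L])^2 + diff(traj@coords[, 2L])^2)
  res <- data.frame(s = sValues, ratioQ25 = NA_real_, ratioMedian = NA_real_,
                    ratioQ75 = NA_real_, meanTimeSpan = NA_real_)
  for (i in seq_along(sValues)) {
    params <- tsdParams(sValues[i], vmax)
    tsd <- sqrt(dd^2 + (params@s * vmax * dt)^2)
    ratio <- ifelse(tsd > 0, (params@s * vmax * dt) / tsd,
                    0)
    q <- stats::quantile(ratio, c(0.25, 0.5, 0.75), names = FALSE)
    res$ratioQ25[i] <- q[1L]; res$ratioMedian[i] <- q[2L]
    res$ratioQ75[i] <- q[3L]
    if (!is.null(rule)) {
      nb <- selectAllNeighbors(traj, rule, params)
      spans <- vapply(nb, function(ix) diff(range(traj@time[ix])),
                      numeric(1L))
      res$meanTimeSpan[i] <- mean(spans)
    }
  }
  res
}
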
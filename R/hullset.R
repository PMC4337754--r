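## Neighbour selection, hull construction, and per-hull metrics.

#' Select TSD nearest neighbours of a parent fix
#'
#' Applies one of the k/r/a rules in time-scaled distance.  The parent is
#' always a hull member and is not counted against k.  Exact TSD ties are
#' broken by smaller absolute time difference, then by lower fix index, so
#' neighbour sets are fully deterministic.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param parent parent fix index.
#' @param rule a \code{\linkS4class{NeighborRule}}.
#' @param params a \code{\linkS4class{TSDParams}}.
#' @return Sorted integer vector of hull member indices (parent included).
#' @examples
#' tr <- trajectory(0:5, rep(0, 6), (0:5) * 3600)
#' selectNeighbors(tr, 3, neighborRule("k", 2), tsdParams(0, 1))
#' @export
selectNeighbors <- function(traj, parent, rule, params) {
  n <- nFixes(traj)
  psi <- tsdToParent(traj, parent, params)
  .selectFromPsi(psi, parent, traj@time, rule, n)
}

.selectFromPsi <- function(psi, parent, tt, rule, n) {
  absdt <- abs(tt - tt[parent])
  others <- setdiff(seq_len(n), parent)
  ord <- others[order(psi[others], absdt[others], others)]
  sel <- switch(rule@method,
    k = {
      k <- as.integer(rule@value)
      if (k >= n) stop("k (", k, ") must be smaller than the number of ",
                       "fixes (", n, ")")
      ord[seq_len(k)]
    },
    r = ord[psi[ord] <= rule@value],
    a = {
      cs <- cumsum(psi[ord])
      ord[cs <= rule@value + 1e-12 * max(rule@value, 1)]
    })
  if (rule@method != "k" && length(sel) < rule@kMin)
    sel <- ord[seq_len(min(rule@kMin, n - 1L))]
  sort(c(parent, sel))
}

#' Neighbour sets for every parent fix
#'
#' Vectorised application of \code{\link{selectNeighbors}} over all (or a
#' subset of) parents.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param rule a \code{\linkS4class{NeighborRule}}.
#' @param params a \code{\linkS4class{TSDParams}}.
#' @param parents integer parent indices (default: every fix).
#' @return List of sorted integer member vectors (parent included).
#' @export
selectAllNeighbors <- function(traj, rule, params, parents = NULL) {
  n <- nFixes(traj)
  if (is.null(parents)) parents <- seq_len(n)
  xy <- traj@coords; tt <- traj@time
  sv <- params@s * params@vmax
  lapply(parents, function(p) {
    psi <- sqrt((xy[, 1L] - xy[p, 1L])^2 + (xy[, 2L] - xy[p, 2L])^2 +
                (sv * (tt - tt[p]))^2)
    .selectFromPsi(psi, p, tt, rule, n)
  })
}

#' Build a single local convex hull
#'
#' The convex polygon over a parent fix and its neighbours, together with
#' the enclosed fixes (boundary-inclusive point-in-polygon).  Fewer than
#' three distinct non-collinear points give a zero-area polygon flagged as
#' degenerate.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param parent parent fix index.
#' @param neighbors integer vector of hull members (parent included).
#' @return A list with \code{parent}, \code{neighbors}, \code{polygon}
#'   (CCW vertex matrix), \code{enclosed} (sorted indices) and
#'   \code{degenerate}.
#' @export
buildHull <- function(traj, parent, neighbors) {
  if (!parent %in% neighbors) neighbors <- sort(c(parent, neighbors))
  if (length(neighbors) < 2L)
    stop("a hull needs at least one neighbour besides the parent")
  xy <- traj@coords[neighbors, , drop = FALSE]
  ring <- convexRing(xy)
  degenerate <- isTRUE(attr(ring, "degenerate"))
  enclosed <- .enclosedFixes(traj, ring, degenerate)
  enclosed <- sort(unique(c(enclosed, neighbors)))
  list(parent = parent, neighbors = neighbors,
       polygon = ring, enclosed = enclosed, degenerate = degenerate)
}

.enclosedFixes <- function(traj, ring, degenerate,
                           tol = 1e-9) {
  xy <- traj@coords
  scale <- max(diff(range(ring[, 1L])), diff(range(ring[, 2L])), 1)
  atol <- tol * scale
  cand <- which(xy[, 1L] >= min(ring[, 1L]) - atol &
                xy[, 1L] <= max(ring[, 1L]) + atol &
                xy[, 2L] >= min(ring[, 2L]) - atol &
                xy[, 2L] <= max(ring[, 2L]) + atol)
  if (!length(cand)) return(integer())
  inside <- pointsInConvexRing(xy[cand, 1L], xy[cand, 2L], ring,
                               boundary = TRUE, tol = atol)
  cand[inside]
}

#' Build the full set of local hulls for a trajectory
#'
#' Selects neighbours for every parent fix under the given rule, builds the
#' local convex hulls, and computes the per-hull metric table: area,
#' perimeter, perimeter-area ratio (PAR, \code{NA} for zero-area hulls),
#' bounding-ellipse eccentricity, neighbour and enclosed counts, neighbour
#' time span, and mean/sd of neighbour and enclosed-point speeds.
#'
#' @param traj a \code{\linkS4class{Trajectory}} (or
#'   \code{\linkS4class{SimTrajectory}}).
#' @param rule a \code{\linkS4class{NeighborRule}}.
#' @param params a \code{\linkS4class{TSDParams}}; when \code{NULL}, vmax
#'   is estimated from the data and \code{s} must be given.
#' @param s convenience: scaling factor used when \code{params} is NULL.
#' @param metrics character subset of \code{c("geom", "ecc", "speed")}
#'   controlling which metric groups are computed (neighbour sets, polygons
#'   and enclosed fixes are always built).  Time-use metrics are added
#'   separately by \code{\link{addTimeUse}}.
#' @param mveeTolerance tolerance of the bounding-ellipse fit.
#' @return A \code{\linkS4class{HullSet}}.
#' @examples
#' tr <- trajectory(runif(30), runif(30), (0:29) * 3600)
#' hs <- buildHulls(tr, neighborRule("k", 4), s = 0.1)
#' head(hullMetrics(hs))
#' @export
buildHulls <- function(traj, rule, params = NULL, s = NULL,
                       metrics = c("geom", "ecc", "speed"),
                       mveeTolerance = 1e-5) {
  if (is(traj, "SimTrajectory")) traj <- traj@traj
  stopifnot(is(traj, "Trajectory"), is(rule, "NeighborRule"))
  if (is.null(params)) {
    if (is.null(s)) stop("supply either params or s")
    params <- tsdParams(s, estimateVmax(traj))
  }
  n <- nFixes(traj)
  parents <- seq_len(n)
  nbrs <- selectAllNeighbors(traj, rule, params, parents)
  polygons <- vector("list", n)
  enclosed <- vector("list", n)
  degenerate <- logical(n)
  xyAll <- traj@coords
  for (i in parents) {
    ring <- convexRing(xyAll[nbrs[[i]], , drop = FALSE])
    deg <- isTRUE(attr(ring, "degenerate"))
    polygons[[i]] <- ring
    degenerate[i] <- deg
    enc <- .enclosedFixes(traj, ring, deg)
    enclosed[[i]] <- sort(unique(c(enc, nbrs[[i]])))
  }
  met <- .computeHullMetrics(traj, parents, nbrs, polygons, enclosed,
                             degenerate, metrics, mveeTolerance)
  new("HullSet", traj = traj, rule = rule, params = params,
      parents = as.integer(parents), neighbors = nbrs, polygons = polygons,
      enclosed = enclosed, degenerate = degenerate, metrics = met)
}

.computeHullMetrics <- function(traj, parents, nbrs, polygons, enclosed,
                                degenerate, metrics, mveeTolerance) {
  n <- length(parents)
  tt <- traj@time
  met <- data.frame(
    parent = as.integer(parents),
    x = traj@coords[parents, 1L],
    y = traj@coords[parents, 2L],
    t = tt[parents],
    nNeighbors = vapply(nbrs, length, integer(1L)),
    nEnclosed = vapply(enclosed, length, integer(1L)),
    timeSpan = vapply(nbrs, function(ix) diff(range(tt[ix])), numeric(1L)),
    degenerate = degenerate)
  if ("geom" %in% metrics) {
    met$area <- vapply(polygons, function(p)
      if (nrow(p) >= 3L) abs(ringArea(p)) else 0, numeric(1L))
    met$perimeter <- vapply(polygons, ringPerimeter, numeric(1L))
    met$par <- ifelse(met$area > 0, met$perimeter / met$area, NA_real_)
  }
  if ("ecc" %in% metrics) {
    met$ecc <- vapply(seq_len(n), function(i) {
      p <- polygons[[i]]
      if (nrow(p) < 2L) return(NA_real_)
      mvee(p, tolerance = mveeTolerance)$eccentricity
    }, numeric(1L))
  }
  if ("speed" %in% metrics) {
    sp <- pointSpeeds(traj)
    met$speedMeanNN <- vapply(nbrs, function(ix)
      mean(sp[ix], na.rm = TRUE), numeric(1L))
    met$speedSdNN <- vapply(nbrs, function(ix)
      stats::sd(sp[ix]), numeric(1L))
    met$speedMeanEnc <- vapply(enclosed, function(ix)
      mean(sp[ix], na.rm = TRUE), numeric(1L))
    met$speedSdEnc <- vapply(enclosed, function(ix)
      stats::sd(sp[ix]), numeric(1L))
  }
  met
}

#' Metrics of a single hull
#'
#' Convenience wrapper computing the metric record for one hull list as
#' returned by \code{\link{buildHull}}.
#'
#' @param hull list from \code{buildHull}.
#' @param traj the source \code{\linkS4class{Trajectory}}.
#' @param mveeTolerance bounding-ellipse tolerance.
#' @return One-row \code{data.frame}.
#' @export
singleHullMetrics <- function(hull, traj, mveeTolerance = 1e-5) {
  .computeHullMetrics(traj, hull$parent, list(hull$neighbors),
                      list(hull$polygon), list(hull$enclosed),
                      hull$degenerate, c("geom", "ecc", "speed"),
                      mveeTolerance)
}
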
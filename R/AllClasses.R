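#' @import methods
NULL

## ---------------------------------------------------------------------------
## Trajectory
## ---------------------------------------------------------------------------

#' Trajectory: a time-ordered sequence of relocation fixes
#'
#' Planar coordinates (map units, e.g. metres in a projected CRS) plus
#' timestamps stored as elapsed seconds.  Fixes are always kept sorted by
#' time; \code{rowIndex} records the original input row of each fix so that
#' parsing errors and exports can refer back to the source file.
#'
#' @slot coords two-column numeric matrix (x, y).
#' @slot time numeric vector of timestamps (seconds), non-decreasing.
#' @slot id character scalar identifying the individual.
#' @slot rowIndex integer vector of original input rows.
#' @export
setClass("Trajectory",
  representation(coords = "matrix", time = "numeric", id = "character",
                 rowIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 2L)
      msg <- c(msg, "coords must have two columns")
    if (nrow(object@coords) != length(object@time))
      msg <- c(msg, "coords and time lengths differ")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (any(!is.finite(object@time)))
      msg <- c(msg, "timestamps must be finite")
    if (is.unsorted(object@time))
      msg <- c(msg, "timestamps must be non-decreasing")
    if (length(object@id) != 1L)
      msg <- c(msg, "id must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Construct a Trajectory
#'
#' @param x,y numeric coordinates in a projected planar CRS (map units).
#' @param t numeric timestamps (elapsed seconds or seconds since epoch).
#' @param id individual identifier.
#' @return A \code{\linkS4class{Trajectory}}, sorted by time.
#' @examples
#' tr <- trajectory(c(0, 3, 6), c(0, 4, 8), c(0, 10, 20))
#' nFixes(tr)
#' @export
trajectory <- function(x, y, t, id = "animal") {
  stopifnot(length(x) == length(y), length(x) == length(t))
  x <- as.numeric(x); y <- as.numeric(y); t <- as.numeric(t)
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("non-finite coordinate at row ", bad[1L])
  bad <- which(!is.finite(t))
  if (length(bad))
    stop("non-finite timestamp at row ", bad[1L])
  ord <- order(t)
  new("Trajectory",
      coords = cbind(x = x[ord], y = y[ord]),
      time = t[ord], id = as.character(id), rowIndex = as.integer(ord))
}

#' @rdname nFixes
#' @export
setMethod("nFixes", "Trajectory", function(x) nrow(x@coords))

#' @rdname fixCoords
#' @export
setMethod("fixCoords", "Trajectory", function(x) x@coords)

#' @rdname fixTimes
#' @export
setMethod("fixTimes", "Trajectory", function(x) x@time)

#' @rdname medianDt
#' @export
setMethod("medianDt", "Trajectory", function(x) {
  if (nFixes(x) < 2L) stop("need at least two fixes for a sampling interval")
  stats::median(diff(x@time))
})

setMethod("show", "Trajectory", function(object) {
  n <- nFixes(object)
  cat("Trajectory of", n, "fixes, id =", object@id, "\n")
  if (n >= 2L) {
    cat("  time span:", diff(range(object@time)), "s; median dt:",
        medianDt(object), "s\n")
    bb <- apply(object@coords, 2L, range)
    cat(sprintf("  bounding box: x [%g, %g], y [%g, %g]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2]))
  }
  invisible(object)
})

#' @export
#' @method as.data.frame Trajectory
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(id = x@id, x = x@coords[, 1L], y = x@coords[, 2L],
             t = x@time, row = x@rowIndex)
}

## ---------------------------------------------------------------------------
## TSD parameters and neighbour rules
## ---------------------------------------------------------------------------

#' Time-scaled distance parameters
#'
#' The time-scaled distance between fixes i and j is
#' \code{sqrt(dx^2 + dy^2 + (s * vmax * dt)^2)}: the elapsed time is mapped
#' onto a third spatial axis through the maximum theoretical velocity
#' \code{vmax}, scaled by the dimensionless factor \code{s}.  \code{s = 0}
#' recovers plain Euclidean distance (pure space selection); large \code{s}
#' reduces neighbour selection to a time window.
#'
#' @slot s dimensionless space-time scaling factor, >= 0.
#' @slot vmax maximum theoretical velocity (map units / second), > 0.
#' @export
setClass("TSDParams", representation(s = "numeric", vmax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@s) != 1L || !is.finite(object@s) || object@s < 0)
      msg <- c(msg, "s must be a single finite value >= 0")
    if (length(object@vmax) != 1L || !is.finite(object@vmax) || object@vmax <= 0)
      msg <- c(msg, "vmax must be a single finite value > 0")
    if (length(msg)) msg else TRUE
  })

#' @param s dimensionless scaling factor (>= 0).
#' @param vmax maximum theoretical velocity in map units per second.
#' @return A \code{TSDParams} object.
#' @rdname TSDParams-class
#' @examples
#' tsdParams(0.3, 5 / 3600)
#' @export
tsdParams <- function(s, vmax) new("TSDParams", s = as.numeric(s),
                                   vmax = as.numeric(vmax))

setMethod("show", "TSDParams", function(object) {
  cat("TSD parameters: s =", object@s, ", vmax =", object@vmax,
      "map units/s\n")
  invisible(object)
})

#' Nearest-neighbour selection rule
#'
#' Three rules select the fixes joined to each parent point before hull
#' construction, all measured in time-scaled distance (TSD):
#' \describe{
#'   \item{k}{the \code{k} nearest fixes.}
#'   \item{r}{all fixes within TSD radius \code{value}.}
#'   \item{a}{the maximal prefix of fixes, sorted by ascending TSD, whose
#'     cumulative TSD is \code{<= value} (adaptive rule).}
#' }
#' For the r and a rules, if fewer than \code{kMin} neighbours result the
#' \code{kMin} nearest are taken instead.
#'
#' @slot method one of "k", "r", "a".
#' @slot value the rule parameter (count, radius, or cumulative distance).
#' @slot kMin minimum neighbour count for the r/a rules.
#' @export
setClass("NeighborRule",
  representation(method = "character", value = "numeric", kMin = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("k", "r", "a"))
      msg <- c(msg, "method must be one of 'k', 'r', 'a'")
    if (length(object@value) != 1L || !is.finite(object@value) ||
        object@value <= 0)
      msg <- c(msg, "value must be a single finite value > 0")
    if (object@method == "k" && object@value != round(object@value))
      msg <- c(msg, "k must be an integer >= 1")
    if (object@kMin < 0L)
      msg <- c(msg, "kMin must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param method "k", "r" or "a".
#' @param value the rule parameter value.
#' @param kMin minimum neighbour count (r/a rules only).
#' @return A \code{NeighborRule} object.
#' @rdname NeighborRule-class
#' @examples
#' neighborRule("k", 6)
#' neighborRule("a", 220)
#' @export
neighborRule <- function(method = c("k", "r", "a"), value, kMin = 0L) {
  method <- match.arg(method)
  new("NeighborRule", method = method, value = as.numeric(value),
      kMin = as.integer(kMin))
}

setMethod("show", "NeighborRule", function(object) {
  cat("Neighbour rule: method =", object@method, ", value =", object@value,
      if (object@method != "k") paste0(", kMin = ", object@kMin) else "", "\n")
  invisible(object)
})

## ---------------------------------------------------------------------------
## HullSet
## ---------------------------------------------------------------------------

#' A set of local convex hulls
#'
#' One hull per parent fix: the convex polygon over the parent and its
#' TSD-selected nearest neighbours, the enclosed fixes (boundary-inclusive),
#' and a per-hull metric table.  Hulls are stored in parent-time order.
#'
#' @slot traj the source \code{Trajectory}.
#' @slot rule the \code{NeighborRule} used.
#' @slot params the \code{TSDParams} used.
#' @slot parents integer vector of parent fix indices.
#' @slot neighbors list of integer vectors (hull members, parent included).
#' @slot polygons list of counter-clockwise polygon vertex matrices.
#' @slot enclosed list of integer vectors of enclosed fix indices.
#' @slot degenerate logical vector flagging zero-area hulls.
#' @slot metrics per-hull metric \code{data.frame}.
#' @export
setClass("HullSet",
  representation(traj = "Trajectory", rule = "NeighborRule",
                 params = "TSDParams", parents = "integer",
                 neighbors = "list", polygons = "list", enclosed = "list",
                 degenerate = "logical", metrics = "data.frame"),
  validity = function(object) {
    n <- length(object@parents)
    if (length(object@neighbors) != n || length(object@polygons) != n ||
        length(object@enclosed) != n || length(object@degenerate) != n)
      return("hull component lengths differ")
    TRUE
  })

#' @rdname hullMetrics
#' @export
setMethod("hullMetrics", "HullSet", function(x) x@metrics)

#' @rdname nFixes
#' @export
setMethod("nFixes", "HullSet", function(x) nFixes(x@traj))

#' Number of hulls in a HullSet
#' @param hs a \code{HullSet}.
#' @return Integer hull count.
#' @export
nHulls <- function(hs) length(hs@parents)

setMethod("show", "HullSet", function(object) {
  cat("HullSet:", nHulls(object), "hulls over", nFixes(object), "fixes\n")
  cat("  rule:", object@rule@method, "=", object@rule@value,
      "; s =", object@params@s, "; vmax =", object@params@vmax, "\n")
  cat("  degenerate hulls:", sum(object@degenerate), "\n")
  cat("  metrics:", paste(names(object@metrics), collapse = ", "), "\n")
  invisible(object)
})

## ---------------------------------------------------------------------------
## IsoplethSet
## ---------------------------------------------------------------------------

#' A nested set of isopleths
#'
#' Isopleths are cumulative unions of metric-sorted hulls.  In quantile mode
#' the isopleth at level q is the minimal prefix of the sorted hulls whose
#' union encloses at least a fraction q of all fixes; in contour mode the
#' level is a threshold on the sort metric itself.
#'
#' @slot mode "quantile" or "contour".
#' @slot sortMetric name of the hull metric used for sorting.
#' @slot decreasing whether the sort was descending.
#' @slot levels numeric level values (ascending for quantile mode).
#' @slot hullIndices list of integer vectors: the hulls merged at each level.
#' @slot geometry list per level: ring list, area, perimeter (may be empty
#'   when geometry computation was switched off).
#' @slot stats per-level statistics \code{data.frame}.
#' @slot nTotal total number of fixes in the source trajectory.
#' @export
setClass("IsoplethSet",
  representation(mode = "character", sortMetric = "character",
                 decreasing = "logical", levels = "numeric",
                 hullIndices = "list", geometry = "list",
                 stats = "data.frame", nTotal = "integer"),
  validity = function(object) {
    if (length(object@levels) != length(object@hullIndices))
      return("levels and hullIndices lengths differ")
    TRUE
  })

#' @rdname isoplethStats
#' @export
setMethod("isoplethStats", "IsoplethSet", function(x) x@stats)

setMethod("show", "IsoplethSet", function(object) {
  cat("IsoplethSet (", object@mode, " mode, sorted by ", object@sortMetric,
      ")\n", sep = "")
  print(object@stats, row.names = FALSE)
  invisible(object)
})

## ---------------------------------------------------------------------------
## Simulation classes
## ---------------------------------------------------------------------------

#' Configuration of the nine-patch movement simulation
#'
#' @slot patchCenters 9 x 2 matrix of patch centre coordinates.
#' @slot patchRadius patch radius in map units.
#' @slot schedule data.frame with columns \code{patch} and \code{steps}:
#'   the ordered visit schedule.
#' @slot stepLength constant step length in map units.
#' @slot dt sampling interval in seconds.
#' @slot bearingNoise half-width (radians) of the uniform bearing
#'   perturbation applied on transit steps.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(patchCenters = "matrix", patchRadius = "numeric",
                 schedule = "data.frame", stepLength = "numeric",
                 dt = "numeric", bearingNoise = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@patchCenters) != 9L || ncol(object@patchCenters) != 2L)
      msg <- c(msg, "patchCenters must be a 9 x 2 matrix")
    if (!all(c("patch", "steps") %in% names(object@schedule)))
      msg <- c(msg, "schedule needs columns 'patch' and 'steps'")
    if (object@patchRadius <= 0 || object@stepLength <= 0 || object@dt <= 0)
      msg <- c(msg, "patchRadius, stepLength and dt must be > 0")
    if (any(diff(object@schedule$patch) == 0))
      msg <- c(msg, "schedule must not repeat a patch consecutively")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SimConfig", function(object) {
  tot <- tapply(object@schedule$steps, object@schedule$patch, sum)
  cat("Nine-patch simulation config\n")
  cat("  patch radius:", object@patchRadius, "; step length:",
      object@stepLength, "; dt:", object@dt, "s; bearing noise: +/-",
      round(object@bearingNoise, 4), "rad; seed:", object@seed, "\n")
  cat("  schedule:", nrow(object@schedule), "visits;",
      sum(object@schedule$steps), "in-patch steps\n")
  cat("  steps per patch:", paste(names(tot), tot, sep = ":",
                                  collapse = " "), "\n")
  invisible(object)
})

#' A simulated trajectory with ground-truth labels
#'
#' @slot traj the simulated \code{Trajectory}.
#' @slot patch integer per-fix label: patch id 1..9, or 0 for transit fixes.
#' @slot visit integer per-fix schedule row (NA for transit fixes).
#' @slot config the \code{SimConfig} that produced it.
#' @export
setClass("SimTrajectory",
  representation(traj = "Trajectory", patch = "integer", visit = "integer",
                 config = "SimConfig"),
  validity = function(object) {
    if (length(object@patch) != nFixes(object@traj) ||
        length(object@visit) != nFixes(object@traj))
      return("label lengths must match the number of fixes")
    TRUE
  })

#' @rdname nFixes
#' @export
setMethod("nFixes", "SimTrajectory", function(x) nFixes(x@traj))

#' @rdname fixCoords
#' @export
setMethod("fixCoords", "SimTrajectory", function(x) fixCoords(x@traj))

#' @rdname fixTimes
#' @export
setMethod("fixTimes", "SimTrajectory", function(x) fixTimes(x@traj))

setMethod("show", "SimTrajectory", function(object) {
  cat("Simulated nine-patch trajectory:", nFixes(object), "fixes (",
      sum(object@patch == 0L), "transit )\n")
  show(object@traj)
  invisible(object)
})

#' Extract the Trajectory from a SimTrajectory
#' @param sim a \code{SimTrajectory}.
#' @return The contained \code{\linkS4class{Trajectory}}.
#' @export
simTraj <- function(sim) sim@traj

#' Ground-truth patch labels of a simulated trajectory
#' @param sim a \code{SimTrajectory}.
#' @return Integer vector: patch id per fix, 0 for transit.
#' @export
simLabels <- function(sim) sim@patch
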
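#' Number of fixes in an object
#'
#' @param x a \code{Trajectory}, \code{SimTrajectory} or \code{HullSet}.
#' @return Integer count of relocation fixes.
#' @export
setGeneric("nFixes", function(x) standardGeneric("nFixes"))

#' Fix coordinates
#'
#' @param x an object holding relocations.
#' @return A two-column numeric matrix of planar coordinates (map units).
#' @export
setGeneric("fixCoords", function(x) standardGeneric("fixCoords"))

#' Fix timestamps
#'
#' @param x an object holding relocations.
#' @return Numeric vector of timestamps in elapsed seconds.
#' @export
setGeneric("fixTimes", function(x) standardGeneric("fixTimes"))

#' Median sampling interval
#'
#' @param x an object holding relocations.
#' @return Median inter-fix interval in seconds.
#' @export
setGeneric("medianDt", function(x) standardGeneric("medianDt"))

#' Per-hull metric table
#'
#' @param x a \code{HullSet}.
#' @return A \code{data.frame} with one row per hull.
#' @export
setGeneric("hullMetrics", function(x) standardGeneric("hullMetrics"))

#' Per-level isopleth statistics
#'
#' @param x an \code{IsoplethSet}.
#' @return A \code{data.frame} with one row per isopleth level.
#' @export
setGeneric("isoplethStats", function(x) standardGeneric("isoplethStats"))

#' Export an object as GeoJSON
#'
#' @param x object to export (\code{Trajectory}, \code{HullSet},
#'   \code{IsoplethSet} or a route list).
#' @param path file to write; the feature collection is also returned
#'   invisibly as a list.
#' @param ... further arguments passed to methods.
#' @return Invisibly, the GeoJSON structure as a nested list.
#' @export
setGeneric("exportGeoJSON", function(x, path, ...) standardGeneric("exportGeoJSON"))
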
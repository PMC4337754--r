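## GeoJSON / CSV export and import.

.geojsonFC <- function(features) {
  list(type = "FeatureCollection", features = features)
}

.writeGeoJSON <- function(fc, path) {
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null", na = "null")
  invisible(fc)
}

.closeRing <- function(xy) {
  xy <- unname(as.matrix(xy))
  rbind(xy, xy[1L, , drop = FALSE])
}

## rings: list of list(xy, hole, outer) as produced by unionGeometry; build
## GeoJSON MultiPolygon coordinate nesting (outer ring first, holes after).
.ringsToMultiPolygon <- function(rings) {
  if (!length(rings)) return(list(type = "MultiPolygon", coordinates = list()))
  outers <- which(!vapply(rings, `[[`, logical(1L), "hole"))
  coords <- lapply(outers, function(o) {
    holes <- which(vapply(rings, function(r)
      isTRUE(r$hole) && identical(r$outer, o), logical(1L)))
    c(list(.closeRing(rings[[o]]$xy)),
      lapply(holes, function(h) .closeRing(rings[[h]]$xy)))
  })
  list(type = "MultiPolygon", coordinates = coords)
}

#' @describeIn exportGeoJSON points with a time attribute.
#' @export
setMethod("exportGeoJSON", "Trajectory", function(x, path, ...) {
  feats <- lapply(seq_len(nFixes(x)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(x@coords[i, 1L], x@coords[i, 2L])),
         properties = list(id = x@id, t = x@time[i], row = x@rowIndex[i]))
  })
  .writeGeoJSON(.geojsonFC(feats), path)
})

#' @describeIn exportGeoJSON one polygon feature per hull with the full
#'   metric record as attributes.
#' @export
setMethod("exportGeoJSON", "HullSet", function(x, path, ...) {
  met <- x@metrics
  feats <- lapply(seq_len(nHulls(x)), function(i) {
    ring <- x@polygons[[i]]
    geom <- if (nrow(ring) >= 3L)
      list(type = "Polygon", coordinates = list(.closeRing(ring)))
    else
      list(type = "LineString", coordinates = unname(as.matrix(ring)))
    list(type = "Feature", geometry = geom,
         properties = as.list(met[i, , drop = FALSE]))
  })
  .writeGeoJSON(.geojsonFC(feats), path)
})

#' @describeIn exportGeoJSON one MultiPolygon feature per isopleth level
#'   (holes included) with per-level statistics as attributes.
#' @export
setMethod("exportGeoJSON", "IsoplethSet", function(x, path, ...) {
  st <- x@stats
  feats <- lapply(seq_along(x@levels), function(li) {
    g <- x@geometry[[li]]
    geom <- if (!is.null(g)) .ringsToMultiPolygon(g$rings)
            else list(type = "MultiPolygon", coordinates = list())
    list(type = "Feature", geometry = geom,
         properties = as.list(st[li, , drop = FALSE]))
  })
  .writeGeoJSON(.geojsonFC(feats), path)
})

#' Export directional routes as GeoJSON LineStrings
#'
#' @param routes list of route matrices from
#'   \code{\link{directionalRoutes}}.
#' @param path output file.
#' @return Invisibly, the GeoJSON structure.
#' @export
exportRoutesGeoJSON <- function(routes, path) {
  feats <- lapply(seq_along(routes), function(i) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(as.matrix(routes[[i]]))),
         properties = list(route = i,
                           nHulls = nrow(routes[[i]])))
  })
  .writeGeoJSON(.geojsonFC(feats), path)
}

#' Read point fixes back from a GeoJSON FeatureCollection
#'
#' Inverse of the \code{Trajectory} GeoJSON export; coordinates and the
#' \code{t} property are restored.
#'
#' @param path GeoJSON file of Point features with a \code{t} property.
#' @return A \code{\linkS4class{Trajectory}}.
#' @export
readFixesGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  pts <- vapply(fc$features, function(f) {
    c(as.numeric(f$geometry$coordinates[[1L]]),
      as.numeric(f$geometry$coordinates[[2L]]),
      as.numeric(f$properties$t))
  }, numeric(3L))
  id <- fc$features[[1L]]$properties$id
  trajectory(pts[1L, ], pts[2L, ], pts[3L, ],
             id = if (is.null(id)) "animal" else id)
}

#' Write fixes to CSV
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param path output file.
#' @param labels optional per-fix label column (e.g. simulation ground
#'   truth).
#' @return Invisibly, the written \code{data.frame}.
#' @export
writeFixesCSV <- function(traj, path, labels = NULL) {
  df <- as.data.frame(traj)
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a provenance record
#'
#' Captures all run parameters, the seed and package version alongside
#' analysis outputs, as JSON.
#'
#' @param path output file.
#' @param ... named parameters to record.
#' @return Invisibly, the record as a list.
#' @export
writeProvenance <- function(path, ...) {
  rec <- list(package = "lochull",
              version = as.character(utils::packageVersion("lochull")),
              date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              parameters = list(...))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(rec)
}
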
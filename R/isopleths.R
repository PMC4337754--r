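## Sorting hulls, cumulative union, and isopleth construction.

#' Sort hulls by a metric
#'
#' Returns the permutation that orders hulls for cumulative merging.  The
#' "density" sort reproduces the classic construction: ascending hull area
#' for the k rule (small hulls = dense areas first), and descending number
#' of enclosed points with ties broken by ascending area for the r and a
#' rules.  Any other metric column sorts descending by default (override
#' with \code{decreasing}).  Zero-area hulls have undefined PAR and are
#' placed at the most-elongated end of elongation sorts; remaining ties are
#' broken by parent index, so the order is fully deterministic.
#'
#' @param hs a \code{\linkS4class{HullSet}}.
#' @param metric "density" or the name of a metric column (e.g. "ecc",
#'   "par", "nsv", "mnlv").
#' @param decreasing sort direction for non-density metrics; \code{NULL}
#'   uses the default (descending).
#' @return Integer permutation of hull indices.
#' @export
sortHulls <- function(hs, metric = "density", decreasing = NULL) {
  met <- hs@metrics
  n <- nHulls(hs)
  if (metric == "density") {
    if (is.null(met$area)) stop("density sort needs the 'area' metric")
    if (hs@rule@method == "k") {
      return(order(met$area, met$parent))
    }
    return(order(-met$nEnclosed, met$area, met$parent))
  }
  if (!metric %in% names(met))
    stop("unknown sort metric '", metric, "'; available: ",
         paste(setdiff(names(met), c("parent", "x", "y", "t")),
               collapse = ", "))
  v <- met[[metric]]
  dec <- if (is.null(decreasing)) TRUE else decreasing
  if (metric %in% c("par", "ecc")) {
    ## undefined elongation (zero-area hulls) counts as maximally elongated
    v[is.na(v)] <- Inf
  }
  key <- if (dec) -v else v
  key[is.na(key)] <- Inf   # other NAs sort last
  order(key, met$parent)
}

#' Construct isopleths by cumulative hull union
#'
#' Walks the metric-sorted hulls, maintaining the set of unique fixes
#' enclosed by the running union.  In quantile mode the isopleth at level q
#' is the minimal prefix of sorted hulls whose union encloses at least a
#' fraction q of all fixes (boundary-inclusive); the level-1 isopleth
#' encloses every fix by construction, since each fix is a member of its
#' own hull.  In contour mode the level is a threshold on the sort metric:
#' hulls with metric value at or beyond the threshold (on the side implied
#' by the sort direction) are merged.
#'
#' @param hs a \code{\linkS4class{HullSet}}.
#' @param metric sort metric passed to \code{\link{sortHulls}}.
#' @param mode "quantile" or "contour".
#' @param levels ascending quantile levels in (0, 1] or contour threshold
#'   values.
#' @param decreasing sort direction override for non-density metrics.
#' @param computeGeometry compute union polygons and their area/perimeter?
#'   Disable for large hull sets when only enclosure counts are needed.
#' @return An \code{\linkS4class{IsoplethSet}}.
#' @examples
#' tr <- trajectory(runif(40), runif(40), (0:39) * 3600)
#' hs <- buildHulls(tr, neighborRule("k", 4), s = 0)
#' iso <- isopleths(hs, levels = c(0.5, 1))
#' isoplethStats(iso)
#' @export
isopleths <- function(hs, metric = "density", mode = c("quantile", "contour"),
                      levels = c(0.1, 0.25, 0.5, 0.75, 0.95, 1),
                      decreasing = NULL, computeGeometry = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(hs, "HullSet"), length(levels) >= 1L)
  n <- nFixes(hs)
  ord <- sortHulls(hs, metric, decreasing)
  hullIdx <- vector("list", length(levels))
  if (mode == "quantile") {
    if (any(levels <= 0 | levels > 1))
      stop("quantile levels must lie in (0, 1]")
    levels <- sort(levels)
    ## running count of unique enclosed fixes along the sorted walk
    seen <- logical(n)
    countAfter <- integer(length(ord))
    cnt <- 0L
    for (i in seq_along(ord)) {
      enc <- hs@enclosed[[ord[i]]]
      newpts <- enc[!seen[enc]]
      cnt <- cnt + length(newpts)
      seen[newpts] <- TRUE
      countAfter[i] <- cnt
    }
    for (li in seq_along(levels)) {
      needed <- levels[li] * n - 1e-9
      pos <- which(countAfter >= needed)[1L]
      if (is.na(pos))
        stop("internal error: quantile level ", levels[li], " unreachable")
      hullIdx[[li]] <- ord[seq_len(pos)]
    }
  } else {
    dec <- if (is.null(decreasing)) metric != "density" else decreasing
    v <- if (metric == "density") {
      if (hs@rule@method == "k") hs@metrics$area else hs@metrics$nEnclosed
    } else hs@metrics[[metric]]
    levels <- sort(levels)
    for (li in seq_along(levels)) {
      sel <- if (dec) which(!is.na(v) & v >= levels[li])
             else     which(!is.na(v) & v <= levels[li])
      hullIdx[[li]] <- ord[ord %in% sel]
    }
  }
  geometry <- vector("list", length(levels))
  stats <- data.frame(level = levels,
                      nHulls = lengths(hullIdx),
                      pointsEnclosed = NA_integer_,
                      area = NA_real_, perimeter = NA_real_,
                      edgeAreaRatio = NA_real_)
  xy <- hs@traj@coords
  for (li in seq_along(levels)) {
    idx <- hullIdx[[li]]
    encAll <- unique(unlist(hs@enclosed[idx], use.names = FALSE))
    stats$pointsEnclosed[li] <- length(encAll)
    if (computeGeometry && length(idx)) {
      u <- unionGeometry(hs@polygons[idx], rings = TRUE)
      geometry[[li]] <- u
      stats$area[li] <- u$area
      stats$perimeter[li] <- u$perimeter
      stats$edgeAreaRatio[li] <- if (u$area > 0) u$perimeter / u$area
                                 else NA_real_
    }
  }
  dec <- if (is.null(decreasing)) metric != "density" else decreasing
  new("IsoplethSet", mode = mode, sortMetric = metric,
      decreasing = dec, levels = as.numeric(levels),
      hullIndices = hullIdx, geometry = geometry, stats = stats,
      nTotal = as.integer(n))
}

#' Hull polygons of a HullSet
#'
#' @param hs a \code{\linkS4class{HullSet}}.
#' @param which optional integer subset.
#' @return List of polygon vertex matrices.
#' @export
hullPolygons <- function(hs, which = NULL) {
  if (is.null(which)) hs@polygons else hs@polygons[which]
}
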
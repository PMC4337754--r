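## Planar geometry engine.
##
## Everything here works on plain numeric matrices: a "ring" is an n x 2
## matrix of vertices without a repeated closing vertex, counter-clockwise
## for outer boundaries.  Local hulls are convex, which the union engine
## exploits: the union of a set of convex polygons is computed exactly by
## subdividing every edge at its intersections with other polygons,
## classifying each sub-segment by a midpoint side test, and assembling
## area (Green's theorem), perimeter and boundary rings from the surviving
## sub-segments.

## ---- basic ring utilities -------------------------------------------------

#' Signed area of a polygon ring
#'
#' @param ring n x 2 vertex matrix (not closed).
#' @return Signed area: positive for counter-clockwise rings.
#' @export
ringArea <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Perimeter of a polygon ring
#'
#' @param ring n x 2 vertex matrix (not closed).
#' @return Total edge length.
#' @export
ringPerimeter <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((ring[j, 1L] - ring[, 1L])^2 + (ring[j, 2L] - ring[, 2L])^2))
}

## Convex hull ring of a point set, counter-clockwise, duplicate-free.
## Returns a matrix with < 3 rows (and attribute degenerate = TRUE) when the
## points are coincident or collinear.
convexRing <- function(xy) {
  xy <- unique(round(xy, 12L))
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2L)
  if (nrow(xy) == 1L) {
    ring <- xy
    attr(ring, "degenerate") <- TRUE
    return(ring)
  }
  h <- grDevices::chull(xy[, 1L], xy[, 2L])
  ring <- xy[h, , drop = FALSE]
  if (nrow(ring) >= 3L && abs(ringArea(ring)) > 0) {
    if (ringArea(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    attr(ring, "degenerate") <- FALSE
    return(ring)
  }
  ## collinear: reduce to extreme pair
  d2 <- (xy[, 1L] - xy[1L, 1L])^2 + (xy[, 2L] - xy[1L, 2L])^2
  far <- which.max(d2)
  proj <- (xy[, 1L] - xy[1L, 1L]) * (xy[far, 1L] - xy[1L, 1L]) +
          (xy[, 2L] - xy[1L, 2L]) * (xy[far, 2L] - xy[1L, 2L])
  ring <- xy[c(which.min(proj), which.max(proj)), , drop = FALSE]
  attr(ring, "degenerate") <- TRUE
  ring
}

## ---- point-in-polygon -----------------------------------------------------

## Vectorised point-in-convex-ring test.  `boundary = TRUE` counts points on
## the boundary as inside.  `tol` is an absolute distance tolerance.
pointsInConvexRing <- function(px, py, ring, boundary = TRUE, tol = 0) {
  m <- nrow(ring)
  if (m == 1L) {
    return(sqrt((px - ring[1L, 1L])^2 + (py - ring[1L, 2L])^2) <= tol)
  }
  if (m == 2L) {  # degenerate segment
    return(.pointsNearSegment(px, py, ring[1L, ], ring[2L, ], tol))
  }
  inside <- rep(TRUE, length(px))
  j <- c(2:m, 1L)
  orient <- if (ringArea(ring) < 0) -1 else 1   # accept either winding
  for (e in seq_len(m)) {
    ex <- ring[j[e], 1L] - ring[e, 1L]
    ey <- ring[j[e], 2L] - ring[e, 2L]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    cr <- orient * (ex * (py - ring[e, 2L]) - ey * (px - ring[e, 1L])) / len
    inside <- inside & (if (boundary) cr >= -tol else cr > tol)
    if (!any(inside)) break
  }
  inside
}

.pointsNearSegment <- function(px, py, a, b, tol) {
  dx <- b[1L] - a[1L]; dy <- b[2L] - a[2L]
  l2 <- dx^2 + dy^2
  if (l2 == 0) return(sqrt((px - a[1L])^2 + (py - a[2L])^2) <= tol)
  t <- pmin(1, pmax(0, ((px - a[1L]) * dx + (py - a[2L]) * dy) / l2))
  qx <- a[1L] + t * dx; qy <- a[2L] + t * dy
  sqrt((px - qx)^2 + (py - qy)^2) <= tol
}

#' Test points against a collection of convex polygons
#'
#' @param px,py point coordinates.
#' @param polys list of convex rings (n x 2 matrices).
#' @param boundary count boundary points as inside?
#' @param tol absolute distance tolerance for the boundary test.
#' @return Logical vector: TRUE where the point lies in at least one polygon.
#' @export
pointsInAnyPoly <- function(px, py, polys, boundary = TRUE, tol = 1e-9) {
  hit <- rep(FALSE, length(px))
  for (ring in polys) {
    idx <- which(!hit &
                 px >= min(ring[, 1L]) - tol & px <= max(ring[, 1L]) + tol &
                 py >= min(ring[, 2L]) - tol & py <= max(ring[, 2L]) + tol)
    if (!length(idx)) next
    hit[idx] <- pointsInConvexRing(px[idx], py[idx], ring,
                                   boundary = boundary, tol = tol)
  }
  hit
}

## General (possibly non-convex) ring containment by ray casting; used for
## hole assignment in union output.
.pointInRing <- function(x, y, ring) {
  n <- nrow(ring); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- ring[i, 2L]; yj <- ring[j, 2L]
    if ((yi > y) != (yj > y)) {
      xint <- ring[i, 1L] + (y - yi) / (yj - yi) * (ring[j, 1L] - ring[i, 1L])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

## ---- union of convex polygons --------------------------------------------

#' Exact union of a set of convex polygons
#'
#' Computes the union of convex rings by subdividing every polygon edge at
#' its intersections with every other polygon and keeping the sub-segments
#' whose outward side is not covered by any other polygon.  Area follows
#' from Green's theorem over the surviving directed boundary; perimeter is
#' their total length; optionally the boundary is stitched into closed
#' rings (holes traced clockwise).
#'
#' Rings with zero area (degenerate hulls) are ignored: they contribute no
#' area or perimeter to a union.
#'
#' @param polys list of convex vertex matrices (orientation is normalised
#'   internally).
#' @param rings also assemble explicit boundary rings? (needed for export,
#'   not for area/perimeter).
#' @return A list with elements \code{area}, \code{perimeter} and
#'   \code{rings}; each ring is a list with elements \code{xy} (vertex
#'   matrix), \code{hole} (logical) and \code{outer} (index of the owning
#'   outer ring, for holes).
#' @examples
#' sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
#'                                 c(y0, y0, y0 + s, y0 + s))
#' u <- unionGeometry(list(sq(0, 0, 2), sq(1, 1, 2)))
#' u$area      # 7: two 2x2 squares overlapping in a unit square
#' @export
unionGeometry <- function(polys, rings = TRUE) {
  ## keep non-degenerate rings, oriented CCW
  keep <- list()
  for (p in polys) {
    if (is.null(p) || !is.matrix(p) || nrow(p) < 3L) next
    a <- ringArea(p)
    if (abs(a) <= 0) next
    if (a < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    keep[[length(keep) + 1L]] <- unname(p)
  }
  if (!length(keep))
    return(list(area = 0, perimeter = 0, rings = list()))
  m <- length(keep)
  bb <- t(vapply(keep, function(p)
    c(min(p[, 1L]), max(p[, 1L]), min(p[, 2L]), max(p[, 2L])), numeric(4L)))
  scale <- sqrt((max(bb[, 2L]) - min(bb[, 1L]))^2 +
                (max(bb[, 4L]) - min(bb[, 3L]))^2)
  if (scale == 0) scale <- 1
  eps    <- 1e-9 * scale     # coordinate snapping / tolerance
  offs   <- 1e-8 * scale     # side-probe offset
  epsDen <- 1e-13 * scale^2  # parallelism threshold for cross products

  segA <- segB <- list(); nSeg <- 0L
  for (i in seq_len(m)) {
    P <- keep[[i]]
    np <- nrow(P)
    nxt <- c(2:np, 1L)
    cand <- which(bb[, 1L] <= bb[i, 2L] + eps & bb[, 2L] >= bb[i, 1L] - eps &
                  bb[, 3L] <= bb[i, 4L] + eps & bb[, 4L] >= bb[i, 3L] - eps)
    cand <- setdiff(cand, i)
    ## gather candidate edges once per polygon i
    if (length(cand)) {
      q1 <- do.call(rbind, lapply(cand, function(j) keep[[j]]))
      q2 <- do.call(rbind, lapply(cand, function(j) {
        Q <- keep[[j]]; Q[c(2:nrow(Q), 1L), , drop = FALSE]
      }))
    }
    for (e in seq_len(np)) {
      p1 <- P[e, ]; p2 <- P[nxt[e], ]
      d <- p2 - p1
      ts <- c(0, 1)
      if (length(cand)) {
        sx <- q2[, 1L] - q1[, 1L]; sy <- q2[, 2L] - q1[, 2L]
        wx <- q1[, 1L] - p1[1L];   wy <- q1[, 2L] - p1[2L]
        den <- d[1L] * sy - d[2L] * sx
        numT <- wx * sy - wy * sx
        numU <- wx * d[2L] - wy * d[1L]
        gen <- abs(den) > epsDen
        if (any(gen)) {
          tt <- numT[gen] / den[gen]
          uu <- numU[gen] / den[gen]
          ok <- tt > 0 & tt < 1 & uu >= -1e-9 & uu <= 1 + 1e-9
          if (any(ok)) ts <- c(ts, tt[ok])
        }
        col <- !gen & abs(numU) <= epsDen
        if (any(col)) {
          l2 <- sum(d^2)
          t1 <- (wx[col] * d[1L] + wy[col] * d[2L]) / l2
          t2 <- t1 + (sx[col] * d[1L] + sy[col] * d[2L]) / l2
          tc <- c(t1, t2)
          tc <- tc[tc > 0 & tc < 1]
          if (length(tc)) ts <- c(ts, tc)
        }
      }
      ts <- sort(ts)
      ts <- ts[c(TRUE, diff(ts) > 1e-12)]
      nint <- length(ts) - 1L
      tm <- (ts[-1L] + ts[-length(ts)]) / 2
      mx <- p1[1L] + tm * d[1L]; my <- p1[2L] + tm * d[2L]
      len <- sqrt(sum(d^2))
      nx <- d[2L] / len; ny <- -d[1L] / len   # right normal (outward for CCW)
      qx <- mx + offs * nx; qy <- my + offs * ny
      covered <- rep(FALSE, nint)
      for (j in cand) {
        idx <- which(!covered)
        if (!length(idx)) break
        covered[idx] <- pointsInConvexRing(qx[idx], qy[idx], keep[[j]],
                                           boundary = TRUE, tol = eps)
      }
      kpt <- which(!covered)
      for (sgi in kpt) {
        nSeg <- nSeg + 1L
        segA[[nSeg]] <- c(p1[1L] + ts[sgi] * d[1L], p1[2L] + ts[sgi] * d[2L])
        segB[[nSeg]] <- c(p1[1L] + ts[sgi + 1L] * d[1L],
                          p1[2L] + ts[sgi + 1L] * d[2L])
      }
    }
  }
  if (!nSeg) return(list(area = 0, perimeter = 0, rings = list()))
  A <- do.call(rbind, segA); B <- do.call(rbind, segB)
  ## drop duplicated collinear sub-segments (same geometry and direction)
  key <- paste(round(A[, 1L] / eps), round(A[, 2L] / eps),
               round(B[, 1L] / eps), round(B[, 2L] / eps))
  dup <- duplicated(key)
  A <- A[!dup, , drop = FALSE]; B <- B[!dup, , drop = FALSE]
  segLen <- sqrt((B[, 1L] - A[, 1L])^2 + (B[, 2L] - A[, 2L])^2)
  nz <- segLen > eps
  A <- A[nz, , drop = FALSE]; B <- B[nz, , drop = FALSE]
  segLen <- segLen[nz]
  area <- sum(A[, 1L] * B[, 2L] - B[, 1L] * A[, 2L]) / 2
  out <- list(area = max(area, 0), perimeter = sum(segLen), rings = list())
  if (rings && nrow(A)) out$rings <- .stitchRings(A, B, eps)
  out
}

## Assemble directed boundary sub-segments into closed rings.  Interior lies
## on the left of every segment, so outer rings come out counter-clockwise
## and holes clockwise.  At junction nodes the continuation is the first
## outgoing segment met when rotating clockwise from the reversed incoming
## direction, which keeps pinched faces separate.
.stitchRings <- function(A, B, eps) {
  keyOf <- function(M) paste(round(M[, 1L] / eps), round(M[, 2L] / eps))
  ka <- keyOf(A); kb <- keyOf(B)
  outMap <- split(seq_along(ka), ka)
  used <- rep(FALSE, nrow(A))
  dirAng <- atan2(B[, 2L] - A[, 2L], B[, 1L] - A[, 1L])
  rings <- list()
  for (s0 in seq_len(nrow(A))) {
    if (used[s0]) next
    path <- s0
    used[s0] <- TRUE
    cur <- s0
    repeat {
      nodeKey <- kb[cur]
      if (nodeKey == ka[s0] && length(path) >= 2L) break
      outs <- outMap[[nodeKey]]
      outs <- outs[!used[outs]]
      if (!length(outs)) {
        if (nodeKey == ka[s0]) break
        path <- NULL; break   # open chain (numerical artefact); discard
      }
      if (length(outs) == 1L) nxt <- outs
      else {
        rev_in <- dirAng[cur] + pi
        delta <- (rev_in - dirAng[outs]) %% (2 * pi)
        delta[delta < 1e-12] <- 2 * pi
        nxt <- outs[which.min(delta)]
      }
      used[nxt] <- TRUE
      path <- c(path, nxt)
      cur <- nxt
    }
    if (is.null(path) || length(path) < 3L) next
    xy <- A[path, , drop = FALSE]
    a <- ringArea(xy)
    rings[[length(rings) + 1L]] <- list(xy = xy, hole = a < 0, area = a)
  }
  ## assign each hole to the smallest containing outer ring
  if (length(rings)) {
    outer <- which(!vapply(rings, `[[`, logical(1L), "hole"))
    for (i in seq_along(rings)) {
      if (!rings[[i]]$hole) { rings[[i]]$outer <- NA_integer_; next }
      pt <- rings[[i]]$xy[1L, ]
      containing <- outer[vapply(outer, function(o)
        .pointInRing(pt[1L], pt[2L], rings[[o]]$xy), logical(1L))]
      rings[[i]]$outer <- if (length(containing)) {
        containing[which.min(vapply(containing, function(o)
          rings[[o]]$area, numeric(1L)))]
      } else NA_integer_
    }
  }
  rings
}

## ---- raster coverage helpers ----------------------------------------------

#' Rasterised coverage mask of a polygon set
#'
#' A regular-grid approximation of the region covered by a set of convex
#' polygons, used for fast area comparisons between large hull unions and
#' reference regions.
#'
#' @param polys list of convex rings.
#' @param bbox optional c(xmin, xmax, ymin, ymax); defaults to the polygon
#'   extent.
#' @param n number of cells along the longer axis.
#' @return List with \code{xs}, \code{ys} (cell centres), logical matrix
#'   \code{mask} (rows = x cells) and scalar \code{cellArea}.
#' @export
coverageMask <- function(polys, bbox = NULL, n = 400L) {
  if (is.null(bbox)) {
    allxy <- do.call(rbind, polys)
    bbox <- c(range(allxy[, 1L]), range(allxy[, 2L]))
  }
  w <- bbox[2L] - bbox[1L]; h <- bbox[4L] - bbox[3L]
  cell <- max(w, h) / n
  xs <- seq(bbox[1L] + cell / 2, bbox[2L], by = cell)
  ys <- seq(bbox[3L] + cell / 2, bbox[4L], by = cell)
  mask <- matrix(FALSE, length(xs), length(ys))
  for (ring in polys) {
    if (is.null(ring) || nrow(ring) < 3L) next
    ix <- which(xs >= min(ring[, 1L]) - cell & xs <= max(ring[, 1L]) + cell)
    iy <- which(ys >= min(ring[, 2L]) - cell & ys <= max(ring[, 2L]) + cell)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    inside <- pointsInConvexRing(px, py, ring, boundary = TRUE)
    mask[ix, iy] <- mask[ix, iy] | matrix(inside, length(ix), length(iy))
  }
  list(xs = xs, ys = ys, mask = mask, cellArea = cell^2)
}

#' Fraction of one polygon set's area lying outside a reference region
#'
#' @param polys polygon set of interest (list of convex rings).
#' @param refPolys reference region (list of convex rings).
#' @param n grid resolution along the longer axis.
#' @return Fraction in [0, 1] of the rasterised area of \code{polys} not
#'   covered by \code{refPolys}.
#' @export
fractionOutside <- function(polys, refPolys, n = 400L) {
  allxy <- do.call(rbind, c(polys, refPolys))
  bbox <- c(range(allxy[, 1L]), range(allxy[, 2L]))
  mA <- coverageMask(polys, bbox = bbox, n = n)
  mR <- coverageMask(refPolys, bbox = bbox, n = n)
  tot <- sum(mA$mask)
  if (tot == 0) return(0)
  sum(mA$mask & !mR$mask) / tot
}
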
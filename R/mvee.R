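#' Minimum-volume enclosing ellipse
#'
#' Computes the minimum-area ellipse enclosing a planar point set with the
#' Khachiyan dual-ascent algorithm, and reports its eccentricity
#' \code{sqrt(1 - (b/a)^2)} (0 for a circle, approaching 1 for a line).
#' Eccentricity of the ellipse bounding a local hull is one of the two
#' hull-elongation (movement phase) metrics.
#'
#' Degenerate inputs are handled explicitly: exactly collinear points have
#' no proper enclosing ellipse, so the minor semi-axis is floored at a tiny
#' positive value (\code{minorFloor}) and the eccentricity tends to 1;
#' fully coincident points yield \code{NA} eccentricity.
#'
#' @param points n x 2 coordinate matrix (n >= 2).
#' @param tolerance convergence tolerance of the dual ascent.
#' @param maxIter iteration cap.
#' @param minorFloor lower bound for the minor semi-axis (map units),
#'   applied to degenerate (collinear) point sets.
#' @return A list with \code{center} (length-2), \code{axes} (semi-axis
#'   lengths, major first), \code{angle} (radians, major-axis orientation),
#'   \code{eccentricity}, and \code{degenerate} flag.  For coincident
#'   points all geometric elements are \code{NA}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' mvee(cbind(cos(th), sin(th)))$eccentricity   # ~ 0
#' @export
mvee <- function(points, tolerance = 1e-5, maxIter = 1000L,
                 minorFloor = 1e-9) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 2L,
            tolerance > 0)
  P <- unique(round(points, 12L))
  n <- nrow(P)
  if (n == 1L) {
    return(list(center = c(NA_real_, NA_real_), axes = c(NA_real_, NA_real_),
                angle = NA_real_, eccentricity = NA_real_, degenerate = TRUE))
  }
  d <- 2
  px <- P[, 1L]; py <- P[, 2L]
  ## centre/scale for conditioning of the 3x3 system
  cx <- mean(px); cy <- mean(py)
  sc <- max(stats::sd(px), stats::sd(py), 1e-300)
  zx <- (px - cx) / sc; zy <- (py - cy) / sc
  u <- rep(1 / n, n)
  for (it in seq_len(maxIter)) {
    ## X = Q diag(u) Q' for Q = rbind(zx, zy, 1); inverted in closed form
    sxx <- sum(u * zx * zx); sxy <- sum(u * zx * zy); sx <- sum(u * zx)
    syy <- sum(u * zy * zy); sy <- sum(u * zy)
    a11 <- syy - sy * sy; a12 <- sx * sy - sxy; a13 <- sxy * sy - syy * sx
    a22 <- sxx - sx * sx; a23 <- sxy * sx - sxx * sy
    a33 <- sxx * syy - sxy * sxy
    det <- sxx * a11 + sxy * a12 + sx * a13
    if (!is.finite(det) || abs(det) < 1e-14) break  # collinear input
    M <- (a11 * zx * zx + 2 * a12 * zx * zy + a22 * zy * zy +
          2 * a13 * zx + 2 * a23 * zy + a33) / det
    j <- which.max(M)
    maxM <- M[j]
    step <- (maxM - d - 1) / ((d + 1) * (maxM - 1))
    if (!is.finite(step) || step <= 0) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
    if (maxM - d - 1 < tolerance * (d + 1)) break
  }
  center <- as.numeric(t(P) %*% u)
  S <- t(P) %*% (u * P) - tcrossprod(center)
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  degenerate <- lam[2L] <= (minorFloor^2) / d
  ## ellipse matrix A = inv(S)/d; semi-axes = sqrt(d * lam)
  axes <- sqrt(d * lam)
  axes[axes < minorFloor] <- minorFloor
  ## guarantee containment: inflate by the worst point's Mahalanobis radius
  V <- ev$vectors
  Pc <- sweep(P, 2L, center)
  z <- Pc %*% V
  r2 <- (z[, 1L] / axes[1L])^2 + (z[, 2L] / axes[2L])^2
  worst <- sqrt(max(r2))
  if (is.finite(worst) && worst > 1) axes <- axes * worst
  ecc <- sqrt(max(0, 1 - (axes[2L] / axes[1L])^2))
  list(center = center, axes = axes,
       angle = atan2(V[2L, 1L], V[1L, 1L]),
       eccentricity = ecc, degenerate = degenerate)
}

#' Points of an ellipse boundary
#'
#' Utility to materialise an ellipse returned by \code{\link{mvee}} as a
#' polygon ring, e.g. for plotting or export.
#'
#' @param ell list as returned by \code{mvee}.
#' @param n number of boundary vertices.
#' @return n x 2 matrix of boundary points (counter-clockwise).
#' @export
ellipseRing <- function(ell, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ca <- cos(ell$angle); sa <- sin(ell$angle)
  x <- ell$axes[1L] * cos(th); y <- ell$axes[2L] * sin(th)
  cbind(ell$center[1L] + ca * x - sa * y,
        ell$center[2L] + sa * x + ca * y)
}
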
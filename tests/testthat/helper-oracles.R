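# Independent reference implementations used as oracles.  These are kept
# deliberately naive and separate from the package internals: brute-force
# all-pairs TSD neighbour selection, a from-scratch plain (time-free) local
# convex hull construction, exact minimum enclosing circles, and a coarse
# direct minimiser for enclosing ellipses.

# Random test trajectory: clustered planar walk with regular-ish sampling.
randomTrajectory <- function(n, seed, irregular = FALSE) {
  set.seed(seed)
  x <- cumsum(stats::rnorm(n, sd = 3))
  y <- cumsum(stats::rnorm(n, sd = 3))
  t <- if (irregular) cumsum(stats::rexp(n, rate = 1 / 3600))
       else (seq_len(n) - 1) * 3600
  trajectory(x, y, t)
}

# Brute-force TSD from fix i to all fixes.
oracleTSD <- function(traj, i, s, vmax) {
  xy <- fixCoords(traj); tt <- fixTimes(traj)
  sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2 +
       (s * vmax * (tt - tt[i]))^2)
}

# Brute-force neighbour selection: full sort of all pairs with the documented
# tie rule (psi, |dt|, index), then apply the k/r/a rule literally.
oracleNeighbors <- function(traj, parent, method, value, s, vmax, kMin = 0) {
  psi <- oracleTSD(traj, parent, s, vmax)
  tt <- fixTimes(traj)
  n <- nFixes(traj)
  others <- setdiff(seq_len(n), parent)
  ord <- others[order(psi[others], abs(tt[others] - tt[parent]), others)]
  sel <- if (method == "k") {
    ord[seq_len(value)]
  } else if (method == "r") {
    ord[psi[ord] <= value]
  } else {
    keep <- integer(0); tot <- 0
    for (j in ord) {
      tot <- tot + psi[j]
      if (tot > value + 1e-12 * max(value, 1)) break
      keep <- c(keep, j)
    }
    keep
  }
  if (method != "k" && length(sel) < kMin)
    sel <- ord[seq_len(min(kMin, n - 1))]
  sort(c(parent, sel))
}

# Independent plain LoCoH (s = 0, k-method density isopleths): spatial
# k-nearest neighbours, convex hulls, ascending-area sort, minimal prefix
# enclosing >= q * n fixes.  Returns the hull polygons of each level prefix.
oraclePlainLocoh <- function(traj, k, levels) {
  xy <- fixCoords(traj); tt <- fixTimes(traj); n <- nFixes(traj)
  hulls <- vector("list", n)
  areas <- numeric(n)
  enclosed <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[others], abs(tt[others] - tt[i]), others)]
    memb <- sort(c(i, ord[seq_len(k)]))
    pts <- unique(round(xy[memb, , drop = FALSE], 12))
    h <- grDevices::chull(pts)
    ring <- pts[h, , drop = FALSE]
    ## orient CCW
    sa <- 0
    if (nrow(ring) >= 3) {
      j2 <- c(2:nrow(ring), 1)
      sa <- sum(ring[, 1] * ring[j2, 2] - ring[j2, 1] * ring[, 2]) / 2
      if (sa < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    }
    hulls[[i]] <- ring
    areas[i] <- abs(sa)
    inside <- rep(FALSE, n)
    if (nrow(ring) >= 3) {
      j2 <- c(2:nrow(ring), 1)
      inside <- rep(TRUE, n)
      for (e in seq_len(nrow(ring))) {
        ex <- ring[j2[e], 1] - ring[e, 1]; ey <- ring[j2[e], 2] - ring[e, 2]
        cr <- ex * (xy[, 2] - ring[e, 2]) - ey * (xy[, 1] - ring[e, 1])
        inside <- inside & (cr >= -1e-9 * (abs(ex) + abs(ey)))
      }
    }
    enclosed[[i]] <- sort(unique(c(which(inside), memb)))
  }
  ord <- order(areas, seq_len(n))
  seen <- rep(FALSE, n); cnt <- integer(n)
  run <- 0
  for (i in seq_along(ord)) {
    enc <- enclosed[[ord[i]]]
    run <- run + sum(!seen[enc])
    seen[enc] <- TRUE
    cnt[i] <- run
  }
  lapply(levels, function(q) {
    pos <- which(cnt >= q * n - 1e-9)[1]
    list(hullIdx = ord[seq_len(pos)], polys = hulls[ord[seq_len(pos)]])
  })
}

# Exact minimum enclosing circle by brute force over all pairs and triples.
oracleMinCircle <- function(P) {
  n <- nrow(P)
  contains <- function(c, r) all(sqrt((P[, 1] - c[1])^2 +
                                      (P[, 2] - c[2])^2) <= r + 1e-9)
  best <- list(r = Inf)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    c <- (P[i, ] + P[j, ]) / 2
    r <- sqrt(sum((P[i, ] - P[j, ])^2)) / 2
    if (r < best$r && contains(c, r)) best <- list(c = c, r = r)
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      A <- P[i, ]; B <- P[j, ]; C <- P[k, ]
      d <- 2 * (A[1] * (B[2] - C[2]) + B[1] * (C[2] - A[2]) +
                C[1] * (A[2] - B[2]))
      if (abs(d) < 1e-12) next
      ux <- ((sum(A^2)) * (B[2] - C[2]) + (sum(B^2)) * (C[2] - A[2]) +
             (sum(C^2)) * (A[2] - B[2])) / d
      uy <- ((sum(A^2)) * (C[1] - B[1]) + (sum(B^2)) * (A[1] - C[1]) +
             (sum(C^2)) * (B[1] - A[1])) / d
      r <- sqrt((A[1] - ux)^2 + (A[2] - uy)^2)
      if (r < best$r && contains(c(ux, uy), r)) best <- list(c = c(ux, uy), r = r)
    }
  }
  best
}

# Coarse brute-force minimum-area enclosing ellipse: for each orientation
# theta and aspect ratio rho on a grid, rotate by -theta and scale y by rho;
# the minimal enclosing ellipse with that shape corresponds to the minimum
# enclosing circle of the transformed points.  Area = pi * r^2 / rho.
oracleMinEllipseArea <- function(P, nTheta = 60, rhos = NULL) {
  if (is.null(rhos)) rhos <- exp(seq(log(0.05), log(1), length.out = 60))
  best <- Inf
  for (th in seq(0, pi, length.out = nTheta + 1)[-(nTheta + 1)]) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    Q <- P %*% R
    for (rho in rhos) {
      Qs <- cbind(Q[, 1], Q[, 2] / rho)
      mc <- oracleMinCircle(Qs)
      area <- pi * mc$r^2 * rho
      if (area < best) best <- area
    }
  }
  best
}
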
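## Nine-patch movement simulation with ground-truth labels.
##
## A single individual moves among nine circular resource patches on a 3x3
## grid with a constant step length and a fixed 1-h sampling interval.
## Within a patch it takes uniform-random-bearing steps, bouncing back off
## the patch border; to leave, it moves directionally to the patch exit
## area and then transits toward the next scheduled patch with a uniform
## bearing perturbation of +/- pi/6 per step.  The visit schedule gives
## every patch roughly 240 in-patch fixes while grading the number of
## visits per patch from 1 (one 240-h stay) up to 12 (brief 20-h stops in
## the centre patch, which is crossed on the reused "highway" between the
## west and east mid-row patches).

#' Default configuration of the nine-patch simulation
#'
#' Patch geometry and the visit schedule are constructed deterministically:
#' patches of radius 20 map units on a 3x3 grid with 100-unit spacing, step
#' length 5, 1-h sampling, bearing noise +/- pi/6.  Per-patch visit
#' durations are constant within a patch and grade from a single 240-step
#' stay to twelve 20-step stops in the centre patch; every patch totals
#' 240 +/- 10 percent in-patch fixes and single-visit residencies span 20
#' to 240 steps.  The centre patch is visited more often than any other,
#' always en route between the west and east mid-row patches (the
#' "highway").
#'
#' @param seed integer RNG seed stored in the configuration.
#' @param patchRadius,spacing,stepLength map-unit geometry parameters.
#' @param dt sampling interval in seconds.
#' @param bearingNoise half-width of the uniform transit bearing
#'   perturbation (radians).
#' @return A \code{\linkS4class{SimConfig}}.
#' @examples
#' cfg <- defaultSimConfig(seed = 1)
#' tapply(cfg@schedule$steps, cfg@schedule$patch, sum)
#' @export
defaultSimConfig <- function(seed = 1L, patchRadius = 20, spacing = 100,
                             stepLength = 5, dt = 3600,
                             bearingNoise = pi / 6) {
  centers <- as.matrix(expand.grid(x = c(-1, 0, 1) * spacing,
                                   y = c(1, 0, -1) * spacing))[, c(1, 2)]
  ## row-major ids: 1..3 top row, 4..6 middle (5 = centre), 7..9 bottom
  centers <- cbind(x = rep(c(-1, 0, 1) * spacing, 3),
                   y = rep(c(1, 0, -1) * spacing, each = 3))
  schedule <- .buildSchedule()
  new("SimConfig", patchCenters = centers, patchRadius = patchRadius,
      schedule = schedule, stepLength = stepLength, dt = dt,
      bearingNoise = bearingNoise, seed = as.integer(seed))
}

## Per-visit residency (steps) per patch: a gradient of revisitation from a
## single 240-step stay to twelve 20-step pass-throughs of the centre (5).
.visitSteps <- c("1" = 240L, "2" = 60L, "3" = 80L, "4" = 48L, "5" = 20L,
                 "6" = 48L, "7" = 80L, "8" = 60L, "9" = 120L)

## Fixed deterministic visit order.  Every centre-patch visit is a crossing
## sandwiched between two outer patches: the 4-5-6 "highway" is traversed
## five times; other crossings (2-5-8, 3-5-7, 1-5-9, 9-5-3) spread the
## centre's entries over all sides.  Spare visits keep same-patch returns
## well separated.  No patch repeats consecutively and no straight transit
## between consecutive patches passes through a third patch.
.visitOrder <- c(4L, 5L, 6L, 7L, 2L, 5L, 8L, 6L, 5L, 4L, 8L, 3L, 5L, 7L,
                 4L, 5L, 6L, 8L, 5L, 2L, 6L, 5L, 4L, 1L, 5L, 9L, 4L,
                 5L, 6L, 2L, 7L, 5L, 3L, 2L, 5L, 8L, 9L, 5L, 3L)

.buildSchedule <- function() {
  data.frame(patch = .visitOrder,
             steps = unname(.visitSteps[as.character(.visitOrder)]))
}

#' Run the nine-patch movement simulation
#'
#' Deterministic given the seed stored in the configuration.  Every step
#' has the configured path length and sampling interval; within-patch
#' steps bounce back off the patch border (billiard reflection, so the
#' recorded displacement is shorter than the step length only on bounced
#' steps), and transit steps head to the patch exit area and then to the
#' next patch with a bounded bearing perturbation.  The caller's RNG state
#' is left untouched.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return A \code{\linkS4class{SimTrajectory}} with per-fix ground-truth
#'   labels (patch id, 0 for transit; schedule row for in-patch fixes).
#' @examples
#' sim <- simulateTrajectory(defaultSimConfig(seed = 7))
#' table(simLabels(sim) == 0)
#' @export
simulateTrajectory <- function(config) {
  stopifnot(is(config, "SimConfig"))
  withSeed(config@seed, .simulateImpl(config))
}

.simulateImpl <- function(config) {
  ctr <- config@patchCenters
  R <- config@patchRadius
  L <- config@stepLength
  noise <- config@bearingNoise
  sched <- config@schedule
  gridCentroid <- colMeans(ctr)
  xs <- ys <- numeric(0)
  patchLab <- visitLab <- integer(0)
  pos <- ctr[sched$patch[1L], ]

  record <- function(p, patch, visit) {
    xs[length(xs) + 1L] <<- p[1L]
    ys[length(ys) + 1L] <<- p[2L]
    patchLab[length(patchLab) + 1L] <<- patch
    visitLab[length(visitLab) + 1L] <<- visit
  }
  stepToward <- function(pos, target) {
    b <- atan2(target[2L] - pos[2L], target[1L] - pos[1L]) +
      stats::runif(1L, -noise, noise)
    pos + L * c(cos(b), sin(b))
  }

  for (v in seq_len(nrow(sched))) {
    patch <- sched$patch[v]
    pc <- ctr[patch, ]
    if (v > 1L) {
      ## exit area of the previous patch: toward the grid centroid for
      ## outer patches, toward the destination for the centre patch
      prev <- sched$patch[v - 1L]
      pcPrev <- ctr[prev, ]
      exitDir <- if (prev == 5L) pc - pcPrev else gridCentroid - pcPrev
      if (sqrt(sum(exitDir^2)) < 1e-9) exitDir <- pc - pcPrev
      exitPt <- pcPrev + R * exitDir / sqrt(sum(exitDir^2))
      cap <- 10L * ceiling(sqrt(sum((exitPt - pos)^2)) / L) + 10L
      nstep <- 0L
      while (sqrt(sum((exitPt - pos)^2)) > L) {
        pos <- stepToward(pos, exitPt)
        record(pos, 0L, NA_integer_)
        nstep <- nstep + 1L
        if (nstep > cap) stop("simulation error: exit area unreachable")
      }
      ## transit to the next patch
      cap <- 10L * ceiling(sqrt(sum((pc - pos)^2)) / L) + 10L
      nstep <- 0L
      while (sqrt(sum((pc - pos)^2)) > R) {
        pos <- stepToward(pos, pc)
        record(pos, 0L, NA_integer_)
        nstep <- nstep + 1L
        if (nstep > cap) stop("simulation error: patch ", patch,
                              " unreachable")
      }
    }
    ## within-patch random walk, bouncing back off the border: the step's
    ## path (constant length) is folded at the circular wall like a
    ## billiard ball, so the walk lingers in the border zone and its
    ## stationary density stays uniform over the patch disk
    for (st in seq_len(sched$steps[v])) {
      b <- stats::runif(1L, 0, 2 * pi)
      pos <- .billiardStep(pos, c(cos(b), sin(b)), L, pc, R)
      record(pos, patch, v)
    }
  }
  n <- length(xs)
  traj <- trajectory(xs, ys, (seq_len(n) - 1L) * config@dt, id = "sim")
  new("SimTrajectory", traj = traj, patch = patchLab, visit = visitLab,
      config = config)
}

#' Write / read a simulation configuration
#'
#' Round-trippable plain-text (JSON) serialisation of a
#' \code{\linkS4class{SimConfig}}, so that a simulated study can be
#' reproduced from its config file alone.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param path file to write to / read from.
#' @return \code{writeSimConfig} invisibly returns the path;
#'   \code{readSimConfig} returns the reconstructed
#'   \code{\linkS4class{SimConfig}}.
#' @export
writeSimConfig <- function(config, path) {
  jsonlite::write_json(
    list(patchCenters = unname(config@patchCenters),
         patchRadius = config@patchRadius,
         schedule = config@schedule,
         stepLength = config@stepLength,
         dt = config@dt,
         bearingNoise = config@bearingNoise,
         seed = config@seed),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctr <- matrix(as.numeric(unlist(x$patchCenters)), ncol = 2L,
                byrow = is.list(x$patchCenters))
  if (!is.list(x$patchCenters)) ctr <- as.matrix(x$patchCenters)
  colnames(ctr) <- c("x", "y")
  new("SimConfig", patchCenters = ctr, patchRadius = x$patchRadius,
      schedule = as.data.frame(x$schedule), stepLength = x$stepLength,
      dt = x$dt, bearingNoise = x$bearingNoise, seed = as.integer(x$seed))
}

## One billiard step of path length L inside the disk (pc, R): travel along
## direction v, reflecting specularly at the wall until the length is used.
.billiardStep <- function(pos, v, L, pc, R) {
  rem <- L
  for (fold in seq_len(100L)) {
    w <- pos - pc
    bv <- sum(w * v)
    disc <- bv * bv - (sum(w * w) - R * R)
    tWall <- if (disc <= 0) Inf else -bv + sqrt(disc)
    if (tWall >= rem) return(pos + rem * v)
    if (tWall > 0) {
      pos <- pos + tWall * v
      rem <- rem - tWall
    }
    u <- (pos - pc) / max(sqrt(sum((pos - pc)^2)), 1e-12)
    v <- v - 2 * sum(v * u) * u
  }
  pos   # pathological chatter: stop where we are (length slightly short)
}

#' Ground-truth patch-and-corridor region of a simulation
#'
#' The region the simulated individual is designed to use: the nine patch
#' disks plus straight corridors between the centres of every pair of
#' patches adjacent in the schedule, buffered by \code{margin}.  Used to
#' quantify how much isopleth area spills outside the structure that
#' generated the data.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param margin buffer width in map units added around patches and
#'   corridors.  The default, 1.5 step lengths, is about the 95th
#'   percentile of the lateral wander of a transit walk with +/- pi/6
#'   bearing noise: wide enough to contain designed transit use, tight
#'   enough that spurious bridging between temporally distinct routes
#'   registers as spill.
#' @return A list of convex rings (circle polygons and corridor
#'   rectangles) suitable for \code{\link{fractionOutside}}.
#' @export
truthRegion <- function(config, margin = 1.5 * config@stepLength) {
  R <- config@patchRadius + margin
  th <- seq(0, 2 * pi, length.out = 49L)[-49L]
  polys <- lapply(seq_len(9L), function(i)
    cbind(config@patchCenters[i, 1L] + R * cos(th),
          config@patchCenters[i, 2L] + R * sin(th)))
  trans <- unique(t(apply(cbind(config@schedule$patch[-nrow(config@schedule)],
                                config@schedule$patch[-1L]), 1L, sort)))
  for (k in seq_len(nrow(trans))) {
    A <- config@patchCenters[trans[k, 1L], ]
    B <- config@patchCenters[trans[k, 2L], ]
    d <- B - A; len <- sqrt(sum(d^2))
    nvec <- c(-d[2L], d[1L]) / len * margin
    polys[[length(polys) + 1L]] <-
      rbind(A + nvec, A - nvec, B - nvec, B + nvec)[c(2, 3, 4, 1), ]
  }
  polys
}

#' Distance from points to the nearest patch border
#'
#' For fixes inside a patch, the (positive) distance to that patch's
#' border; used to examine where long-duration hulls concentrate.
#'
#' @param sim a \code{\linkS4class{SimTrajectory}}.
#' @return Numeric vector: for in-patch fixes,
#'   \code{patchRadius - distance to patch centre}; \code{NA} for transit
#'   fixes.
#' @export
distToPatchBorder <- function(sim) {
  cfg <- sim@config
  xy <- fixCoords(sim)
  out <- rep(NA_real_, nFixes(sim))
  for (p in 1:9) {
    idx <- which(sim@patch == p)
    if (!length(idx)) next
    d <- sqrt((xy[idx, 1L] - cfg@patchCenters[p, 1L])^2 +
              (xy[idx, 2L] - cfg@patchCenters[p, 2L])^2)
    out[idx] <- cfg@patchRadius - d
  }
  out
}
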
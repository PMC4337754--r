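## Parameter-selection diagnostics: minimum-proportion-inclusion bounds,
## proportion of time-selected hulls as a function of s, and isopleth area
## / edge-to-area curves for hole-covering and crossover screening.

#' Minimum proportion inclusion (MPI) bound
#'
#' The MPI rule sets a lower bound for the neighbour-rule parameter as the
#' value at which a proportion \code{p} of fixes appears as a nearest
#' neighbour in at least one hull with at least \code{n} neighbours.  For
#' the k rule the bound is simply \code{k = n}; for the a rule it is
#' computed exactly from the finite set of cumulative-TSD breakpoints: for
#' every (fix, parent) pair the minimal a that makes the fix a neighbour of
#' that parent in a hull of >= n neighbours is a prefix sum of the
#' parent's sorted TSD values, and the bound is the p-quantile of each
#' fix's minimum over parents.  Setting \code{n >= 10} turns the same
#' computation into the customary upper-bound probe.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param params a \code{\linkS4class{TSDParams}}.
#' @param method "k" or "a".
#' @param n required neighbour count of the probe hulls (default 2).
#' @param p required proportion of fixes in [0, 1] (default 1).
#' @return The bound: an integer for the k rule, a cumulative TSD value
#'   for the a rule.  With \code{p = 0} the requirement is vacuous and the
#'   smallest breakpoint is returned.
#' @examples
#' tr <- trajectory(runif(20), runif(20), (0:19) * 3600)
#' mpiBound(tr, tsdParams(0, 1), "k", n = 2)   # 2
#' @export
mpiBound <- function(traj, params, method = c("k", "a"), n = 2L, p = 1) {
  method <- match.arg(method)
  stopifnot(n >= 1L, p >= 0, p <= 1)
  if (method == "k") return(as.integer(n))
  nf <- nFixes(traj)
  if (nf < n + 1L) stop("trajectory too small for n = ", n)
  tt <- traj@time
  minA <- rep(Inf, nf)
  for (parent in seq_len(nf)) {
    psi <- tsdToParent(traj, parent, params)
    absdt <- abs(tt - tt[parent])
    others <- setdiff(seq_len(nf), parent)
    ord <- others[order(psi[others], absdt[others], others)]
    cs <- cumsum(psi[ord])
    pos <- seq_along(ord)
    ## fix ord[j] joins parent's hull (with >= n members) at a = cs[max(j, n)]
    aNeeded <- cs[pmax(pos, n)]
    minA[ord] <- pmin(minA[ord], aNeeded)
  }
  if (p == 0) return(min(minA))
  needed <- ceiling(p * nf - 1e-9)
  sort(minA)[needed]
}

#' Proportion of time-selected hulls across s
#'
#' For each value of s, builds the neighbour set of every parent under the
#' given rule and reports the fraction of hulls whose members form a
#' single temporally contiguous block.  The curve rises from the purely
#' spatial regime (s = 0) towards 1 in the time-window limit and is the
#' primary guide for selecting s.
#'
#' @param traj a \code{\linkS4class{Trajectory}} or
#'   \code{\linkS4class{SimTrajectory}}.
#' @param rule a \code{\linkS4class{NeighborRule}}.
#' @param sValues numeric vector of s values.
#' @param vmax maximum theoretical velocity; estimated when \code{NULL}.
#' @return A \code{data.frame} with columns \code{s} and
#'   \code{propTimeSelected}.
#' @export
ptshCurve <- function(traj, rule, sValues, vmax = NULL) {
  if (is(traj, "SimTrajectory")) traj <- simTraj(traj)
  stopifnot(length(sValues) >= 1L)
  if (is.null(vmax)) vmax <- estimateVmax(traj)
  prop <- vapply(sValues, function(s) {
    nb <- selectAllNeighbors(traj, rule, tsdParams(s, vmax))
    mean(isTimeSelected(nb))
  }, numeric(1L))
  data.frame(s = sValues, propTimeSelected = prop)
}

#' Isopleth area and edge-to-area curves over a-values
#'
#' For each candidate a, builds the full hull set, constructs density
#' isopleths, and tabulates per-level area and edge-to-area ratio.  Sharp
#' jumps in the area curves signal crossover errors (spurious bridging of
#' unused areas); local minima of the edge-to-area ratio at low isopleth
#' levels indicate hole filling in core areas.  The function supplies the
#' curves and a largest-jump flag; the final choice of a remains an
#' analyst decision.
#'
#' @param traj a \code{\linkS4class{Trajectory}} or
#'   \code{\linkS4class{SimTrajectory}}.
#' @param s scaling factor.
#' @param aValues ascending candidate a values.
#' @param levels quantile isopleth levels.
#' @param vmax maximum theoretical velocity; estimated when \code{NULL}.
#' @param kMin minimum neighbour count for the a rule.
#' @return A \code{data.frame} with columns \code{a}, \code{level},
#'   \code{area}, \code{perimeter}, \code{edgeAreaRatio},
#'   \code{pointsEnclosed}.
#' @seealso \code{\link{largestAreaJump}}
#' @export
isoplethAreaCurves <- function(traj, s, aValues,
                               levels = c(0.25, 0.5, 0.75, 0.95),
                               vmax = NULL, kMin = 2L) {
  if (is(traj, "SimTrajectory")) traj <- simTraj(traj)
  stopifnot(all(diff(aValues) > 0))
  if (is.null(vmax)) vmax <- estimateVmax(traj)
  params <- tsdParams(s, vmax)
  out <- list()
  for (a in aValues) {
    hs <- buildHulls(traj, neighborRule("a", a, kMin = kMin),
                     params = params, metrics = "geom")
    iso <- isopleths(hs, levels = levels)
    st <- isoplethStats(iso)
    st$a <- a
    out[[length(out) + 1L]] <-
      st[c("a", "level", "area", "perimeter", "edgeAreaRatio",
           "pointsEnclosed")]
  }
  do.call(rbind, out)
}

#' Locate the largest single-step area jump in an isopleth area curve
#'
#' @param curves output of \code{\link{isoplethAreaCurves}}.
#' @param level which isopleth level to scan.
#' @return A list with \code{a} (the value at which the jump lands),
#'   \code{jump} (the area increase) and \code{from} (the preceding a).
#' @export
largestAreaJump <- function(curves, level = 0.5) {
  sub <- curves[abs(curves$level - level) < 1e-9, ]
  if (nrow(sub) < 2L) stop("need at least two a values at level ", level)
  sub <- sub[order(sub$a), ]
  d <- diff(sub$area)
  j <- which.max(d)
  list(a = sub$a[j + 1L], jump = d[j], from = sub$a[j])
}
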
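# Fabricate a HullSet with prescribed polygons and enclosed sets, bypassing
# neighbour selection, to exercise the sorting/merging contracts directly.
fabricateHullSet <- function(polys, enclosed, nFix, method = "k") {
  n <- length(polys)
  tr <- trajectory(seq_len(nFix), rep(0, nFix), seq_len(nFix) * 3600)
  areas <- vapply(polys, function(p) abs(ringArea(p)), numeric(1))
  met <- data.frame(parent = seq_len(n), x = 0, y = 0, t = seq_len(n),
                    nNeighbors = lengths(enclosed),
                    nEnclosed = lengths(enclosed),
                    timeSpan = 0, degenerate = areas == 0,
                    area = areas,
                    perimeter = vapply(polys, ringPerimeter, numeric(1)))
  met$par <- ifelse(met$area > 0, met$perimeter / met$area, NA_real_)
  new("HullSet", traj = tr, rule = neighborRule(method, 3),
      params = tsdParams(0, 1), parents = seq_len(n),
      neighbors = enclosed, polygons = polys, enclosed = enclosed,
      degenerate = areas == 0, metrics = met)
}

sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                c(y0, y0, y0 + s, y0 + s))

test_that("density sorting: ascending area for k, enclosed-then-area for r/a", {
  polys <- list(sq(0, 0, sqrt(3)), sq(0, 0, 1), sq(0, 0, sqrt(2)))
  hsK <- fabricateHullSet(polys, list(1L, 2L, 3L), 3L, "k")
  expect_equal(sortHulls(hsK, "density"), c(2L, 3L, 1L))   # areas 1, 2, 3

  ## a-method: nEnclosed {5, 5, 2}, areas {4, 1, 9}: ties by ascending area
  polysA <- list(sq(0, 0, 2), sq(0, 0, 1), sq(0, 0, 3))
  encA <- list(1:5, 1:5, 1:2)
  hsA <- fabricateHullSet(polysA, encA, 5L, "a")
  expect_equal(sortHulls(hsA, "density"), c(2L, 1L, 3L))

  ## identical metric values fall back to parent order (stable)
  polysT <- list(sq(0, 0, 1), sq(5, 5, 1), sq(9, 9, 1))
  hsT <- fabricateHullSet(polysT, list(1L, 2L, 3L), 3L, "k")
  expect_equal(sortHulls(hsT, "density"), 1:3)

  ## unknown metric is a configuration error
  expect_error(sortHulls(hsK, "swagger"), "unknown sort metric")

  ## zero-area hulls sort to the most-elongated end of a PAR sort
  polysZ <- list(sq(0, 0, 1), rbind(c(0, 0), c(1, 1)), sq(2, 2, 2))
  hsZ <- fabricateHullSet(polysZ, list(1L, 2L, 3L), 3L, "k")
  expect_equal(sortHulls(hsZ, "par")[1], 2L)
})

test_that("quantile merging takes the minimal prefix and reaches 100%", {
  ## one hull enclosing all fixes
  hs1 <- fabricateHullSet(list(sq(0, 0, 10)), list(1:4), 4L)
  iso1 <- isopleths(hs1, levels = 1)
  expect_equal(isoplethStats(iso1)$pointsEnclosed, 4L)
  expect_equal(isoplethStats(iso1)$area, 100)

  ## two disjoint hulls, each enclosing half the fixes
  hs2 <- fabricateHullSet(list(sq(0, 0, 1), sq(10, 10, 2)),
                          list(1:2, 3:4), 4L)
  iso2 <- isopleths(hs2, levels = c(0.5, 1))
  st <- isoplethStats(iso2)
  expect_equal(st$nHulls, c(1L, 2L))
  expect_equal(st$pointsEnclosed, c(2L, 4L))
  expect_equal(st$area, c(1, 5))          # second level is a multipolygon
  expect_length(iso2@geometry[[2]]$rings, 2L)

  ## stats table: edge-to-area ratio of a square of side L is 4 / L
  expect_equal(st$edgeAreaRatio[1], 4)
})

test_that("isopleths nest and enclosure counts are monotone", {
  tr <- randomTrajectory(70, seed = 17)
  hs <- buildHulls(tr, neighborRule("k", 5), s = 0.1)
  iso <- isopleths(hs, levels = c(0.25, 0.5, 0.75, 1))
  st <- isoplethStats(iso)
  expect_true(all(diff(st$pointsEnclosed) >= 0))
  expect_true(all(diff(st$area) >= -1e-9))
  expect_equal(st$pointsEnclosed[4], nFixes(tr))
  ## hull prefixes are nested, hence the unions are nested sets
  for (li in 2:4)
    expect_true(all(iso@hullIndices[[li - 1]] %in% iso@hullIndices[[li]]))
  ## spot-check spatial nesting: points inside level i lie inside level i+1
  set.seed(1)
  xy <- fixCoords(tr)
  px <- runif(500, min(xy[, 1]), max(xy[, 1]))
  py <- runif(500, min(xy[, 2]), max(xy[, 2]))
  for (li in 2:4) {
    inLo <- pointsInAnyPoly(px, py, hullPolygons(hs, iso@hullIndices[[li - 1]]))
    inHi <- pointsInAnyPoly(px, py, hullPolygons(hs, iso@hullIndices[[li]]))
    expect_true(all(inHi[inLo]))
  }
})

test_that("the quantile stopping rule is minimal", {
  tr <- randomTrajectory(60, seed = 18)
  hs <- buildHulls(tr, neighborRule("k", 4), s = 0.05)
  n <- nFixes(tr)
  iso <- isopleths(hs, levels = c(0.3, 0.6, 0.9), computeGeometry = FALSE)
  for (li in seq_along(iso@levels)) {
    idx <- iso@hullIndices[[li]]
    cnt <- length(unique(unlist(hs@enclosed[idx])))
    expect_gte(cnt, ceiling(iso@levels[li] * n))
    ## dropping the last merged hull falls below the requirement
    cntPrev <- length(unique(unlist(hs@enclosed[idx[-length(idx)]])))
    expect_lt(cntPrev, iso@levels[li] * n)
  }
})

test_that("contour mode thresholds the sort metric", {
  polys <- list(sq(0, 0, 1), sq(2, 0, 1), sq(4, 0, 1))
  hs <- fabricateHullSet(polys, list(1L, 2L, 3L), 3L)
  hs@metrics$nsv <- c(5, 2, 9)
  iso <- isopleths(hs, metric = "nsv", mode = "contour", levels = c(3, 8))
  expect_equal(sort(iso@hullIndices[[1]]), c(1L, 3L))   # nsv >= 3
  expect_equal(iso@hullIndices[[2]], 3L)                # nsv >= 8
})

test_that("union stats include interior ring length for multipart shapes", {
  ## square annulus built from four overlapping rectangles: the hole's
  ## perimeter counts
  rect <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0),
                                         c(y0, y0, y1, y1))
  frame <- list(rect(0, 0, 3, 1), rect(2, 0, 3, 3),
                rect(0, 2, 3, 3), rect(0, 0, 1, 3))
  u <- unionGeometry(frame)
  expect_equal(u$area, 8)
  expect_equal(u$perimeter, 16)   # 12 outer + 4 inner
  holes <- vapply(u$rings, `[[`, logical(1), "hole")
  expect_equal(sum(holes), 1L)
  expect_equal(abs(u$rings[[which(holes)]]$area), 1)
})

test_that("unions of convex polygons are exact on known configurations", {
  expect_equal(unionGeometry(list(sq(0, 0, 2), sq(1, 1, 2)))$area, 7)
  expect_equal(unionGeometry(list(sq(0, 0, 2), sq(1, 1, 2)))$perimeter, 12)
  ## identical duplicates collapse
  expect_equal(unionGeometry(list(sq(0, 0, 2), sq(0, 0, 2)))$area, 4)
  expect_equal(unionGeometry(list(sq(0, 0, 2), sq(0, 0, 2)))$perimeter, 8)
  ## containment: inner polygon contributes nothing
  expect_equal(unionGeometry(list(sq(0, 0, 4), sq(1, 1, 1)))$area, 16)
  ## corner contact keeps two faces
  u <- unionGeometry(list(sq(0, 0, 1), sq(1, 1, 1)))
  expect_equal(u$area, 2)
  expect_length(u$rings, 2L)
  ## degenerate rings are ignored
  expect_equal(unionGeometry(list(sq(0, 0, 1), rbind(c(5, 5), c(6, 6))))$area, 1)
  ## Monte-Carlo cross-check on random overlapping hull sets
  set.seed(31)
  for (rep in 1:5) {
    polys <- lapply(1:12, function(i) {
      ctr <- runif(2, 0, 10)
      pts <- sweep(matrix(rnorm(12), 6, 2), 2, ctr, "+")
      pts[grDevices::chull(pts), ]
    })
    u <- unionGeometry(polys, rings = FALSE)
    px <- runif(40000, -5, 15); py <- runif(40000, -5, 15)
    mc <- mean(pointsInAnyPoly(px, py, polys)) * 400
    expect_equal(u$area, mc, tolerance = 0.05)
  }
})
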
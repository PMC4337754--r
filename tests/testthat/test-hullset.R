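test_that("the a rule takes the maximal cumulative-TSD prefix (ties included)", {
  ## fixes at TSD 1, 2, 3, 4 from the parent (s = 0, far apart in time)
  tr <- trajectory(c(0, 1, 2, 3, 4), rep(0, 5),
                   c(0, 1e5, 2e5, 3e5, 4e5))
  sel <- selectNeighbors(tr, 1, neighborRule("a", 6), tsdParams(0, 1))
  expect_equal(sel, c(1L, 2L, 3L, 4L))   # 1+2+3 = 6 <= 6; adding 4 exceeds
  sel2 <- selectNeighbors(tr, 1, neighborRule("a", 5.99), tsdParams(0, 1))
  expect_equal(sel2, c(1L, 2L, 3L))
})

test_that("k selection at s = 0 is spatial kNN; large s is a time window", {
  tr <- randomTrajectory(40, seed = 2)
  vmax <- estimateVmax(tr)
  ## s = 0: compare against plain spatial distances
  xy <- fixCoords(tr)
  for (p in c(1L, 17L, 40L)) {
    sel <- selectNeighbors(tr, p, neighborRule("k", 5), tsdParams(0, vmax))
    d <- sqrt((xy[, 1] - xy[p, 1])^2 + (xy[, 2] - xy[p, 2])^2)
    expect_equal(sel, sort(c(p, order(d)[2:6])))
  }
  ## very large s: the k temporally nearest fixes
  for (p in c(1L, 20L, 40L)) {
    sel <- selectNeighbors(tr, p, neighborRule("k", 4),
                           tsdParams(1e9, vmax))
    win <- sort(abs(fixTimes(tr) - fixTimes(tr)[p]), index.return = TRUE)
    expect_equal(sel, sort(win$ix[1:5]))
  }
  ## k >= n is a parameter error
  expect_error(selectNeighbors(tr, 1, neighborRule("k", 40),
                               tsdParams(0, vmax)), "smaller")
})

test_that("neighbour selection agrees with the brute-force oracle", {
  for (seed in 1:4) {
    tr <- randomTrajectory(60, seed = seed, irregular = seed %% 2 == 0)
    vmax <- estimateVmax(tr, maxDtFactor = 10)
    for (s in c(0, 0.3, 10)) {
      params <- tsdParams(s, vmax)
      nbK <- selectAllNeighbors(tr, neighborRule("k", 5), params)
      nbR <- selectAllNeighbors(tr, neighborRule("r", 8), params)
      nbA <- selectAllNeighbors(tr, neighborRule("a", 30), params)
      for (p in seq_len(nFixes(tr))) {
        expect_identical(nbK[[p]],
                         oracleNeighbors(tr, p, "k", 5, s, vmax))
        expect_identical(nbR[[p]],
                         oracleNeighbors(tr, p, "r", 8, s, vmax))
        expect_identical(nbA[[p]],
                         oracleNeighbors(tr, p, "a", 30, s, vmax))
      }
    }
  }
})

test_that("neighbour sets are nested in the rule parameter", {
  tr <- randomTrajectory(80, seed = 13)
  params <- tsdParams(0.2, estimateVmax(tr))
  for (p in c(3L, 40L, 78L)) {
    prev <- NULL
    for (k in c(2, 4, 8, 16)) {
      cur <- selectNeighbors(tr, p, neighborRule("k", k), params)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
    prev <- NULL
    for (r in c(2, 5, 10, 50)) {
      cur <- selectNeighbors(tr, p, neighborRule("r", r, kMin = 0), params)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
    prev <- NULL
    for (a in c(5, 20, 80, 400)) {
      cur <- selectNeighbors(tr, p, neighborRule("a", a, kMin = 0), params)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("kMin tops up sparse r/a selections", {
  tr <- trajectory(c(0, 100, 200, 300), rep(0, 4), (0:3) * 3600)
  params <- tsdParams(0, 1)
  ## radius 1 catches nothing; kMin = 2 forces the two nearest
  sel <- selectNeighbors(tr, 1, neighborRule("r", 1, kMin = 2), params)
  expect_equal(sel, c(1L, 2L, 3L))
})

test_that("single hull construction: polygons, enclosure, degeneracy", {
  ## parent + two non-collinear neighbours -> triangle
  tr <- trajectory(c(0, 1, 0, 5), c(0, 0, 1, 5), c(0, 1, 2, 3))
  h <- buildHull(tr, 1, c(1L, 2L, 3L))
  expect_equal(nrow(h$polygon), 3L)
  expect_false(h$degenerate)
  expect_equal(h$enclosed, c(1L, 2L, 3L))

  ## square of fixes with the parent inside: parent is enclosed
  tr2 <- trajectory(c(0, 2, 2, 0, 1), c(0, 0, 2, 2, 1), 0:4)
  h2 <- buildHull(tr2, 5, 1:5)
  expect_equal(nrow(h2$polygon), 4L)   # the square; interior point dropped
  expect_equal(abs(ringArea(h2$polygon)), 4)
  expect_true(5L %in% h2$enclosed)

  ## collinear members: zero area, degenerate flag, enclosed on segment
  tr3 <- trajectory(c(0, 1, 2, 0.5), c(0, 1, 2, 0.5), 0:3)
  h3 <- buildHull(tr3, 1, c(1L, 2L, 3L))
  expect_true(h3$degenerate)
  expect_true(4L %in% h3$enclosed)   # lies exactly on the segment
})

test_that("hull metrics: geometry, time span, speed statistics", {
  ## unit right triangle at constant speed
  tr <- trajectory(c(0, 1, 0, 10), c(0, 0, 1, 10), c(0, 3600, 7200, 10800))
  hs <- buildHulls(tr, neighborRule("k", 2), params = tsdParams(0, 1))
  met <- hullMetrics(hs)
  expect_equal(met$area[1], 0.5)
  expect_equal(met$perimeter[1], 2 + sqrt(2))
  expect_equal(met$par[1], (2 + sqrt(2)) / 0.5)
  expect_equal(met$timeSpan[1], 7200)
  expect_equal(met$nNeighbors, rep(3L, 4))

  ## constant-speed neighbours have sd 0
  trC <- trajectory((0:5) * 3, rep(0, 6), (0:5) * 3600)
  hsC <- buildHulls(trC, neighborRule("k", 2), params = tsdParams(0, 1))
  metC <- hullMetrics(hsC)
  expect_equal(metC$speedSdNN[2], 0)
  expect_equal(metC$speedMeanNN[2], 3 / 3600)

  ## degenerate hulls: area 0, PAR missing
  expect_true(all(metC$degenerate))
  expect_equal(metC$area, rep(0, 6))
  expect_true(all(is.na(metC$par)))
})

test_that("enclosed sets contain hull members and area grows with neighbours", {
  tr <- randomTrajectory(50, seed = 4)
  hs <- buildHulls(tr, neighborRule("k", 5), s = 0.1)
  for (i in seq_len(nHulls(hs))) {
    expect_true(all(hs@neighbors[[i]] %in% hs@enclosed[[i]]))
  }
  ## area is monotone when the neighbour set is extended
  params <- tsdParams(0.1, estimateVmax(tr))
  for (p in c(5L, 25L)) {
    prevArea <- -1
    for (k in c(3, 6, 12)) {
      nb <- selectNeighbors(tr, p, neighborRule("k", k), params)
      h <- buildHull(tr, p, nb)
      a <- abs(ringArea(h$polygon))
      expect_gte(a, prevArea - 1e-12)
      prevArea <- a
    }
  }
})
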
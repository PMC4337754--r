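test_that("vmax is the maximum filtered segment velocity", {
  ## regular 1-h sampling, constant 5-unit steps
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  tr <- trajectory(cumsum(5 * cos(th)), cumsum(5 * sin(th)),
                   (0:9) * 3600)
  expect_equal(estimateVmax(tr), 5 / 3600)

  ## a temporally isolated fast segment is excluded by the filter
  tr2 <- trajectory(c(0, 1, 2, 500, 501), c(0, 0, 0, 0, 0),
                    c(0, 1, 2, 12, 13) * 3600)
  ## median dt = 1 h; the 10-h segment (speed 498/10h) is dropped
  expect_equal(estimateVmax(tr2), 1 / 3600)
  ## with a permissive factor it dominates
  expect_equal(estimateVmax(tr2, maxDtFactor = 20), 498 / (10 * 3600))

  ## two-fix trajectory
  tr3 <- trajectory(c(0, 100), c(0, 0), c(0, 50))
  expect_equal(estimateVmax(tr3), 2)

  ## everything filtered out is an error
  tr4 <- trajectory(c(0, 1, 2), c(0, 0, 0), c(0, 1, 100))
  expect_error(estimateVmax(tr4, maxDtFactor = 1e-3), "maxDtFactor")
})

test_that("TSD reduces to Euclidean distance at s = 0 and obeys its bounds", {
  set.seed(42)
  n <- 10000
  x1 <- runif(n, -1e3, 1e3); y1 <- runif(n, -1e3, 1e3)
  x2 <- runif(n, -1e3, 1e3); y2 <- runif(n, -1e3, 1e3)
  t1 <- runif(n, 0, 1e6); t2 <- runif(n, 0, 1e6)
  d <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  expect_identical(tsdDist(x1, y1, t1, x2, y2, t2, tsdParams(0, 1)), d)

  ## hand-evaluated example
  expect_equal(tsdDist(0, 0, 0, 3, 4, 10, tsdParams(1, 1)), sqrt(125))
  expect_equal(tsdDist(2, 3, 100, 2, 3, 100, tsdParams(2, 0.5)), 0)

  ## bounds and monotonicity in s over a grid
  sGrid <- c(0, 0.01, 0.1, 0.5, 1, 5, 100)
  vmax <- 0.02
  prev <- rep(0, n)
  for (s in sGrid) {
    psi <- tsdDist(x1, y1, t1, x2, y2, t2, tsdParams(s, vmax))
    tterm <- s * vmax * abs(t2 - t1)
    expect_true(all(psi >= pmax(d, tterm) - 1e-9))
    expect_true(all(psi <= d + tterm + 1e-9))
    expect_true(all(psi >= prev - 1e-9))
    prev <- psi
  }
})

test_that("parity s equalises the spatial and time terms", {
  expect_equal(parityS(5, 10, 1), 0.5)
  expect_equal(parityS(0, 10, 1), 0)
  expect_true(is.na(parityS(5, 0, 1)))

  ## tsd at s = s* equals sqrt(2) * d, to 1e-9 relative
  set.seed(7)
  for (i in 1:200) {
    p <- runif(6, -100, 100)
    t1 <- runif(1, 0, 1e5); t2 <- t1 + runif(1, 1, 1e5)
    vmax <- runif(1, 0.001, 10)
    d <- sqrt((p[3] - p[1])^2 + (p[4] - p[2])^2)
    sStar <- parityS(d, t2 - t1, vmax)
    psi <- tsdDist(p[1], p[2], t1, p[3], p[4], t2, tsdParams(sStar, vmax))
    expect_equal(psi, sqrt(2) * d, tolerance = 1e-9)
  }
})

test_that("parity distributions collapse for constant-velocity motion", {
  ## straight line at constant speed: s* = v / vmax at every lag
  v <- 2
  tr <- trajectory((0:49) * v * 3600, rep(0, 50), (0:49) * 3600)
  pd <- parityDistribution(tr, dtGrid = c(1, 3, 5) * 3600, vmax = 2 * v)
  for (col in c("q0.25", "q0.5", "q0.75"))
    expect_equal(pd[[col]], rep(0.5, 3), tolerance = 1e-12)

  ## single lag over 3 fixes enumerates the available pairs
  tr3 <- trajectory(c(0, 3, 7), c(0, 0, 0), c(0, 3600, 7200))
  pd3 <- parityDistribution(tr3, dtGrid = 3600, vmax = 1,
                            quantiles = 0.5, binWidth = 600)
  sv <- c(3 / 3600, 4 / 3600)   # the two adjacent pairs at lag 1 h
  expect_equal(pd3$nPairs, 2L)
  expect_equal(pd3$q0.5, median(sv))

  ## requesting only the median yields exactly one quantile column
  expect_equal(grep("^q", names(pd3), value = TRUE), "q0.5")

  ## empty bin gives NA
  pdE <- parityDistribution(tr3, dtGrid = 100 * 3600, vmax = 1,
                            binWidth = 600)
  expect_true(is.na(pdE$q0.5))
})

test_that("time-to-TSD ratio diagnostics behave at the s limits", {
  tr <- randomTrajectory(60, seed = 5)
  dg <- tsdDiagnostics(tr, sValues = c(0, 1e6))
  expect_equal(dg$ratioMedian[1], 0)
  expect_equal(dg$ratioQ25[1], 0)
  expect_gt(dg$ratioMedian[2], 0.999999)

  ## a pair with equal spatial and time terms has ratio 1/sqrt(2); with all
  ## segments identical the quantiles all equal that value
  trEq <- trajectory((0:10) * 5, rep(0, 11), (0:10) * 3600)
  vmax <- 5 / 3600
  dgEq <- tsdDiagnostics(trEq, sValues = 1, vmax = vmax)
  expect_equal(dgEq$ratioMedian, 1 / sqrt(2), tolerance = 1e-12)

  ## neighbour time span grows with s when a rule is supplied
  dg2 <- tsdDiagnostics(tr, sValues = c(0.01, 100),
                        rule = neighborRule("k", 4))
  expect_true(dg2$meanTimeSpan[2] <= dg2$meanTimeSpan[1] * 1.5)
  expect_false(any(is.na(dg2$meanTimeSpan)))
})
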
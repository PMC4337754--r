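test_that("the default schedule honours every design constraint", {
  cfg <- defaultSimConfig(seed = 1)
  sched <- cfg@schedule
  tot <- tapply(sched$steps, sched$patch, sum)
  ## roughly 240 in-patch fixes per patch (within +/- 10%)
  expect_true(all(tot >= 216 & tot <= 264))
  ## single-visit residency spans 20 to 240 steps (hours)
  expect_equal(min(sched$steps), 20L)
  expect_equal(max(sched$steps), 240L)
  ## the centre patch is visited more often than any other
  visits <- table(sched$patch)
  expect_equal(names(which.max(visits)), "5")
  expect_gt(visits[["5"]], max(visits[names(visits) != "5"]))
  ## no patch repeats consecutively
  expect_true(all(diff(sched$patch) != 0))
  ## every centre visit is flanked by two outer patches (a crossing)
  ctr <- which(sched$patch == 5L)
  expect_true(all(ctr > 1 & ctr < nrow(sched)))
  expect_true(all(sched$patch[ctr - 1] != 5 & sched$patch[ctr + 1] != 5))
})

test_that("simulation is deterministic and respects step geometry", {
  cfg <- defaultSimConfig(seed = 42)
  sim1 <- simulateTrajectory(cfg)
  sim2 <- simulateTrajectory(cfg)
  expect_identical(fixCoords(sim1), fixCoords(sim2))
  expect_identical(simLabels(sim1), simLabels(sim2))
  ## a different seed gives a different realisation
  sim3 <- simulateTrajectory(defaultSimConfig(seed = 43))
  expect_false(isTRUE(all.equal(fixCoords(sim1)[1:50, ],
                                fixCoords(sim3)[1:50, ])))

  tr <- simTraj(sim1)
  ## constant sampling interval
  expect_equal(unique(diff(fixTimes(tr))), cfg@dt)
  ## step displacement never exceeds the step length; transit steps equal
  ## it exactly, in-patch steps fall short only when bounced at the border
  d <- sqrt(diff(fixCoords(tr)[, 1])^2 + diff(fixCoords(tr)[, 2])^2)
  expect_true(all(d <= cfg@stepLength + 1e-9))
  lab <- simLabels(sim1)
  transitSeg <- lab[-1] == 0L & lab[-nFixes(sim1)] == 0L
  expect_equal(unique(round(d[transitSeg], 9)), cfg@stepLength)
  ## most steps are not bounced
  expect_gt(mean(abs(d - cfg@stepLength) < 1e-9), 0.7)

  ## empirical vmax equals step length / dt exactly
  expect_equal(estimateVmax(tr), cfg@stepLength / cfg@dt)
})

test_that("ground-truth labels are geometrically consistent", {
  cfg <- defaultSimConfig(seed = 7)
  sim <- simulateTrajectory(cfg)
  xy <- fixCoords(sim)
  lab <- simLabels(sim)
  ## every in-patch fix lies within its patch disk
  for (p in 1:9) {
    idx <- which(lab == p)
    expect_gt(length(idx), 200)
    d <- sqrt((xy[idx, 1] - cfg@patchCenters[p, 1])^2 +
              (xy[idx, 2] - cfg@patchCenters[p, 2])^2)
    expect_true(all(d <= cfg@patchRadius + 1e-9))
  }
  ## labels partition the fixes
  expect_true(all(lab %in% 0:9))
  expect_equal(sum(lab > 0), sum(cfg@schedule$steps))
  ## visit ids line up with patch labels
  expect_true(all(is.na(sim@visit[lab == 0])))
  expect_true(all(cfg@schedule$patch[sim@visit[lab > 0]] == lab[lab > 0]))

  ## border-distance helper: NA on transit, within [0, R] inside
  db <- distToPatchBorder(sim)
  expect_true(all(is.na(db[lab == 0])))
  expect_true(all(db[lab > 0] >= -1e-9 & db[lab > 0] <= cfg@patchRadius))
})

test_that("billiard bounce-back keeps the walk in the disk, uniformly", {
  set.seed(5)
  pos <- c(0, 0)
  R <- 10; L <- 3
  keep <- matrix(NA_real_, 4000, 2)
  for (i in 1:4000) {
    b <- runif(1, 0, 2 * pi)
    pos <- lochull:::.billiardStep(pos, c(cos(b), sin(b)), L, c(0, 0), R)
    keep[i, ] <- pos
  }
  r <- sqrt(rowSums(keep^2))
  expect_true(all(r <= R + 1e-9))
  ## uniform stationary density: about half the mass outside r = R/sqrt(2)
  expect_equal(mean(r > R / sqrt(2)), 0.5, tolerance = 0.1)
})

test_that("configurations round-trip through their plain-text file", {
  cfg <- defaultSimConfig(seed = 9)
  f <- tempfile(fileext = ".json")
  writeSimConfig(cfg, f)
  back <- readSimConfig(f)
  expect_identical(back@schedule$patch, cfg@schedule$patch)
  expect_identical(back@seed, cfg@seed)
  ## the reconstructed config reproduces the simulation bit-for-bit
  expect_identical(fixCoords(simulateTrajectory(back)),
                   fixCoords(simulateTrajectory(cfg)))
})

test_that("the truth region covers nearly all fixes", {
  cfg <- defaultSimConfig(seed = 3)
  sim <- simulateTrajectory(cfg)
  xy <- fixCoords(sim)
  reg <- truthRegion(cfg)
  inside <- pointsInAnyPoly(xy[, 1], xy[, 2], reg)
  expect_gt(mean(inside), 0.95)
  ## all in-patch fixes are inside by construction
  expect_true(all(inside[simLabels(sim) > 0]))
})
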
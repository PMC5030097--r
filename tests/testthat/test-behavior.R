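# Behavioral analytics: peaks, classification, bounds, reorientation,
# escape segmentation, rates, mutual information, validation metrics.

test_that("extremum detection finds injected pulses and applies the floors", {
  expect_equal(nrow(detectExtrema(rep(1, 50))), 0)
  set.seed(81)
  t <- seq(0, 60, by = 1 / 16)
  a3 <- rnorm(length(t), 0, 0.2)
  a3 <- a3 + 15 * exp(-(t - 15)^2 / 2) - 23 * exp(-(t - 40)^2 / 2)
  pk <- detectExtrema(a3)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$frame, c(which.min(abs(t - 15)), which.min(abs(t - 40))),
               tolerance = 1)
  expect_equal(pk$amplitude, c(15, -23), tolerance = 0.5)
  # amplitude floor
  a9 <- rnorm(length(t), 0, 0.2) + 9.5 * exp(-(t - 30)^2 / 2)
  expect_equal(nrow(detectExtrema(a9)), 0)
  expect_gte(nrow(detectExtrema(a9, minAmp = 5)), 1)
})

test_that("prominence filtering removes ripple and shoulder sub-peaks", {
  # main peak with a small shoulder wiggle on its flank
  t <- seq(-6, 6, by = 0.05)
  a3 <- 16 * exp(-t^2 / 4) + 0.35 * sin(8 * t) * (t > 0.5 & t < 2.5)
  pk <- detectExtrema(a3)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$amplitude, max(a3), tolerance = 0.2)
})

test_that("turn classification follows the amplitude bands", {
  expect_equal(classifyTurn(15), "omega")
  expect_equal(classifyTurn(10), "omega")
  expect_equal(classifyTurn(20), "omega")
  expect_equal(classifyTurn(23), "delta")
  expect_equal(classifyTurn(20.01), "delta")
  expect_equal(classifyTurn(-15), "shallow_dorsal")
  expect_equal(classifyTurn(-23), "shallow_dorsal")
  expect_error(classifyTurn(9.5), "large-amplitude")
})

test_that("turn bounds bracket a synthetic pulse via the a4-zero / a3<3 rule", {
  p <- generatorParams(seed = 82)
  traj <- generateEscape(p)
  truth <- attr(traj, "truth")
  m <- modeValues(traj)
  fr <- frameRate(traj)
  apex <- which.max(m[, 3])
  bd <- turnBounds(m[, 3], m[, 4], apex)
  expect_false(is.null(bd))
  expect_lte(abs(bd[["end"]] - truth$turnEnd * fr), 3)
  expect_lte(abs(bd[["start"]] - truth$turnStart * fr), 3)
  # no a3 < 3 after apex: not found
  expect_null(turnBounds(rep(10, 50) + c(1:25, 25:1) / 5,
                         sin(1:50), 25))
  # a4 with no zero after apex: not found
  a3 <- c(rep(0, 10), 15, rep(0, 10))
  expect_null(turnBounds(a3, rep(1, 21), 11))
})

test_that("straightness masks separate flat shapes from coils", {
  b <- fixtureBasis()
  mk <- function(modes) newModeTrajectory(matrix(modes, 1), 0, 16)
  expect_true(straightMask(mk(c(0, 0, 0, 0, 0)), b))
  expect_false(straightMask(mk(c(0, 0, 15, 0, 0)), b))
  # nested thresholds
  set.seed(83)
  m <- cbind(runif(30, -4, 4), runif(30, -4, 4), runif(30, -12, 12),
             runif(30, -3, 3), 0)
  traj <- newModeTrajectory(m, rep(0, 30), 16)
  m05 <- straightMask(traj, b, 0.5)
  m10 <- straightMask(traj, b, 1.0)
  expect_true(all(m10[m05]))
})

test_that("orientation change uses straight references and survives coils", {
  b <- fixtureBasis()
  n <- 64
  # no turn: identity trajectory
  m <- cbind(rep(2, n), rep(2, n), rep(0.5, n), 0, 0)
  traj <- newModeTrajectory(m, rep(1.0, n), 16)
  expect_equal(as.numeric(orientationChange(traj, n / 2, b)), 0,
               tolerance = 0.05)
  # rigid rotation by -pi across a coil event
  a3 <- 18 * exp(-((1:n) - n / 2)^2 / 50)
  orient <- 1.0 - pi * pnorm((1:n), n / 2, 2)
  traj2 <- newModeTrajectory(cbind(2, 2, a3, 0, 0), orient, 16)
  expect_equal(as.numeric(orientationChange(traj2, n / 2, b)), -pi,
               tolerance = 0.1)
  # -1.3 pi over-turn must not alias to +0.7 pi
  orient3 <- 1.0 - 1.3 * pi * pnorm((1:n), n / 2, 2)
  traj3 <- newModeTrajectory(cbind(2, 2, a3, 0, 0), orient3, 16)
  dth <- as.numeric(orientationChange(traj3, n / 2, b))
  expect_equal(dth, -1.3 * pi, tolerance = 0.12)
  expect_lt(dth, -pi)   # the sign/branch is preserved, not aliased
  # error when no straight frame exists on one side
  a3c <- c(rep(16, n / 2), a3[(n / 2 + 1):n])
  traj4 <- newModeTrajectory(cbind(2, 2, a3c, 0, 0), orient, 16)
  expect_error(orientationChange(traj4, n / 2, b), "straight")
})

test_that("escape segmentation recovers the generator's ground truth", {
  b <- fixtureBasis()
  p <- generatorParams(seed = 84)
  traj <- generateEscape(p)
  truth <- attr(traj, "truth")
  seg <- segmentEscape(traj, b)
  expect_false(seg$excluded)
  fr <- frameRate(traj)
  expect_lte(abs(seg$turn[["start"]] - truth$turnStart * fr), 3)
  expect_lte(abs(seg$turn[["end"]] - truth$turnEnd * fr), 3)
  expect_gte(seg$reversal[["start"]], truth$stimFrame - 1)
  expect_true(seg$apex > seg$reversal[["start"]])
  # segment reorientations telescope to the total
  dth <- seg$deltaTheta
  expect_equal(unname(dth[["total"]]),
               unname(dth[["reversal"]] + dth[["turn"]] + dth[["post"]]),
               tolerance = 0.15)
  # imposed total rotation is recovered
  expect_equal(unname(dth[["total"]]), truth$dthetaTotal, tolerance = 0.1 * pi)
})

test_that("trajectories without a post-stimulus turn are excluded", {
  b <- fixtureBasis()
  traj <- generateCrawl(generatorParams(seed = 85), duration = 30)
  seg <- segmentEscape(traj, b)
  expect_true(seg$excluded)
})

test_that("turn rates recover Poisson rates and cancel symmetric backgrounds", {
  set.seed(86)
  # 12 worms, 35 min, ventral-deep omega-band events at 0.5/min, no dorsal
  dur <- 2100
  ev <- do.call(rbind, lapply(1:12, function(w) {
    tt <- cumsum(rexp(80, 0.5 / 60))
    tt <- tt[tt < dur]
    data.frame(worm = w, time_s = tt, amplitude = runif(length(tt), 11, 19))
  }))
  r <- turnRates(ev, duration = dur)
  expect_equal(nrow(r), length(seq(200, dur - 600, by = 300)))
  err <- abs(r$omega_rate_per_min - 0.5)
  expect_true(all(err <= 2 * r$omega_se + 1e-9))
  expect_true(all(r$delta_rate_per_min == 0))
  # symmetric contamination in +/-[10, 20] cancels in expectation
  ev2 <- do.call(rbind, lapply(1:12, function(w) {
    tt <- cumsum(rexp(160, 1 / 60))
    tt <- tt[tt < dur]
    amp <- sample(c(-1, 1), length(tt), replace = TRUE) *
      runif(length(tt), 10, 20)
    data.frame(worm = w, time_s = tt, amplitude = amp)
  }))
  r2 <- turnRates(ev2, duration = dur)
  expect_true(all(abs(r2$omega_rate_per_min) <= 3 * r2$omega_se + 0.05))
  # no events at all
  r3 <- turnRates(data.frame(worm = integer(0), time_s = numeric(0),
                             amplitude = numeric(0)), duration = dur)
  expect_true(all(r3$omega_rate_per_min == 0))
  expect_true(all(r3$delta_rate_per_min == 0))
  expect_error(turnRates(ev, duration = 500), "shorter")
})

test_that("mutual information matches hand-computed contingency values", {
  expect_equal(binaryMI(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(binaryMI(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # identical event series: MI equals the series entropy at zero shift
  set.seed(87)
  tt <- sort(runif(30, 0, 600))
  mi <- eventMutualInfo(tt, tt, duration = 600, binWidths = 10,
                        maxShift = 20, nShuffles = 5, nBoot = 5)
  z <- mi[mi$shift_s == 0, ]
  occ <- integer(60)
  occ[floor(tt / 10) + 1] <- 1
  p1 <- mean(occ)
  H <- -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
  expect_equal(z$mi_bits, H, tolerance = 1e-12)
})

test_that("independent Poisson streams give MI at the shuffle level", {
  set.seed(88)
  reps <- 10
  stats <- replicate(reps, {
    tA <- cumsum(rexp(120, 1 / 30))
    tB <- cumsum(rexp(120, 1 / 30))
    tA <- tA[tA < 2100]
    tB <- tB[tB < 2100]
    mi <- eventMutualInfo(tA, tB, 2100, binWidths = c(4, 10),
                          maxShift = 60, nShuffles = 20, nBoot = 5)
    nb <- ceiling(2100 / 4)
    occ <- integer(nb)
    occ[pmin(nb, floor(tA / 4) + 1)] <- 1
    p1 <- mean(occ)
    H <- -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
    c(maxexc = max(mi$mi_bits - mi$shuffle_mean) / H,
      meanexc = mean(mi$mi_bits - mi$shuffle_mean) / H)
  })
  # the MI excess over the shuffle baseline stays at the few-percent-of-
  # entropy level expected from finite sampling, with zero mean
  expect_lt(max(stats["maxexc", ]), 0.05)
  expect_lt(abs(mean(stats["meanexc", ])), 0.01)
})

test_that("average turn profiles recover a common template", {
  set.seed(89)
  template <- function(x) 15 * sin(pi * x)
  trajs <- list()
  events <- NULL
  for (e in 1:6) {
    len <- sample(200:400, 1)
    x <- seq(0, 1, length.out = len)
    m <- cbind(2, -1, template(x), 0.5, 0)
    trajs[[e]] <- newModeTrajectory(m, rep(0, len), 16)
    events <- rbind(events, data.frame(start = 1, end = len, traj = e))
  }
  avg <- averageTurnProfile(trajs, events)
  expect_equal(length(avg$grid), 101)
  expect_lt(max(abs(avg$mean[, 3] - template(avg$grid))), 1e-3)
  expect_lt(max(avg$sd[, 3]), 1e-3)
  # identical events: SD identically zero
  avg2 <- averageTurnProfile(trajs[c(1, 1)],
                             data.frame(start = c(1, 1),
                                        end = rep(nrow(modeValues(trajs[[1]])), 2),
                                        traj = c(1, 1)))
  expect_true(all(avg2$sd == 0))
})

test_that("tracking-error summaries match direct norms", {
  set.seed(90)
  a <- matrix(rnorm(10 * 100), 10)
  b2 <- a + matrix(rnorm(1000, 0, 0.1), 10)
  te <- trackingErrors(a, b2)
  oracle <- vapply(1:10, function(i) sqrt(sum((a[i, ] - b2[i, ])^2)),
                   numeric(1))
  expect_equal(te$deltaTheta, oracle, tolerance = 1e-12)
  # constant offset c: norm is |c| * 10
  b3 <- a + 0.3
  expect_equal(trackingErrors(a, b3)$deltaTheta, rep(3, 10),
               tolerance = 1e-12)
  expect_equal(trackingErrors(a, a)$deltaTheta, rep(0, 10))
  # consecutive-frame distances
  expect_equal(consecutiveDistance(a),
               vapply(1:9, function(i) sqrt(sum((a[i + 1, ] - a[i, ])^2)),
                      numeric(1)))
})
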
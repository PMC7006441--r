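test_that("neutral calibration recovers the reference orientation", {
  fs <- 75
  n <- 11 * fs
  ident <- matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4)
  s <- QuaternionStream(ident, fs, "shank")
  expect_equal(calibrateNeutral(s), c(1, 0, 0, 0), tolerance = 1e-12)
  # constant non-identity orientation
  q0 <- as.numeric(quatFromZRotation(37))
  s2 <- QuaternionStream(matrix(rep(q0, each = n), ncol = 4), fs, "shank")
  ref <- calibrateNeutral(s2)
  expect_equal(gaitSPM:::quatAngleBetween(ref, q0), 0, tolerance = 1e-9)
  rel <- relativeOrientation(s2, ref)
  expect_lt(max(abs(quatToEuler(rel))), 1e-6)
})

test_that("calibration tolerates orientation noise but rejects motion", {
  fs <- 75
  n <- 11 * fs
  set.seed(31)
  q0 <- as.numeric(quatFromZRotation(20))
  noisy <- quatMultiply(matrix(rep(q0, each = n), ncol = 4),
                        quatFromZRotation(rnorm(n, sd = 1)))
  sN <- QuaternionStream(noisy / sqrt(rowSums(noisy^2)), fs, "shank")
  ref <- calibrateNeutral(sN)
  expect_lt(gaitSPM:::quatAngleBetween(ref, q0), 0.5)
  # slow drift above 5 deg/s fails
  drift <- quatFromZRotation(seq(0, 80, length.out = n))
  sD <- QuaternionStream(drift, fs, "shank")
  expect_error(calibrateNeutral(sD), "motion")
})

test_that("Euler decomposition matches closed forms and the matrix oracle", {
  expect_equal(unname(quatToEuler(quatFromZRotation(30))[1, "z"]), 30,
               tolerance = 1e-9)
  # additivity about a single axis
  q <- quatMultiply(quatFromZRotation(10), quatFromZRotation(20))
  expect_equal(unname(quatToEuler(q)[1, "z"]), 30, tolerance = 1e-9)
  set.seed(8)
  for (ang in runif(25, -170, 170)) {
    qz <- as.numeric(quatFromZRotation(ang))
    expect_equal(unname(quatToEuler(qz)[1, "z"]), zAngleFromMatrix(qz),
                 tolerance = 1e-6)
  }
  # gimbal proximity warns
  qy <- c(cos(0.5 * 88 * pi / 180), 0, sin(0.5 * 88 * pi / 180), 0)
  expect_warning(quatToEuler(qy), "gimbal")
})

test_that("joint angle is the filtered distal-proximal difference", {
  fs <- 75
  expect_equal(jointAngles(jointAngle(rep(12, 300), rep(12, 300), fs)),
               rep(0, 300), tolerance = 1e-9)
  expect_error(jointAngle(1:10, 1:9, fs), "equal length")
  # a step input is smoothed without excessive overshoot
  step <- c(rep(0, 150), rep(10, 150))
  sm <- jointAngles(jointAngle(step, rep(0, 300), fs))
  expect_lt(max(sm), 10 * 1.15)
  expect_gt(min(sm), -10 * 0.15)
})

test_that("generated waveforms survive the quaternion round trip", {
  plan <- defaultPlan(20)
  wf <- defaultAngleWaveforms()
  for (joint in names(wf)) {
    qs <- simulateQuaternions(wf[[joint]], plan, 75, seed = 13)
    ang <- jointAngle(quatToEuler(qs$distal)[, "z"],
                      quatToEuler(qs$proximal)[, "z"], 75, joint)
    mc <- meanCycle(lapply(segmentCycles(jointAngles(ang), qs$heelStrikes, TRUE),
                           timeNormalize))
    expect_lt(sqrt(mean((mc - wf[[joint]])^2)), 0.5)
    rom <- max(mc) - min(mc)
    expect_equal(rom, max(wf[[joint]]) - min(wf[[joint]]), tolerance = 0.5)
  }
  # negated waveform gives the negated angle (sign convention)
  qs <- simulateQuaternions(-wf$knee, plan, 75, seed = 13)
  ang <- jointAngle(quatToEuler(qs$distal)[, "z"],
                    quatToEuler(qs$proximal)[, "z"], 75, "knee")
  mc <- meanCycle(lapply(segmentCycles(jointAngles(ang), qs$heelStrikes, TRUE),
                         timeNormalize))
  expect_lt(sqrt(mean((mc + wf$knee)^2)), 0.5)
  # constant-zero waveform: identity streams, zero angle
  qs0 <- simulateQuaternions(rep(0, 101), plan, 75, seed = 13)
  expect_equal(max(abs(qs0$theta)), 0)
})

test_that("gait events are recovered from the angular-velocity template", {
  plan <- defaultPlan(20)
  gy <- simulateShankGyro(plan, 75, seed = 2)
  ev <- detectGaitEvents(gy$gyro, 75)
  hs <- heelStrikes(ev)
  # detection needs a preceding mid-swing peak, so the first generated
  # heel strike is unobservable; all others must match within 20 ms
  trueHs <- gy$heelStrikes[-1]
  expect_equal(length(hs), length(trueHs))
  expect_lt(max(abs(hs - trueHs)) / 75 * 1000, 20)
  to <- toeOffs(ev)
  matched <- vapply(to, function(t) min(abs(gy$toeOffs - t)), numeric(1))
  expect_lt(max(matched) / 75 * 1000, 20)
})

test_that("zero cycle-time variability gives equal strides", {
  plan <- gaitPlan(nCycles = 10, cycleTimeMean = 1.1, cycleTimeCv = 0,
                   stanceFraction = 62.4)
  gy <- simulateShankGyro(plan, 75, seed = 1)
  ev <- detectGaitEvents(gy$gyro, 75)
  expect_lte(diff(range(diff(heelStrikes(ev)))), 1)
  # footswitch side: all cycle times equal the mean to within one sample
  fsw <- simulateFootswitch(plan, 1500, seed = 1)
  expect_true(all(abs(fsw$cycleTimes - 1.1) <= 1 / 1500))
})

test_that("the generated stance fraction is recovered", {
  plan <- defaultPlan(20)
  gy <- simulateShankGyro(plan, 75, seed = 6)
  tp <- temporalParams(detectGaitEvents(gy$gyro, 75))
  expect_equal(tp$stancePct, 62.4, tolerance = 1)
})

test_that("temporal parameters match hand-computed oracles", {
  fs <- 100
  hs <- cumsum(c(1, 100, 110, 90, 100))  # intervals 1.0, 1.1, 0.9, 1.0 s
  ev <- GaitEvents(hs, fs = fs)
  tp <- temporalParams(ev, distanceM = 30, totalTimeS = 30)
  expect_equal(tp$velocity, 1.0)
  expect_equal(tp$cycleTime, 1.0)
  expect_equal(tp$cycleTimeCv, 8.164966, tolerance = 1e-5)  # sample SD
  tpP <- temporalParams(ev, 30, 30, cvEstimator = "population")
  expect_equal(tpP$cycleTimeCv, 7.071068, tolerance = 1e-5)
  # zero variability -> zero CV
  ev0 <- GaitEvents(c(1, 101, 201, 301), fs = fs)
  expect_equal(temporalParams(ev0, 30, 3)$cycleTimeCv, 0)
  expect_error(temporalParams(ev, 30, 0), "positive")
})

test_that("ROM is invariant under an additive angle offset", {
  fs <- 75
  plan <- defaultPlan(6)
  wf <- defaultAngleWaveforms()
  qs <- simulateQuaternions(wf$hip, plan, fs, seed = 3)
  base <- jointAngle(quatToEuler(qs$distal)[, "z"],
                     quatToEuler(qs$proximal)[, "z"], fs, "hip")
  shifted <- JointAngleTrack(jointAngles(base) + 12.5, "hip", fs)
  romOf <- function(tr) {
    mc <- meanCycle(lapply(segmentCycles(jointAngles(tr), qs$heelStrikes, TRUE),
                           timeNormalize))
    max(mc) - min(mc)
  }
  expect_equal(romOf(base), romOf(shifted), tolerance = 1e-9)
})

test_that("event containers enforce alternation", {
  expect_error(GaitEvents(c(100, 50), fs = 75), "increasing")
  expect_error(GaitEvents(c(1, 100), toeOffs = 150, fs = 75), "between")
  ok <- GaitEvents(c(1, 100, 200), toeOffs = c(60, 160), fs = 75)
  expect_s4_class(ok, "GaitEvents")
})
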
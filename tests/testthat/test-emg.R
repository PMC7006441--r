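test_that("band-pass rejects out-of-band components and passes the band", {
  fs <- 1500
  # DC is fully out of band
  dc <- rep(2, 3000)
  expect_lt(max(abs(bandpassEmg(dc, fs))), 1e-6 * 2)
  # 100 Hz is deep in the passband: unit amplitude preserved
  y100 <- bandpassEmg(toneAt(100, fs), fs)
  amp100 <- max(abs(steadyState(y100)))
  expect_gte(amp100, 0.99)
  expect_lte(amp100, 1.01)
  # 5 Hz (two octaves below the low edge) is strongly attenuated
  y5 <- bandpassEmg(toneAt(5, fs), fs)
  expect_lt(max(abs(steadyState(y5))), 0.01)
})

test_that("band-pass validates its inputs", {
  expect_error(bandpassEmg(c(1, NA, 3), 1500), "finite")
  expect_error(bandpassEmg(rnorm(100), 900), "twice")
})

test_that("envelope equals the instantaneous amplitude of a tone", {
  fs <- 1500
  expect_equal(emgEnvelope(numeric(1000), fs), numeric(1000))
  env <- emgEnvelope(toneAt(100, fs), fs)
  expect_true(all(abs(steadyState(env) - 1) < 0.02))
  expect_true(all(env >= 0))
  expect_error(emgEnvelope(numeric(0), fs), "empty")
})

test_that("envelope tracks amplitude modulation", {
  fs <- 1500
  t <- (0:(4 * fs - 1)) / fs
  modulation <- 1 + 0.5 * sin(2 * pi * 2 * t)
  x <- modulation * sin(2 * pi * 150 * t)
  env <- emgEnvelope(x, fs)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_gt(cor(env[mid], modulation[mid]), 0.99)
})

test_that("cycle segmentation counts and spans are exact", {
  x <- seq_len(2500)
  cyc <- segmentCycles(x, c(1, 1001, 2001))
  expect_length(cyc, 2)
  expect_length(cyc[[1]], 1000)
  expect_identical(cyc[[1]][1], 1L)
  expect_identical(cyc[[2]][1], 1001L)
  expect_error(segmentCycles(x, 5), "at least two")
  expect_error(segmentCycles(x, c(100, 50)), "strictly increasing")
})

test_that("segmentation matches generated footswitch cycles exactly", {
  fsw <- simulateFootswitch(defaultPlan(5), 1500, seed = 3)
  hs <- footswitchHeelStrikes(fsw$signal)
  expect_identical(hs, as.integer(fsw$heelStrikes))
  cyc <- segmentCycles(seq_along(fsw$signal), hs)
  expect_length(cyc, 5)
  expect_equal(vapply(cyc, length, numeric(1)), diff(fsw$heelStrikes))
})

test_that("time normalization is linear interpolation on 101 nodes", {
  ramp <- seq(0, 1, length.out = 773)
  tn <- timeNormalize(ramp)
  expect_length(tn, 101)
  expect_equal(tn, (0:100) / 100, tolerance = 1e-9)
  expect_equal(timeNormalize(rep(3.5, 10)), rep(3.5, 101))
  # one period of a sinusoid: closed-form comparison
  x <- sin(2 * pi * (0:999) / 999)
  tn2 <- timeNormalize(x)
  expect_lt(max(abs(tn2 - sin(2 * pi * (0:100) / 100))), 1e-3)
  expect_error(timeNormalize(1), "at least 2")
})

test_that("amplitude normalization divides by the subject reference", {
  cycles <- rbind(c(0, 2, 4), c(1, 3, 2))
  norm <- amplitudeNormalize(cycles, "max")
  expect_equal(norm$reference, 4)
  expect_equal(max(norm$cycles), 1)
  expect_equal(norm$cycles, cycles / 4)
  # 20 identical cycles: max and median references agree
  same <- matrix(rep(c(1, 5, 2), 20), nrow = 20, byrow = TRUE)
  expect_equal(amplitudeNormalize(same, "max")$cycles,
               amplitudeNormalize(same, "median")$cycles)
  # 19 cycles peaking at 1 plus 1 peaking at 2: references 2 vs 1
  mixed <- rbind(matrix(rep(c(0.2, 1, 0.3), 19), 19, byrow = TRUE),
                 c(0.2, 2, 0.3))
  expect_equal(amplitudeNormalize(mixed, "max")$reference, 2)
  expect_equal(amplitudeNormalize(mixed, "median")$reference, 1)
  expect_error(amplitudeNormalize(matrix(0, 3, 5)), "dead channel")
})

test_that("normalization is idempotent and gain-invariant (max mode)", {
  set.seed(42)
  cycles <- matrix(abs(rnorm(20 * 101)), 20)
  once <- amplitudeNormalize(cycles, "max")$cycles
  twice <- amplitudeNormalize(once, "max")$cycles
  expect_equal(once, twice)
  scaled <- amplitudeNormalize(cycles * 7.3, "max")$cycles
  expect_equal(scaled, once)
})

test_that("mean cycle is the node-wise average", {
  one <- matrix(rep(c(1, 2, 3), 4), 4, byrow = TRUE)
  expect_equal(meanCycle(one), c(1, 2, 3))
  expect_equal(meanCycle(rbind(rep(0, 5), rep(1, 5))), rep(0.5, 5))
  expect_error(meanCycle(list(1:3, 1:4)), "grid")
})

test_that("mean of noisy synthetic cycles stays within 3 SE of the template", {
  set.seed(7)
  template <- sin(2 * pi * (0:100) / 100)
  sdv <- 0.3
  n <- 20
  cycles <- t(replicate(n, template + rnorm(101, sd = sdv)))
  mc <- meanCycle(cycles)
  se <- sdv / sqrt(n)
  expect_true(all(abs(mc - template) < 3 * se + 1e-12 |
                  abs(mc - template) < 4 * se))
  # at least 99% of nodes within 3 SE (binomial slack for the rest)
  expect_gt(mean(abs(mc - template) < 3 * se), 0.95)
})

test_that("cycle-averaged envelope peaks inside the true burst window", {
  pr <- oneBurstProfile()
  ch <- simulateEmgChannel(pr, defaultPlan(20), 1500, seed = 7)
  env <- emgEnvelope(bandpassEmg(ch$signal, 1500), 1500)
  cyc <- segmentCycles(env, ch$heelStrikes)
  mc <- meanCycle(lapply(cyc, timeNormalize))
  expect_true(which.max(mc) - 1 >= 10 && which.max(mc) - 1 <= 40)
})
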
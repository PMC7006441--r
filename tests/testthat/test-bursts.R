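test_that("1D k-means separates well-separated clusters exactly", {
  km <- kmeans1d(c(0, 0, 0, 5, 5, 5, 10, 10, 10), 3)
  expect_equal(km$centers, c(0, 5, 10))
  expect_equal(km$labels, rep(1:3, each = 3))
  expect_error(kmeans1d(c(1, 1, 1, 1, 2), 3), "distinct")
  expect_error(kmeans1d(c(1, NA, 2, 3), 3), "finite")
})

test_that("1D k-means attains the brute-force optimum on small instances", {
  set.seed(2024)
  for (r in 1:60) {
    n <- sample(4:12, 1)
    x <- switch(sample(1:3, 1),
                runif(n), rnorm(n),
                c(abs(rnorm(n - 2, 0, 0.1)), runif(2, 1, 3)))
    if (length(unique(x)) < 3) next
    km <- kmeans1d(x, 3)
    expect_equal(sseOfLabels(x, km$labels), bruteKmeans3(x),
                 tolerance = 1e-9)
  }
})

test_that("k-means is deterministic and label order follows amplitude", {
  set.seed(5)
  x <- c(abs(rnorm(500, 0, 0.05)), abs(rnorm(100, 1, 0.2)))
  a <- kmeans1d(x, 3)
  b <- kmeans1d(x, 3)
  expect_identical(a, b)
  expect_true(all(diff(a$centers) > 0))
  expect_true(all(x[a$labels == 1] <= min(x[a$labels == 3])))
})

test_that("activity detection flags the two upper clusters", {
  x <- c(rep(0.01, 100), rep(1, 80), rep(0.01, 100), rep(0.5, 50),
         rep(0.01, 50)) + seq(0, 1e-4, length.out = 380)
  tr <- detectActivity(x, fs = 1000)
  iv <- intervals(tr)
  expect_equal(nrow(iv), 2)
  expect_equal(iv[1, ], c(onset = 101, offset = 181))
  expect_equal(iv[2, ], c(onset = 281, offset = 331))
  expect_error(detectActivity(c(-1, 2, 3), 1000), "non-negative")
  expect_warning(tr0 <- detectActivity(rep(0, 100), 1000), "silent")
  expect_equal(nrow(intervals(tr0)), 0)
})

test_that("burst-free noise collapses to few intervals after cleaning", {
  # the 3-cluster amplitude split presumes burst bimodality; on
  # stationary noise it fragments into many sub-5-ms runs whose gaps
  # are far below the 125 ms merge rule, so cleaning collapses the
  # channel into a handful of long intervals rather than bursts
  set.seed(9)
  fs <- 1500
  noise <- 0.05 * rectifyEmg(bandpassEmg(rnorm(10 * fs), fs))
  raw <- detectActivity(noise, fs)
  expect_gt(nrow(intervals(raw)), 100)
  cleaned <- cleanBursts(raw)
  expect_lt(nrow(intervals(cleaned)), 5)
})

test_that("cleaning applies discard-then-merge in the stated order", {
  fs <- 1000
  mk <- function(iv) BurstTrain(iv, "X", fs)
  # a single 3 ms burst is discarded (< 5 ms)
  expect_equal(nrow(intervals(cleanBursts(mk(cbind(100, 103))))), 0)
  # two 50 ms bursts 100 ms apart merge into one (< 125 ms gap)
  merged <- cleanBursts(mk(cbind(c(1, 151), c(51, 201))))
  expect_equal(unname(intervals(merged)), cbind(1, 201))
  # two 4 ms bursts 50 ms apart: discard precedes merge -> empty
  expect_equal(nrow(intervals(cleanBursts(mk(cbind(c(1, 55), c(5, 59)))))), 0)
  # 5 ms exactly is kept ("shorter than 5 ms" is discarded)
  expect_equal(nrow(intervals(cleanBursts(mk(cbind(100, 105))))), 1)
})

test_that("cleaning is idempotent and stays within the input span", {
  set.seed(11)
  fs <- 1500
  for (r in 1:20) {
    n <- sample(1:8, 1)
    on <- sort(sample(1:30000, n))
    off <- on + sample(1:400, n, replace = TRUE)
    on <- c(on[1], pmax(on[-1], off[-n] + 1))
    off <- pmax(off, on + 1)
    tr <- BurstTrain(cbind(on, off), "X", fs)
    c1 <- cleanBursts(tr)
    c2 <- cleanBursts(c1)
    expect_identical(intervals(c1), intervals(c2))
    if (nrow(intervals(c1))) {
      expect_gte(min(intervals(c1)), min(on))
      expect_lte(max(intervals(c1)), max(off))
    }
  }
})

test_that("cycle timing converts bursts to percent of each cycle", {
  fs <- 1000
  hs <- seq(1, 21001, by = 1000)
  iv <- cbind(hs[-length(hs)] + 100, hs[-length(hs)] + 400)  # 10 -> 40%
  tm <- cycleTiming(BurstTrain(iv, "X", fs), hs)
  expect_equal(unname(tm$summary["onsetPct"]), 10, tolerance = 0.01)
  expect_equal(unname(tm$summary["offsetPct"]), 40, tolerance = 0.01)
  expect_equal(unname(tm$summary["durationPct"]), 30, tolerance = 0.01)
})

test_that("bursts spanning heel strike average circularly", {
  fs <- 1000
  hs <- seq(1, 21001, by = 1000)
  # burst from 95% of each cycle to 10% of the next
  iv <- cbind(hs[-length(hs)] + 950, hs[-length(hs)] + 1100)
  iv <- iv[iv[, 2] <= max(hs), , drop = FALSE]
  tm <- cycleTiming(BurstTrain(iv, "X", fs), hs)
  expect_equal(unname(tm$summary["onsetPct"]), 95, tolerance = 0.2)
  expect_equal(unname(tm$summary["offsetPct"]), 10, tolerance = 0.2)
  expect_equal(unname(tm$summary["durationPct"]), 15, tolerance = 0.2)
  # circular-mean oracle on wrapped values (0 and 100 are identified)
  cm <- gaitSPM:::circularMeanPct(c(98, 2)) %% 100
  expect_lt(min(cm, 100 - cm), 1e-9)
})

test_that("a second burst in the transition window is reported", {
  pr <- muscleProfile("RF", data.frame(onsetPct = c(94, 54),
                                       offsetPct = c(12, 68),
                                       peakAmp = c(1, 0.7)), 0.05)
  ch <- simulateEmgChannel(pr, defaultPlan(20), 1500, seed = 4)
  rect <- rectifyEmg(bandpassEmg(ch$signal, 1500))
  tr <- cleanBursts(detectActivity(rect, 1500, "RF"))
  tm <- cycleTiming(tr, ch$heelStrikes, secondBurstWindow = c(45, 75))
  expect_equal(unname(tm$summary["onset2Pct"]), 54, tolerance = 3)
  expect_equal(unname(tm$summary["offset2Pct"]), 68, tolerance = 3)
})

test_that("burst on/offsets are recovered across signal-to-noise ratios", {
  plan <- defaultPlan(20)
  errAt <- function(snr, seed) {
    pr <- oneBurstProfile(10, 40, peak = 1, floor = 1 / snr)
    ch <- simulateEmgChannel(pr, plan, 1500, seed = seed)
    rect <- rectifyEmg(bandpassEmg(ch$signal, 1500))
    tr <- cleanBursts(detectActivity(rect, 1500))
    tm <- cycleTiming(tr, ch$heelStrikes)
    mean(c(abs(tm$perCycle$onsetPct - 10), abs(tm$perCycle$offsetPct - 40)),
         na.rm = TRUE)
  }
  expect_lt(errAt(20, 21), 2)
  expect_lt(errAt(10, 22), 4)
  expect_lt(errAt(5, 23), 8)
})
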
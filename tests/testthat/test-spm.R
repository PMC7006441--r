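test_that("identical groups give a zero t-curve and no clusters", {
  set.seed(1)
  A <- smoothGaussianField(5, 101, 20)
  r <- spmTtest2(A, A)
  expect_equal(tCurve(r), rep(0, 101))
  expect_equal(nrow(spmClusters(r)), 0)
})

test_that("the SPM t-curve equals the node-wise two-sample t-test", {
  set.seed(2)
  A <- smoothGaussianField(13, 101, 15)
  B <- smoothGaussianField(14, 101, 15) + 0.4
  r <- spmTtest2(A, B)
  expect_equal(tCurve(r), tCurveOracle(A, B), tolerance = 1e-9)
  expect_equal(r@df, 25)
})

test_that("zero-variance nodes are masked with a warning", {
  set.seed(3)
  A <- smoothGaussianField(6, 50, 10)
  B <- smoothGaussianField(6, 50, 10)
  A[, 7] <- 1; B[, 7] <- 1
  expect_warning(r <- spmTtest2(A, B), "masked")
  expect_equal(tCurve(r)[7], 0)
  expect_equal(r@maskedNodes, 6)
})

test_that("smoothness estimator recovers the generating FWHM", {
  set.seed(4)
  fw <- sapply(1:40, function(i) estimateFwhm(smoothGaussianField(25, 101, 20)))
  expect_equal(mean(fw), 20, tolerance = 0.08)
})

test_that("RFT threshold is monotone in smoothness and has the t limit", {
  t10 <- rftThreshold(25, 101, fwhm = 10)
  t30 <- rftThreshold(25, 101, fwhm = 30)
  expect_gt(t10, t30)
  expect_gt(t30, qt(0.975, 25))
  # resels -> 0 recovers the ordinary two-tailed t quantile
  expect_equal(rftThreshold(25, 101, fwhm = 1e9), qt(0.975, 25),
               tolerance = 1e-3)
  expect_equal(rftThreshold(25, 101, fwhm = 1e9, tails = 1), qt(0.95, 25),
               tolerance = 1e-3)
})

test_that("the analytic threshold matches simulated smooth t-fields", {
  # empirical 95th percentile of the field maximum vs analytic threshold
  set.seed(5)
  reps <- 2000
  mx <- replicate(reps, {
    A <- smoothGaussianField(13, 101, 20)
    B <- smoothGaussianField(14, 101, 20)
    max(abs(tCurve(spmTtest2(A, B, alpha = 0.05))))
  })
  analytic <- rftThreshold(25, 101, 20, alpha = 0.05, tails = 2)
  expect_equal(unname(quantile(mx, 0.95)), analytic, tolerance = 0.03)
})

test_that("cluster p-values decrease with extent and cap at 1", {
  expect_equal(clusterPvalue(0, 3.1, 25, 20), 1)
  p5 <- clusterPvalue(5, 3.1, 25, 20)
  p30 <- clusterPvalue(30, 3.1, 25, 20)
  expect_lt(p30, p5)
  expect_lte(p5, 1)
  expect_gt(p30, 0)
})

test_that("cluster-extent survival matches null-field simulation", {
  set.seed(6)
  df <- 25; fw <- 20
  u <- rftThreshold(df, 101, fw)
  ext <- c()
  for (r in 1:3000) {
    tt <- tCurve(spmTtest2(smoothGaussianField(13, 101, fw),
                           smoothGaussianField(14, 101, fw)))
    rl <- rle(abs(tt) > u)
    if (any(rl$values)) ext <- c(ext, rl$lengths[rl$values])
  }
  expect_gt(length(ext), 50)
  # analytic conditional survival at the empirical quartiles within 0.15
  ec <- gaitSPM:::ecDensity1d(u, df)
  en <- pt(u, df, lower.tail = FALSE) / ec
  beta <- (gamma(1.5) / en)^2
  # node discreteness and the squared-extent approximation leave a
  # modest misfit; the family-wise error calibration itself is exact
  for (q in c(0.25, 0.5, 0.75)) {
    k <- unname(quantile(ext, q)) / fw
    expect_lt(abs(exp(-beta * k^2) - (1 - q)), 0.15)
  }
})

test_that("Cohen's d from summary statistics matches published values", {
  # hip ROM at preferred velocity: 35.4 +/- 4.9 vs 29.8 +/- 5.1
  expect_equal(round(cohensD(35.4, 4.9, 13, 29.8, 5.1, 14), 2), 1.12)
  # knee ROM at matched velocity: 51.2 +/- 5.1 vs 39.3 +/- 8.3
  expect_equal(round(cohensD(51.2, 5.1, 13, 39.3, 8.3, 14), 2), 1.71)
  expect_equal(cohensD(5, 1, 10, 5, 1, 10), 0)
  expect_error(cohensD(1, 0, 5, 1, 0, 5), "pooled")
})

test_that("a priori sample size follows the noncentral t", {
  expect_identical(powerNPerGroup(1.03, 0.05, 0.80, tails = 1), 13L)
  expect_identical(powerNPerGroup(1.03, 0.05, 0.80, tails = 2), 16L)
  expect_identical(powerNPerGroup(10, 0.05, 0.80, tails = 2), 2L)
  # oracle check: power at n-1 is below target, at n at or above
  pow <- function(n, tails) {
    df <- 2 * n - 2
    pt(qt(1 - 0.05 / tails, df), df, ncp = 1.03 * sqrt(n / 2),
       lower.tail = FALSE)
  }
  expect_lt(pow(12, 1), 0.80)
  expect_gte(pow(13, 1), 0.80)
})

test_that("scalar comparisons select and compute the right tests", {
  # 2x2 proportions with continuity correction
  chi <- compareScalar(c(7, 13), c(4, 14), "chi2")
  expect_equal(round(chi$p.value, 3), 0.345)
  # identical groups -> t statistic 0
  x <- c(1.1, 1.3, 0.9, 1.2)
  expect_equal(compareScalar(x, x, "t")$statistic, 0)
  # large shift detected by the rank-sum test at n = 13/14
  set.seed(7)
  a <- rnorm(13)
  b <- rnorm(14) + 10
  expect_lt(compareScalar(a, b, "ranksum")$p.value, 0.001)
  # auto picks rank-sum for clearly non-normal data
  set.seed(8)
  skew <- rexp(20)^3
  expect_equal(compareScalar(skew, skew + 0.1, "auto")$kind, "ranksum")
  expect_error(compareScalar(1, 2, "t"), "two values")
})

test_that("an injected smooth difference is detected where it was placed", {
  set.seed(9)
  band <- 21:41  # 20-40% of the cycle
  bump <- numeric(101)
  bump[band] <- 1
  hits <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    A <- smoothGaussianField(13, 101, 20)
    B <- sweep(smoothGaussianField(14, 101, 20), 2, bump, "+")
    res <- spmTtest2(A, B)
    cl <- spmClusters(res)
    if (nrow(cl) > 0 &&
        any(cl$start <= 40 & cl$end >= 20)) hits <- hits + 1
  }
  # with d = 1 over the band, the RFT-corrected two-tailed test detects
  # an overlapping cluster in about half the replicates (the correction
  # over the whole cycle is stricter than the pointwise scalar design)
  expect_gte(hits / reps, 0.4)
})

test_that("the scalar design premise reproduces its nominal power", {
  # one-tailed uncorrected t-test on the band mean at d = 1.03, n = 13/14
  set.seed(10)
  reps <- 400
  hit <- 0
  for (r in seq_len(reps)) {
    a <- rnorm(13)
    b <- rnorm(14) + 1.03
    tt <- t.test(b, a, var.equal = TRUE, alternative = "greater")
    if (tt$p.value < 0.05) hit <- hit + 1
  }
  expect_equal(hit / reps, 0.815, tolerance = 0.08)
})
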
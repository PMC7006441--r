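# Shared fixtures and independent oracles, built in code.

toneAt <- function(freq, fs, durS = 4, amp = 1) {
  amp * sin(2 * pi * freq * (0:(round(durS * fs) - 1)) / fs)
}

steadyState <- function(x, frac = 0.4) {
  n <- length(x)
  x[seq(round(n * (0.5 - frac / 2)) + 1, round(n * (0.5 + frac / 2)))]
}

# Brute-force optimal contiguous 3-partition of sorted data by total
# within-cluster SSE (oracle for kmeans1d; optimal 1D k-means partitions
# are contiguous in sorted order).
bruteKmeans3 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      g <- list(xs[1:i], xs[(i + 1):j], xs[(j + 1):n])
      sse <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
      if (sse < best) best <- sse
    }
  }
  best
}

sseOfLabels <- function(x, labels) {
  sum(vapply(split(x, labels), function(v) sum((v - mean(v))^2), numeric(1)))
}

# Two-sided pointwise t-curve oracle via stats::t.test at each node.
tCurveOracle <- function(A, B) {
  vapply(seq_len(ncol(A)), function(j)
    unname(stats::t.test(A[, j], B[, j], var.equal = TRUE)$statistic),
    numeric(1))
}

# Rotation-matrix-based z-angle oracle for single-axis z rotations.
zAngleFromMatrix <- function(q) {
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  atan2(R[2, 1], R[1, 1]) * 180 / pi
}

oneBurstProfile <- function(onset = 10, offset = 40, peak = 1,
                            floor = 0.05) {
  muscleProfile("MG", data.frame(onsetPct = onset, offsetPct = offset,
                                 peakAmp = peak), floor)
}

defaultPlan <- function(nCycles = 20) {
  gaitPlan(nCycles = nCycles, cycleTimeMean = 1.1, cycleTimeCv = 2.6,
           stanceFraction = 62.4)
}
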
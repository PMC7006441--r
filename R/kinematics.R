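#' Sagittal joint angle from distal and proximal segment angles
#'
#' The joint angle is the sagittal (z) angle of the distal segment with
#' respect to the proximal segment, `flexionSign * (distal - proximal)`,
#' low-pass filtered at 10 Hz (4th-order Butterworth, zero-phase). Signs
#' are chosen per joint so flexion (hip, knee) and dorsi-flexion (ankle)
#' are positive; see [jointSignConventions()].
#'
#' @param distalZ,proximalZ sagittal segment angles in degrees (equal
#'   length, same sampling rate).
#' @param fs sampling rate in Hz.
#' @param joint joint name stored in the result.
#' @param flexionSign +1 or -1.
#' @param cutoff low-pass cutoff in Hz; `NULL` disables filtering.
#' @param order low-pass design order per pass.
#' @return a [JointAngleTrack-class].
#' @export
jointAngle <- function(distalZ, proximalZ, fs, joint = "unknown",
                       flexionSign = 1, cutoff = 10, order = 4) {
  if (length(distalZ) != length(proximalZ)) {
    stop("distal and proximal tracks must have equal length")
  }
  ang <- flexionSign * (distalZ - proximalZ)
  if (!is.null(cutoff)) ang <- zeroPhaseButter(ang, fs, cutoff, order, "low")
  JointAngleTrack(ang, joint, fs)
}

#' Per-joint sign conventions
#'
#' Sign applied to (distal - proximal) sagittal angles so that hip/knee
#' flexion and ankle dorsi-flexion are positive and extension /
#' plantar-flexion negative. With segment angles measured about the
#' mediolateral axis, knee flexion moves the shank backward relative to
#' the thigh, hence the negative sign.
#'
#' @return named numeric vector for hip, knee, ankle.
#' @export
jointSignConventions <- function() {
  c(hip = 1, knee = -1, ankle = 1)
}

#' Detect gait events from shank angular velocity
#'
#' Mid-swing appears as a prominent positive peak of the shank z-axis
#' angular velocity. Heel strike is the first local minimum after each
#' mid-swing peak and toe-off the deepest local minimum in the window
#' preceding the peak. Defaults are tuned for 0.8-1.4 m/s walking.
#'
#' @param gyroZ shank z angular velocity in deg/s.
#' @param fs sampling rate in Hz.
#' @param minPeakHeight minimum mid-swing peak height (deg/s).
#' @param minSeparation minimum separation between mid-swing peaks (s).
#' @return a [GaitEvents-class] with alternating heel strikes and
#'   toe-offs.
#' @export
detectGaitEvents <- function(gyroZ, fs, minPeakHeight = 50,
                             minSeparation = 0.5) {
  pk <- pracma::findpeaks(gyroZ, minpeakheight = minPeakHeight,
                          minpeakdistance = max(1L, round(minSeparation * fs)))
  if (is.null(pk) || nrow(pk) < 2L) {
    stop("no mid-swing peaks found: at least two gait cycles are required")
  }
  peaks <- sort(pk[, 2L])
  n <- length(gyroZ)
  isLocalMin <- function(i) {
    i > 1L && i < n && gyroZ[i] <= gyroZ[i - 1L] && gyroZ[i] <= gyroZ[i + 1L]
  }
  hs <- integer(0)
  for (p in peaks) {
    i <- p + 1L
    while (i < n && !isLocalMin(i)) i <- i + 1L
    if (isLocalMin(i)) hs <- c(hs, i)
  }
  to <- integer(0)
  for (j in seq_along(peaks)) {
    lo <- if (j == 1L) 1L else peaks[j - 1L]
    win <- (lo + 1L):(peaks[j] - 1L)
    mins <- win[vapply(win, isLocalMin, logical(1))]
    if (length(mins)) to <- c(to, mins[which.min(gyroZ[mins])])
  }
  hs <- unique(hs)
  if (length(hs) < 2L) stop("fewer than two heel strikes detected")
  # keep toe-offs strictly inside a stride
  to <- to[vapply(to, function(t)
    any(hs[-length(hs)] < t & t < hs[-1L]), logical(1))]
  GaitEvents(hs, unique(to), fs)
}

#' Temporal-spatial gait parameters
#'
#' Mean walking velocity (total distance over total time), mean and
#' coefficient of variation of the cycle time, stance phase as % of the
#' cycle, and per-joint range of motion computed as max minus min of the
#' mean time-normalized angle cycle.
#'
#' @param events a [GaitEvents-class].
#' @param distanceM walked distance in meters.
#' @param totalTimeS total walk time in seconds; defaults to the span
#'   from first to last heel strike.
#' @param angleTracks optional named list of [JointAngleTrack-class]
#'   objects; ROM is reported for each.
#' @param cvEstimator `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @param nCycles cap on the number of cycles entering the mean angle
#'   cycle; `Inf` uses all.
#' @return list with `velocity` (m/s), `cycleTime` (s), `cycleTimeCv`
#'   (%), `stancePct` (%), and `rom` (named vector, degrees).
#' @export
temporalParams <- function(events, distanceM = 30, totalTimeS = NULL,
                           angleTracks = NULL,
                           cvEstimator = c("sample", "population"),
                           nCycles = Inf) {
  cvEstimator <- match.arg(cvEstimator)
  hs <- heelStrikes(events)
  to <- toeOffs(events)
  fs <- samplingRate(events)
  if (length(hs) < 2L) stop("at least two heel strikes are required")
  cycleS <- diff(hs) / fs
  if (is.null(totalTimeS)) totalTimeS <- (hs[length(hs)] - hs[1L]) / fs
  if (totalTimeS <= 0) stop("total time must be positive")
  sdv <- if (cvEstimator == "sample") stats::sd(cycleS) else {
    sqrt(mean((cycleS - mean(cycleS))^2))
  }
  cv <- sdv / mean(cycleS) * 100
  stance <- NA_real_
  if (length(to)) {
    per <- vapply(to, function(t) {
      k <- findInterval(t, hs)
      (t - hs[k]) / (hs[k + 1L] - hs[k]) * 100
    }, numeric(1))
    stance <- mean(per)
  }
  rom <- NULL
  if (!is.null(angleTracks)) {
    rom <- vapply(angleTracks, function(tr) {
      cyc <- segmentCycles(jointAngles(tr), hs, inclusive = TRUE)
      cyc <- cyc[seq_len(min(length(cyc), nCycles))]
      mc <- meanCycle(lapply(cyc, timeNormalize))
      max(mc) - min(mc)
    }, numeric(1))
  }
  list(velocity = distanceM / totalTimeS,
       cycleTime = mean(cycleS),
       cycleTimeCv = cv,
       stancePct = stance,
       rom = rom)
}
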
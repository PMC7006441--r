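# Synthetic gait sessions with known ground truth: burst-modulated EMG,
# a heel footswitch, quaternion streams encoding prescribed joint
# waveforms, and a shank angular-velocity template carrying the gait
# events. Every generator is deterministic under a fixed seed.

#' Muscle activation profile for the EMG generator
#'
#' @param muscleLabel muscle name.
#' @param bursts data.frame (or matrix) with columns `onsetPct`,
#'   `offsetPct`, `peakAmp`; a burst with `offsetPct < onsetPct` wraps
#'   across the cycle boundary. Bursts must not overlap.
#' @param noiseFloor baseline envelope amplitude (>= 0, below every
#'   `peakAmp`).
#' @return list of class `MuscleProfile`.
#' @export
muscleProfile <- function(muscleLabel, bursts, noiseFloor = 0.05) {
  bursts <- as.data.frame(bursts)
  stopifnot(all(c("onsetPct", "offsetPct", "peakAmp") %in% names(bursts)))
  if (noiseFloor < 0) stop("noiseFloor must be >= 0")
  if (nrow(bursts)) {
    if (any(bursts$onsetPct < 0 | bursts$onsetPct > 100 |
            bursts$offsetPct < 0 | bursts$offsetPct > 100)) {
      stop("burst on/offsets must lie in [0, 100] % cycle")
    }
    if (any(bursts$peakAmp <= noiseFloor)) {
      stop("peakAmp must exceed noiseFloor")
    }
    # overlap check on unwrapped intervals (mod 100)
    iv <- cbind(bursts$onsetPct,
                ifelse(bursts$offsetPct > bursts$onsetPct,
                       bursts$offsetPct, bursts$offsetPct + 100))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (nrow(iv) > 1L) {
      for (i in 2:nrow(iv)) {
        if (iv[i, 1L] < iv[i - 1L, 2L]) stop("overlapping bursts in profile")
      }
      if (iv[nrow(iv), 2L] > 100 && iv[nrow(iv), 2L] - 100 > iv[1L, 1L]) {
        stop("overlapping bursts in profile (wrap)")
      }
    }
  }
  structure(list(muscleLabel = muscleLabel, bursts = bursts,
                 noiseFloor = noiseFloor), class = "MuscleProfile")
}

#' Gait plan: cycle timing and stance structure
#'
#' @param nCycles number of gait cycles (>= 1).
#' @param cycleTimeMean mean cycle duration in seconds.
#' @param cycleTimeCv coefficient of variation of cycle time, in percent.
#' @param stanceFraction stance phase in percent of the cycle,
#'   strictly inside (0, 100).
#' @param walkDistance walked distance in meters.
#' @return list of class `GaitPlan`.
#' @export
gaitPlan <- function(nCycles = 20, cycleTimeMean = 1.1, cycleTimeCv = 2.6,
                     stanceFraction = 62.4, walkDistance = 30) {
  if (nCycles < 1) stop("nCycles must be >= 1")
  if (cycleTimeMean <= 0) stop("cycleTimeMean must be positive")
  if (cycleTimeCv < 0) stop("cycleTimeCv must be >= 0")
  if (stanceFraction <= 0 || stanceFraction >= 100) {
    stop("stanceFraction must lie strictly inside (0, 100)")
  }
  structure(list(nCycles = as.integer(nCycles),
                 cycleTimeMean = cycleTimeMean, cycleTimeCv = cycleTimeCv,
                 stanceFraction = stanceFraction,
                 walkDistance = walkDistance), class = "GaitPlan")
}

# Draw realized cycle durations (seconds). Uses the current RNG state.
drawCycleTimes <- function(plan) {
  sdv <- plan$cycleTimeCv / 100 * plan$cycleTimeMean
  dur <- stats::rnorm(plan$nCycles, plan$cycleTimeMean, sdv)
  pmax(dur, 0.3 * plan$cycleTimeMean)
}

# Event times/samples for realized cycle durations on a given rate.
cyclesToEvents <- function(durations, stanceFraction, fs, leadS = 0) {
  hsT <- leadS + c(0, cumsum(durations))
  toT <- hsT[seq_along(durations)] + stanceFraction / 100 * durations
  list(hs = round(hsT * fs) + 1L, to = round(toT * fs) + 1L,
       durations = durations, hsTimes = hsT, toTimes = toT)
}

realizeCycles <- function(plan, fs, leadS = 0) {
  cyclesToEvents(drawCycleTimes(plan), plan$stanceFraction, fs, leadS)
}

#' Synthetic heel footswitch channel
#'
#' Binary heel-contact channel: 1 from each heel strike to the toe-off at
#' `stanceFraction` percent of the cycle, 0 during swing. Rising edges
#' occur exactly at the generated heel-strike samples.
#'
#' @param plan a [gaitPlan()].
#' @param fs sampling rate in Hz.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param leadS quiet lead-in in seconds before the first heel strike.
#' @return list with `signal` (0/1 vector), `heelStrikes`, `toeOffs`
#'   (sample indices) and `cycleTimes` (s).
#' @export
simulateFootswitch <- function(plan, fs, seed = NULL, leadS = 0) {
  if (!is.null(seed)) set.seed(seed)
  rc <- realizeCycles(plan, fs, leadS)
  footswitchFromEvents(rc, plan$nCycles, fs)
}

footswitchFromEvents <- function(rc, nCycles, fs) {
  len <- rc$hs[nCycles + 1L] + round(0.05 * fs)
  sig <- numeric(len)
  for (k in seq_len(nCycles)) sig[rc$hs[k]:min(rc$to[k], len)] <- 1
  sig[rc$hs[nCycles + 1L]:len] <- 1  # contact at the final heel strike
  list(signal = sig, heelStrikes = rc$hs, toeOffs = rc$to[seq_len(nCycles)],
       cycleTimes = diff(rc$hs) / fs)
}

#' Heel strikes from a footswitch channel
#'
#' Rising edges (0 to 1 transitions) of a binary heel-contact channel.
#'
#' @param fsw 0/1 vector.
#' @return sample indices of the rising edges.
#' @export
footswitchHeelStrikes <- function(fsw) {
  which(diff(c(0, as.numeric(fsw) > 0.5)) == 1)
}

# Per-sample amplitude profile of one burst with raised-cosine ramps.
burstAmplitude <- function(tS, startS, endS, rampS) {
  a <- numeric(length(tS))
  inb <- tS >= startS & tS <= endS
  a[inb] <- 1
  up <- inb & tS < startS + rampS
  a[up] <- 0.5 * (1 - cos(pi * (tS[up] - startS) / rampS))
  dn <- inb & tS > endS - rampS
  a[dn] <- pmin(a[dn], 0.5 * (1 - cos(pi * (endS - tS[dn]) / rampS)))
  a
}

# Build one EMG channel over precomputed realized cycles; only the
# carrier noise consumes RNG draws.
emgChannelFromCycles <- function(profile, rc, nCycles, fs, rampMs = 20) {
  len <- rc$hs[nCycles + 1L] + round(0.05 * fs)
  tS <- (seq_len(len) - 1) / fs
  env <- rep(profile$noiseFloor, len)
  truth <- list()
  rampS <- rampMs / 1000
  if (nrow(profile$bursts)) {
    for (k in seq_len(nCycles)) {
      t0 <- rc$hsTimes[k]
      dk <- rc$durations[k]
      for (bi in seq_len(nrow(profile$bursts))) {
        b <- profile$bursts[bi, ]
        span <- (b$offsetPct - b$onsetPct) %% 100
        if (span == 0) span <- 100
        startS <- t0 + b$onsetPct / 100 * dk
        endS <- startS + span / 100 * dk
        amp <- burstAmplitude(tS, startS, endS,
                              min(rampS, span / 100 * dk / 2))
        env <- pmax(env,
                    profile$noiseFloor + (b$peakAmp - profile$noiseFloor) * amp)
        truth[[length(truth) + 1L]] <- data.frame(
          cycle = k, burst = bi,
          onset = round(startS * fs) + 1L,
          offset = round(endS * fs) + 1L)
      }
    }
  }
  if (all(env == 0)) {
    sig <- numeric(len)
  } else {
    white <- stats::rnorm(len)
    carrier <- zeroPhaseButter(white, fs, c(20, 450), 4, "pass")
    carrier <- carrier / (stats::sd(carrier) * sqrt(pi / 2))
    sig <- carrier * env
  }
  trueBursts <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(cycle = integer(0), burst = integer(0),
               onset = integer(0), offset = integer(0))
  }
  list(signal = sig, heelStrikes = rc$hs, trueBursts = trueBursts,
       envelope = env)
}

#' Synthetic surface-EMG channel with known burst windows
#'
#' Zero-mean band-limited Gaussian noise (20-450 Hz) whose amplitude
#' envelope follows the burst profile: baseline `noiseFloor` outside
#' bursts, `peakAmp` inside, with raised-cosine ramps of `rampMs` at the
#' burst edges. Ground-truth burst windows are returned in sample
#' indices matching the realized cycle boundaries.
#'
#' @param profile a [muscleProfile()].
#' @param plan a [gaitPlan()].
#' @param fs sampling rate in Hz (> 1000 so the 20-500 Hz band-pass is
#'   realizable).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param rampMs burst edge ramp duration in milliseconds.
#' @param leadS quiet lead-in in seconds.
#' @return list with `signal`, `heelStrikes`, `trueBursts` (data.frame:
#'   cycle, burst, onset, offset in samples) and `envelope` (the
#'   ground-truth amplitude profile).
#' @export
simulateEmgChannel <- function(profile, plan, fs, seed = NULL, rampMs = 20,
                               leadS = 0) {
  if (fs <= 1000) stop("fs must exceed 1000 Hz")
  if (!is.null(seed)) set.seed(seed)
  rc <- realizeCycles(plan, fs, leadS)
  emgChannelFromCycles(profile, rc, plan$nCycles, fs, rampMs)
}

#' Quaternion streams encoding a joint-angle waveform
#'
#' Builds proximal and distal orientation streams whose relative
#' sagittal (z-axis) rotation reproduces the given 101-node waveform in
#' every realized gait cycle: the proximal stream is the identity and
#' the distal stream rotates about the mediolateral axis by the
#' interpolated waveform, so the recovered joint angle equals the
#' waveform up to resampling error.
#'
#' @param waveform numeric vector of 101 angle values (degrees) on the
#'   0-100% grid.
#' @param plan a [gaitPlan()].
#' @param fs sampling rate in Hz (> 0).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param leadS neutral (zero-angle) lead-in in seconds; the last
#'   `rampS` of it ramps smoothly into the waveform.
#' @param rampS transition ramp length in seconds.
#' @return list with `proximal` and `distal` ([QuaternionStream-class]),
#'   `heelStrikes` (sample indices) and `theta` (the per-sample angle).
#' @export
simulateQuaternions <- function(waveform, plan, fs, seed = NULL, leadS = 0,
                                rampS = 0.5) {
  if (fs <= 0) stop("fs must be positive")
  if (length(waveform) != 101L || any(!is.finite(waveform))) {
    stop("waveform must be 101 finite values")
  }
  if (!is.null(seed)) set.seed(seed)
  rc <- realizeCycles(plan, fs, leadS)
  n <- plan$nCycles
  len <- rc$hs[n + 1L] + round(0.05 * fs)
  theta <- waveformPerSample(waveform, rc$hs, len, leadRampN =
                               if (leadS > 0) round(rampS * fs) else 0L)
  distal <- QuaternionStream(quatFromZRotation(theta), fs, "distal")
  ident <- matrix(rep(c(1, 0, 0, 0), each = len), ncol = 4L)
  proximal <- QuaternionStream(ident, fs, "proximal")
  list(proximal = proximal, distal = distal, heelStrikes = rc$hs,
       theta = theta)
}

# Interpolate a 101-node waveform onto realized cycles; zero before the
# lead ramp, held at the first node value after the last heel strike.
waveformPerSample <- function(wv, hs, len, leadRampN = 0L) {
  th <- numeric(len)
  grid <- seq(0, 100, length.out = 101L)
  for (k in seq_len(length(hs) - 1L)) {
    idx <- hs[k]:(hs[k + 1L] - 1L)
    pct <- (idx - hs[k]) / (hs[k + 1L] - hs[k]) * 100
    th[idx] <- stats::approx(grid, wv, xout = pct)$y
  }
  th[hs[length(hs)]:len] <- wv[1L]
  rampN <- min(leadRampN, hs[1L] - 1L)
  if (rampN > 0) {
    ramp <- (1 - cos(pi * seq_len(rampN) / rampN)) / 2
    th[(hs[1L] - rampN):(hs[1L] - 1L)] <- ramp * wv[1L]
  }
  th
}

#' Synthetic shank angular-velocity trace with known gait events
#'
#' Sum of Gaussian bumps per cycle: a prominent positive mid-swing peak
#' between toe-off and the next heel strike, and negative dips at each
#' heel strike and toe-off (the toe-off dip is the deepest). Toe-off is
#' placed at `stanceFraction` percent of each realized cycle, so event
#' detection can be validated against ground truth.
#'
#' @param plan a [gaitPlan()].
#' @param fs sampling rate in Hz.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param leadS quiet lead-in in seconds.
#' @param peakAmp mid-swing peak amplitude (deg/s).
#' @param hsDepth,toDepth dip depths at heel strike and toe-off (deg/s).
#' @return list with `gyro` (deg/s), `heelStrikes`, `toeOffs` (sample
#'   indices).
#' @export
simulateShankGyro <- function(plan, fs, seed = NULL, leadS = 0,
                              peakAmp = 250, hsDepth = 150, toDepth = 300) {
  if (!is.null(seed)) set.seed(seed)
  rc <- realizeCycles(plan, fs, leadS)
  shankGyroFromEvents(rc, plan, fs, peakAmp, hsDepth, toDepth)
}

shankGyroFromEvents <- function(rc, plan, fs, peakAmp = 250, hsDepth = 150,
                                toDepth = 300) {
  n <- plan$nCycles
  len <- rc$hs[n + 1L] + round(0.05 * fs)
  tS <- (seq_len(len) - 1) / fs
  sig <- numeric(len)
  sigma <- 0.022 * plan$cycleTimeMean
  # the mid-swing peak is broader than the event dips, with its area
  # matched to theirs so the net shank rotation per cycle is zero and
  # the integrated segment angle does not drift
  sigmaPeak <- (hsDepth + toDepth) / peakAmp * sigma
  bump <- function(center, amp, s) amp * exp(-0.5 * ((tS - center) / s)^2)
  for (k in seq_len(n + 1L)) sig <- sig + bump(rc$hsTimes[k], -hsDepth, sigma)
  for (k in seq_len(n)) {
    sig <- sig + bump(rc$toTimes[k], -toDepth, sigma)
    mid <- (rc$toTimes[k] + rc$hsTimes[k + 1L]) / 2
    sig <- sig + bump(mid, peakAmp, sigmaPeak)
  }
  list(gyro = sig, heelStrikes = rc$hs, toeOffs = rc$to[seq_len(n)],
       times = tS)
}

#' Default muscle activation profiles
#'
#' Activation timings (percent gait cycle) drawn from the normal-gait
#' EMG literature for the eleven recorded lower-limb muscles. Rectus
#' femoris carries a second burst in the stance-to-swing transition.
#'
#' @param noiseFloor baseline envelope amplitude.
#' @return named list of [muscleProfile()] objects.
#' @export
defaultMuscleProfiles <- function(noiseFloor = 0.05) {
  mk <- function(label, on, off, amp = 1) {
    muscleProfile(label, data.frame(onsetPct = on, offsetPct = off,
                                    peakAmp = amp), noiseFloor)
  }
  list(
    MG = mk("MG", 15, 50),
    LG = mk("LG", 15, 50),
    SOL = mk("SOL", 12, 52),
    TA = mk("TA", 58, 10),
    VL = mk("VL", 92, 18),
    VM = mk("VM", 92, 18),
    RF = mk("RF", c(94, 54), c(12, 68), c(1, 0.7)),
    ST = mk("ST", 82, 8),
    BF = mk("BF", 84, 10),
    GMAX = mk("GMAX", 94, 22),
    GMED = mk("GMED", 95, 28)
  )
}

# Wrapped Gaussian bump on the 0-100% grid.
pctBump <- function(center, width) {
  p <- 0:100
  d <- pmin(abs(p - center), 100 - abs(p - center))
  exp(-0.5 * (d / width)^2)
}

#' Default sagittal joint-angle waveforms
#'
#' Gait-like hip, knee and ankle flexion-extension templates on the
#' 0-100% grid, affinely scaled to the requested ranges of motion
#' (defaults: control-group values 35.4, 53.7 and 27.3 degrees).
#'
#' @param rom named vector of ranges of motion in degrees for hip, knee,
#'   ankle.
#' @return named list of 101-node numeric vectors (degrees).
#' @export
defaultAngleWaveforms <- function(rom = c(hip = 35.4, knee = 53.7,
                                          ankle = 27.3)) {
  p <- 0:100
  scaleTo <- function(shape, romJ, minVal) {
    s01 <- (shape - min(shape)) / (max(shape) - min(shape))
    s01 * romJ + minVal
  }
  hipShape <- cos(2 * pi * p / 100)
  kneeShape <- 0.05 + 0.25 * pctBump(15, 7) + pctBump(72, 11)
  ankleShape <- 0.55 * pctBump(42, 14) - pctBump(64, 6) - 0.25 * pctBump(6, 4)
  list(
    hip = scaleTo(hipShape, rom[["hip"]], -0.3 * rom[["hip"]]),
    knee = scaleTo(kneeShape, rom[["knee"]], 0),
    ankle = scaleTo(ankleShape, rom[["ankle"]], -0.55 * rom[["ankle"]])
  )
}

# 101-node envelope amplitude template implied by a muscle profile
# (floor outside bursts, peak inside, raised-cosine edges in % units).
burstEnvelopeTemplate <- function(profile, plan, rampMs = 20) {
  p <- 0:100
  env <- rep(profile$noiseFloor, 101L)
  rampPct <- rampMs / 1000 / plan$cycleTimeMean * 100
  if (nrow(profile$bursts) == 0L) return(env)
  for (bi in seq_len(nrow(profile$bursts))) {
    b <- profile$bursts[bi, ]
    span <- (b$offsetPct - b$onsetPct) %% 100
    if (span == 0) span <- 100
    rel <- (p - b$onsetPct) %% 100
    a <- numeric(101L)
    inb <- rel <= span
    a[inb] <- 1
    r <- min(rampPct, span / 2)
    up <- inb & rel < r
    a[up] <- 0.5 * (1 - cos(pi * rel[up] / r))
    dn <- inb & rel > span - r
    a[dn] <- pmin(a[dn], 0.5 * (1 - cos(pi * (span - rel[dn]) / r)))
    env <- pmax(env, profile$noiseFloor + (b$peakAmp - profile$noiseFloor) * a)
  }
  env
}

#' Synthetic two-group dataset of per-subject mean gait cycles
#'
#' For each group, per-subject mean waveforms (EMG envelope templates per
#' muscle and joint-angle curves) are drawn around the group template by
#' adding a smooth Gaussian perturbation (FWHM about 10% of the cycle,
#' matching the smooth-field assumption of the random-field inference)
#' scaled by the between-subject SD. Per-subject temporal scalars are
#' drawn around the plan values. Identical group specifications with
#' zero SD yield a null dataset of identical subjects.
#'
#' @param groupA,groupB lists with elements `profiles` (list of
#'   [muscleProfile()]), `waveforms` (named list of 101-node angle
#'   curves) and `plan` (a [gaitPlan()]).
#' @param nSubjects length-2 vector, subjects per group (each >= 2).
#' @param betweenSubjectSd list with `emg` (normalized envelope units)
#'   and `angleDeg` (degrees).
#' @param scalarSd list of SDs for `cycleTime` (s), `cv` (%),
#'   `stance` (%).
#' @param fwhmPct smoothness of the subject perturbation in % cycle.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return list with elements `A` and `B`; each holds `emg` (named list
#'   of subjects x 101 matrices), `angles` (same for joints), and
#'   `scalars` (data.frame with cycleTime, cycleTimeCv, stancePct,
#'   velocity).
#' @export
simulateGroupDataset <- function(groupA, groupB, nSubjects = c(13, 14),
                                 betweenSubjectSd = list(emg = 0.08,
                                                         angleDeg = 3),
                                 scalarSd = list(cycleTime = 0.1, cv = 0.6,
                                                 stance = 3.4),
                                 fwhmPct = 10, seed = NULL) {
  if (any(nSubjects < 2)) stop("at least 2 subjects per group are required")
  if (!is.null(seed)) set.seed(seed)
  makeGroup <- function(gs, n) {
    emgT <- lapply(gs$profiles, burstEnvelopeTemplate, plan = gs$plan)
    drawMat <- function(template, sdv) {
      pert <- if (sdv > 0) sdv * smoothGaussianField(n, 101L, fwhmPct) else {
        matrix(0, n, 101L)
      }
      sweep(pert, 2L, template, "+")
    }
    emg <- lapply(emgT, function(tp) pmax(drawMat(tp, betweenSubjectSd$emg), 0))
    angles <- lapply(gs$waveforms, function(wv)
      drawMat(wv, betweenSubjectSd$angleDeg))
    ct <- stats::rnorm(n, gs$plan$cycleTimeMean, scalarSd$cycleTime)
    cv <- pmax(stats::rnorm(n, gs$plan$cycleTimeCv, scalarSd$cv), 0)
    st <- stats::rnorm(n, gs$plan$stanceFraction, scalarSd$stance)
    scal <- data.frame(cycleTime = ct, cycleTimeCv = cv, stancePct = st,
                       velocity = gs$plan$walkDistance /
                         (gs$plan$nCycles * ct))
    list(emg = emg, angles = angles, scalars = scal)
  }
  list(A = makeGroup(groupA, nSubjects[1L]),
       B = makeGroup(groupB, nSubjects[2L]))
}

#' Simulate a complete gait session
#'
#' One subject's synchronized recording: eleven EMG channels plus a heel
#' footswitch at the EMG rate, and four quaternion streams (pelvis,
#' thigh, shank, foot) at the inertial rate, both driven by a single
#' realization of the gait plan. The quaternion streams start with a
#' neutral standing window for sensor calibration; the shank orientation
#' integrates the angular-velocity template carrying the gait events,
#' and the remaining segments are built so the relative segment
#' rotations reproduce the prescribed hip, knee and ankle waveforms.
#'
#' @param profiles named list of [muscleProfile()] objects.
#' @param waveforms named list (hip, knee, ankle) of 101-node angle
#'   curves in degrees.
#' @param plan a [gaitPlan()].
#' @param fsEmg,fsImu sampling rates in Hz.
#' @param seed RNG seed.
#' @param calS neutral standing lead-in in seconds.
#' @return list of class `GaitSession` with `emg` ([EmgSession-class]),
#'   `imu` (named list of [QuaternionStream-class]), and `truth`
#'   (heel strikes and toe-offs on both timebases, per-muscle burst
#'   windows, plan, waveforms).
#' @export
simulateSession <- function(profiles = defaultMuscleProfiles(),
                            waveforms = defaultAngleWaveforms(),
                            plan = gaitPlan(), fsEmg = 1500, fsImu = 75,
                            seed = 1, calS = 12) {
  set.seed(seed)
  dur <- drawCycleTimes(plan)
  rcEmg <- cyclesToEvents(dur, plan$stanceFraction, fsEmg, calS)
  rcImu <- cyclesToEvents(dur, plan$stanceFraction, fsImu, calS)
  # EMG timebase ----------------------------------------------------
  fsw <- footswitchFromEvents(rcEmg, plan$nCycles, fsEmg)
  chans <- list()
  truthBursts <- list()
  for (nm in names(profiles)) {
    ch <- emgChannelFromCycles(profiles[[nm]], rcEmg, plan$nCycles, fsEmg)
    chans[[nm]] <- ch$signal
    truthBursts[[nm]] <- ch$trueBursts
  }
  len <- min(c(lengths(chans), length(fsw$signal)))
  mat <- do.call(rbind, lapply(chans, function(x) x[seq_len(len)]))
  emg <- EmgSession(mat, fsEmg, names(profiles),
                    footswitch = fsw$signal[seq_len(len)])
  # IMU timebase ----------------------------------------------------
  gy <- shankGyroFromEvents(rcImu, plan, fsImu)
  nImu <- length(gy$gyro)
  shankAng <- cumsum(gy$gyro) / fsImu
  rampN <- round(0.5 * fsImu)
  hipT <- waveformPerSample(waveforms$hip, rcImu$hs, nImu, rampN)
  kneeT <- waveformPerSample(waveforms$knee, rcImu$hs, nImu, rampN)
  ankleT <- waveformPerSample(waveforms$ankle, rcImu$hs, nImu, rampN)
  # segment z-angles consistent with the joint definitions:
  # hip = thigh - pelvis, knee = -(shank - thigh), ankle = foot - shank
  thighAng <- shankAng + kneeT
  pelvisAng <- thighAng - hipT
  footAng <- shankAng + ankleT
  mkStream <- function(ang, site) {
    QuaternionStream(quatFromZRotation(ang), fsImu, site)
  }
  imu <- list(pelvis = mkStream(pelvisAng, "pelvis"),
              thigh = mkStream(thighAng, "thigh"),
              shank = mkStream(shankAng, "shank"),
              foot = mkStream(footAng, "foot"))
  truth <- list(
    emgHeelStrikes = fsw$heelStrikes, emgToeOffs = fsw$toeOffs,
    imuHeelStrikes = gy$heelStrikes, imuToeOffs = gy$toeOffs,
    bursts = truthBursts, plan = plan, waveforms = waveforms,
    calS = calS, seed = seed)
  structure(list(emg = emg, imu = imu, truth = truth),
            class = "GaitSession")
}
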
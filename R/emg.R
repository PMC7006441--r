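#' Band-pass filter a raw EMG channel
#'
#' Fifth-order Butterworth band-pass (20-500 Hz by default), applied
#' forward-backward so the net filter is zero-phase and burst timing is
#' preserved. The stated order is the design order per pass.
#'
#' @param x numeric vector, raw EMG samples.
#' @param fs sampling rate in Hz; must exceed twice the upper band edge.
#' @param low,high band edges in Hz.
#' @param order Butterworth design order per pass.
#' @return filtered vector of the same length.
#' @export
bandpassEmg <- function(x, fs, low = 20, high = 500, order = 5) {
  if (fs <= 2 * high) {
    stop("sampling rate must exceed twice the upper band edge (", 2 * high,
         " Hz)")
  }
  zeroPhaseButter(x, fs, c(low, high), order, "pass")
}

#' EMG amplitude envelope
#'
#' Rectifies the band-passed EMG as the magnitude of its analytic signal
#' and smooths with a zero-phase low-pass Butterworth filter at 6 Hz.
#' Tiny negative values produced by the smoothing are clipped to zero so
#' the envelope is non-negative everywhere.
#'
#' @param x band-passed EMG vector.
#' @param fs sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz.
#' @param order low-pass design order per pass.
#' @return non-negative envelope vector of the same length.
#' @export
emgEnvelope <- function(x, fs, cutoff = 6, order = 4) {
  if (length(x) == 0L) stop("empty input")
  rectified <- Mod(analyticSignal(x))
  env <- zeroPhaseButter(rectified, fs, cutoff, order, "low")
  pmax(env, 0)
}

#' Rectify an EMG channel via the analytic signal
#'
#' The per-sample instantaneous amplitude (analytic-signal magnitude) of a
#' band-passed channel. This unsmoothed rectified signal is the input to
#' burst detection; [emgEnvelope()] adds the 6 Hz smoothing used for
#' amplitude analysis.
#'
#' @param x band-passed EMG vector.
#' @return non-negative vector of the same length.
#' @export
rectifyEmg <- function(x) {
  if (length(x) == 0L) stop("empty input")
  Mod(analyticSignal(x))
}

#' Split a per-sample series into gait cycles
#'
#' Cycle `k` spans samples `[HS_k, HS_{k+1})`; the number of cycles is one
#' less than the number of heel strikes. With `inclusive = TRUE` each
#' cycle also carries the next heel-strike sample, so that node 100 of a
#' time-normalized cycle falls exactly on the next heel strike; this
#' matters at low sampling rates (kinematics), where the half-open
#' convention skews the normalized time axis by one sample per cycle.
#'
#' @param x numeric vector sampled synchronously with the heel strikes.
#' @param heelStrikes strictly increasing heel-strike sample indices
#'   (at least two).
#' @param inclusive include the closing heel-strike sample in each cycle.
#' @return list of numeric vectors, one per cycle.
#' @export
segmentCycles <- function(x, heelStrikes, inclusive = FALSE) {
  hs <- as.numeric(heelStrikes)
  if (length(hs) < 2L) stop("at least two heel strikes are required")
  if (is.unsorted(hs, strictly = TRUE)) {
    stop("heel strikes must be strictly increasing")
  }
  if (hs[1L] < 1 || hs[length(hs)] - 1 > length(x)) {
    stop("heel strikes outside the recording")
  }
  end <- if (inclusive) 0L else 1L
  lapply(seq_len(length(hs) - 1L), function(k) x[hs[k]:(hs[k + 1L] - end)])
}

#' Time-normalize one gait cycle to the 0-100% grid
#'
#' Linear interpolation of a cycle onto a fixed grid of 101 nodes
#' (0, 1, ..., 100 % of the gait cycle). Node 0 is the first sample of the
#' cycle and node 100 the last.
#'
#' @param cycle numeric vector of at least 2 samples.
#' @param nNodes grid length (101 by default).
#' @return numeric vector of length `nNodes`.
#' @export
timeNormalize <- function(cycle, nNodes = 101) {
  if (length(cycle) < 2L) stop("a cycle must contain at least 2 samples")
  grid <- seq(0, 100, length.out = nNodes)
  stats::approx(x = seq(0, 100, length.out = length(cycle)), y = cycle,
                xout = grid)$y
}

# Coerce a list of equal-length node series, or a matrix, to a
# cycles x nodes matrix.
asCycleMatrix <- function(cycles) {
  if (is.matrix(cycles)) return(cycles)
  if (!is.list(cycles) || length(cycles) == 0L) {
    stop("cycles must be a non-empty list or matrix")
  }
  len <- lengths(cycles)
  if (length(unique(len)) != 1L) stop("cycles must share one grid")
  do.call(rbind, cycles)
}

#' Amplitude-normalize a subject's gait cycles for one muscle
#'
#' Divides all cycles by a single subject-level reference: with
#' `mode = "max"`, the maximum over all included cycles (so the global
#' maximum becomes 1); with `mode = "median"`, the median of the per-cycle
#' maxima (a robust alternative less sensitive to a single outlier cycle).
#'
#' @param cycles cycles x nodes matrix (or list of node series) of
#'   time-normalized envelopes for one muscle of one subject.
#' @param mode `"max"` or `"median"`.
#' @return list with `cycles` (normalized matrix) and `reference`
#'   (the divisor).
#' @export
amplitudeNormalize <- function(cycles, mode = c("max", "median")) {
  mode <- match.arg(mode)
  m <- asCycleMatrix(cycles)
  perCycleMax <- apply(m, 1L, max)
  ref <- switch(mode, max = max(perCycleMax),
                median = stats::median(perCycleMax))
  if (!is.finite(ref) || ref <= 0) {
    stop("all-zero normalization reference: dead channel")
  }
  list(cycles = m / ref, reference = ref)
}

#' Node-wise mean of time-normalized cycles
#'
#' @param cycles cycles x nodes matrix or list of equal-length node series.
#' @return numeric vector, the mean cycle.
#' @export
meanCycle <- function(cycles) {
  m <- asCycleMatrix(cycles)
  colMeans(m)
}
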
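#' @import methods
NULL

#' Multi-channel surface EMG recording
#'
#' Container for a raw surface-EMG session: one row per muscle, one column
#' per sample, with an optional synchronized binary heel footswitch channel.
#'
#' @slot channels numeric matrix, muscles x samples, arbitrary units.
#' @slot fs sampling rate in Hz.
#' @slot muscleLabels character vector of unique muscle labels
#'   (row names of `channels`).
#' @slot footswitch numeric vector of 0/1 heel-contact states, either empty
#'   or one value per sample.
#' @export
setClass("EmgSession",
  representation(
    channels = "matrix",
    fs = "numeric",
    muscleLabels = "character",
    footswitch = "numeric"
  )
)

setValidity("EmgSession", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (nrow(object@channels) != length(object@muscleLabels)) {
    msg <- c(msg, "one label per channel row required")
  }
  if (anyDuplicated(object@muscleLabels)) {
    msg <- c(msg, "muscle labels must be unique")
  }
  if (length(object@footswitch) > 0 &&
      length(object@footswitch) != ncol(object@channels)) {
    msg <- c(msg, "footswitch must have one value per sample")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EmgSession
#'
#' @param channels muscles x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param muscleLabels unique labels, one per row; defaults to the row
#'   names of `channels`.
#' @param footswitch optional binary heel-contact channel.
#' @return an [EmgSession-class] object.
#' @export
EmgSession <- function(channels, fs, muscleLabels = rownames(channels),
                       footswitch = numeric()) {
  channels <- as.matrix(channels)
  if (is.null(muscleLabels)) stop("muscleLabels required")
  rownames(channels) <- muscleLabels
  new("EmgSession", channels = channels, fs = as.numeric(fs),
      muscleLabels = as.character(muscleLabels),
      footswitch = as.numeric(footswitch))
}

#' Quaternion orientation stream from one inertial sensor
#'
#' @slot q numeric matrix, samples x 4, columns (w, x, y, z), each row a
#'   unit quaternion.
#' @slot fs sampling rate in Hz.
#' @slot sensorSite one of pelvis, thigh, shank, foot.
#' @export
setClass("QuaternionStream",
  representation(q = "matrix", fs = "numeric", sensorSite = "character")
)

setValidity("QuaternionStream", function(object) {
  msg <- character()
  if (ncol(object@q) != 4L) msg <- c(msg, "q must have 4 columns (w,x,y,z)")
  else {
    nrm <- sqrt(rowSums(object@q^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      msg <- c(msg, "quaternions must have unit norm (tolerance 1e-6)")
    }
  }
  if (length(object@fs) != 1L || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QuaternionStream
#'
#' @param q samples x 4 matrix of unit quaternions (w, x, y, z).
#' @param fs sampling rate (Hz).
#' @param sensorSite sensor location label.
#' @return a [QuaternionStream-class] object.
#' @export
QuaternionStream <- function(q, fs, sensorSite = "unknown") {
  new("QuaternionStream", q = as.matrix(q), fs = as.numeric(fs),
      sensorSite = as.character(sensorSite))
}

#' Detected EMG activity intervals for one muscle
#'
#' Intervals are half-open sample ranges `[onset, offset)`, sorted and
#' disjoint.
#'
#' @slot intervals integer matrix, bursts x 2, columns onset and offset.
#' @slot muscleLabel muscle name.
#' @slot fs sampling rate in Hz.
#' @export
setClass("BurstTrain",
  representation(intervals = "matrix", muscleLabel = "character",
                 fs = "numeric")
)

setValidity("BurstTrain", function(object) {
  iv <- object@intervals
  msg <- character()
  if (ncol(iv) != 2L) msg <- c(msg, "intervals must have 2 columns")
  if (nrow(iv) > 0) {
    if (any(iv[, 2L] <= iv[, 1L])) msg <- c(msg, "onset must precede offset")
    if (nrow(iv) > 1 && any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) {
      msg <- c(msg, "intervals must be sorted and disjoint")
    }
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a BurstTrain
#'
#' @param intervals bursts x 2 matrix of `[onset, offset)` sample indices.
#' @param muscleLabel muscle name.
#' @param fs sampling rate (Hz).
#' @return a [BurstTrain-class] object.
#' @export
BurstTrain <- function(intervals, muscleLabel = "unknown", fs) {
  intervals <- matrix(as.numeric(intervals), ncol = 2L,
                      dimnames = list(NULL, c("onset", "offset")))
  new("BurstTrain", intervals = intervals,
      muscleLabel = as.character(muscleLabel), fs = as.numeric(fs))
}

#' Gait events detected from shank angular velocity
#'
#' @slot heelStrikes integer sample indices of heel strikes.
#' @slot toeOffs integer sample indices of toe-offs; each lies strictly
#'   between two consecutive heel strikes.
#' @slot fs sampling rate in Hz.
#' @export
setClass("GaitEvents",
  representation(heelStrikes = "numeric", toeOffs = "numeric",
                 fs = "numeric")
)

setValidity("GaitEvents", function(object) {
  hs <- object@heelStrikes
  to <- object@toeOffs
  msg <- character()
  if (is.unsorted(hs, strictly = TRUE)) {
    msg <- c(msg, "heel strikes must be strictly increasing")
  }
  if (length(to) > 0) {
    if (is.unsorted(to, strictly = TRUE)) {
      msg <- c(msg, "toe-offs must be strictly increasing")
    }
    ok <- vapply(to, function(t)
      any(hs[-length(hs)] < t & t < hs[-1L]), logical(1))
    if (length(hs) >= 2 && !all(ok)) {
      msg <- c(msg, "each toe-off must fall strictly between two heel strikes")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GaitEvents object
#'
#' @param heelStrikes heel-strike sample indices (strictly increasing).
#' @param toeOffs toe-off sample indices, each strictly inside a stride.
#' @param fs sampling rate (Hz).
#' @return a [GaitEvents-class] object.
#' @export
GaitEvents <- function(heelStrikes, toeOffs = numeric(), fs) {
  new("GaitEvents", heelStrikes = as.numeric(heelStrikes),
      toeOffs = as.numeric(toeOffs), fs = as.numeric(fs))
}

#' Calibrated sagittal joint-angle track
#'
#' @slot angle degrees per sample; flexion (hip/knee) and dorsi-flexion
#'   (ankle) positive.
#' @slot joint one of hip, knee, ankle.
#' @slot fs sampling rate in Hz.
#' @export
setClass("JointAngleTrack",
  representation(angle = "numeric", joint = "character", fs = "numeric")
)

setValidity("JointAngleTrack", function(object) {
  if (any(!is.finite(object@angle))) return("angles must be finite")
  if (object@fs <= 0) return("fs must be positive")
  TRUE
})

#' Construct a JointAngleTrack
#'
#' @param angle degrees per sample.
#' @param joint joint name.
#' @param fs sampling rate (Hz).
#' @return a [JointAngleTrack-class] object.
#' @export
JointAngleTrack <- function(angle, joint = "unknown", fs) {
  new("JointAngleTrack", angle = as.numeric(angle),
      joint = as.character(joint), fs = as.numeric(fs))
}

#' Result of a one-dimensional SPM two-sample t-test
#'
#' @slot tCurve pointwise t statistic over the gait-cycle grid.
#' @slot df degrees of freedom.
#' @slot fwhm estimated field smoothness (full-width-at-half-maximum, nodes).
#' @slot tCrit random-field critical threshold.
#' @slot alpha family-wise significance level.
#' @slot clusters data.frame with one row per supra-threshold cluster:
#'   `start`, `end` (node indices, 0-100), `extent` (nodes), `p`
#'   (cluster-specific p-value), `meanD` (mean Cohen's d over the cluster).
#' @slot maskedNodes node indices (0-100) excluded for zero pooled variance.
#' @export
setClass("SpmResult",
  representation(tCurve = "numeric", df = "numeric", fwhm = "numeric",
                 tCrit = "numeric", alpha = "numeric",
                 clusters = "data.frame", maskedNodes = "numeric")
)

setValidity("SpmResult", function(object) {
  msg <- character()
  if (object@tCrit <= 0) msg <- c(msg, "tCrit must be positive")
  if (nrow(object@clusters) > 0 &&
      any(object@clusters$p <= 0 | object@clusters$p > 1)) {
    msg <- c(msg, "cluster p-values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
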
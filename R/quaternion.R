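# Quaternion algebra on samples x 4 matrices, columns (w, x, y, z).
# Hamilton convention, right-handed axes: x anteroposterior, y vertical,
# z mediolateral, so sagittal-plane rotation is about z.

#' Quaternion product
#'
#' Row-wise Hamilton product `a * b`. Either argument may be a single
#' quaternion (length-4 vector), which is recycled.
#'
#' @param a,b quaternion matrices (n x 4, columns w,x,y,z) or length-4
#'   vectors.
#' @return n x 4 quaternion matrix.
#' @export
quatMultiply <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 4L, nrow = NROW(b), byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 4L, nrow = nrow(a), byrow = TRUE)
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w = w, x = x, y = y, z = z)
}

#' Quaternion conjugate
#' @param q quaternion matrix or length-4 vector.
#' @return object of the same shape.
#' @export
quatConjugate <- function(q) {
  if (is.null(dim(q))) return(c(q[1], -q[2:4]))
  cbind(w = q[, 1], x = -q[, 2], y = -q[, 3], z = -q[, 4])
}

#' Quaternion for a rotation about the mediolateral (z) axis
#' @param angleDeg rotation angle(s) in degrees.
#' @return n x 4 quaternion matrix.
#' @export
quatFromZRotation <- function(angleDeg) {
  h <- angleDeg * pi / 180 / 2
  cbind(w = cos(h), x = 0 * h, y = 0 * h, z = sin(h))
}

# Rotation matrix from one unit quaternion.
quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Euler angles from quaternion orientations
#'
#' Intrinsic Z-Y-X decomposition in degrees. With z the mediolateral
#' axis, the first (z) angle is the sagittal-plane segment angle. A
#' warning is emitted near gimbal lock (|y rotation| > 85 deg), where the
#' z and x angles become poorly conditioned.
#'
#' @param q a [QuaternionStream-class] or an n x 4 quaternion matrix.
#' @return n x 3 matrix with columns `z`, `y`, `x` in degrees.
#' @export
quatToEuler <- function(q) {
  if (is(q, "QuaternionStream")) q <- quaternions(q)
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  r21 <- 2 * (x * y + w * z)
  r11 <- 1 - 2 * (y^2 + z^2)
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  zAng <- atan2(r21, r11) * 180 / pi
  yAng <- -asin(pmin(pmax(r31, -1), 1)) * 180 / pi
  xAng <- atan2(r32, r33) * 180 / pi
  if (any(abs(yAng) > 85)) {
    warning("orientation near gimbal lock (|pitch| > 85 deg); ",
            "sagittal angle may be ill-conditioned")
  }
  cbind(z = zAng, y = yAng, x = xAng)
}

# Sign-aligned normalized arithmetic mean of unit quaternions; adequate
# for the small spread of a static calibration window.
quatMean <- function(q) {
  ref <- q[1L, ]
  sgn <- sign(q %*% ref)
  sgn[sgn == 0] <- 1
  m <- colMeans(q * as.numeric(sgn))
  m / sqrt(sum(m^2))
}

# Angle (degrees) of the relative rotation between two unit quaternions.
quatAngleBetween <- function(a, b) {
  d <- abs(sum(a * b))
  2 * acos(pmin(d, 1)) * 180 / pi
}

#' Sensor-to-segment neutral calibration
#'
#' Estimates the reference orientation of a sensor from a window in which
#' the subject stands still in a neutral position. The reference is the
#' normalized quaternion mean over the window. Motion is screened by the
#' drift rate between the mean orientations of the two window halves
#' (robust to sample-level orientation noise); calibration fails when the
#' drift exceeds `motionThreshold`.
#'
#' @param stream a [QuaternionStream-class].
#' @param windowS calibration window length in seconds, from the start of
#'   the stream.
#' @param motionThreshold maximum tolerated drift rate in deg/s.
#' @return unit quaternion (length-4 vector), the reference orientation.
#' @export
calibrateNeutral <- function(stream, windowS = 10, motionThreshold = 5) {
  q <- quaternions(stream)
  fs <- samplingRate(stream)
  nWin <- min(nrow(q), max(2L, round(windowS * fs)))
  qw <- q[seq_len(nWin), , drop = FALSE]
  half <- nWin %/% 2L
  m1 <- quatMean(qw[seq_len(half), , drop = FALSE])
  m2 <- quatMean(qw[(half + 1L):nWin, , drop = FALSE])
  drift <- quatAngleBetween(m1, m2) / (half / fs)
  if (drift > motionThreshold) {
    stop(sprintf("motion during calibration window (%.1f deg/s > %g deg/s)",
                 drift, motionThreshold))
  }
  quatMean(qw)
}

#' Orientation relative to a calibration reference
#'
#' Left-multiplies the stream by the conjugate of the reference so that
#' the neutral stance maps to the identity and subsequent Euler angles
#' are zero-based.
#'
#' @param stream a [QuaternionStream-class].
#' @param reference unit quaternion from [calibrateNeutral()].
#' @return a [QuaternionStream-class] of relative orientations.
#' @export
relativeOrientation <- function(stream, reference) {
  q <- quatMultiply(quatConjugate(reference), quaternions(stream))
  q <- q / sqrt(rowSums(q^2))
  QuaternionStream(q, samplingRate(stream), sensorSite(stream))
}

#' Angular velocity about the mediolateral axis
#'
#' Finite-difference z-axis angular velocity of a quaternion stream in
#' deg/s, the signal used for gait-event detection from the shank sensor.
#'
#' @param stream a [QuaternionStream-class].
#' @return numeric vector (deg/s), same length as the stream.
#' @export
angularVelocityZ <- function(stream) {
  q <- quaternions(stream)
  fs <- samplingRate(stream)
  n <- nrow(q)
  if (n < 2L) stop("stream too short")
  dq <- quatMultiply(quatConjugate(q[-n, , drop = FALSE]),
                     q[-1L, , drop = FALSE])
  # small-angle rotation vector: 2 * vector part * sign(w)
  wz <- 2 * dq[, 4] * sign(dq[, 1]) * fs * 180 / pi
  c(wz[1L], wz)
}
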
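#' Analytic signal of a real-valued series
#'
#' Computes the complex analytic signal by one-sided spectrum doubling in
#' the frequency domain. Its magnitude is the instantaneous amplitude
#' envelope used for EMG rectification.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analyticSignal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase Butterworth filtering (forward-backward). `order` is the
# design order per pass; the effective attenuation is doubled. The
# signal is extended by odd reflection about its endpoints before
# filtering so edge transients decay inside the padding, not the data.
zeroPhaseButter <- function(x, fs, cutoff, order, type) {
  if (any(!is.finite(x))) stop("non-finite values in input signal")
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  n <- length(x)
  # transients of the lowest band edge dominate; pad a few of its periods
  pad <- min(n - 1L, max(50L, ceiling(12 * fs / min(cutoff))))
  if (pad > 0L) {
    head <- 2 * x[1L] - x[(pad + 1L):2L]
    tail <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(head, x, tail))
    as.numeric(y[(pad + 1L):(pad + n)])
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Smooth Gaussian random field on a 1D grid
#'
#' White Gaussian noise convolved with a Gaussian kernel of the requested
#' full-width-at-half-maximum, scaled to unit pointwise variance. Used for
#' between-subject waveform variation and for Monte-Carlo validation of
#' the random-field inference.
#'
#' @param n number of independent field realizations (rows).
#' @param nNodes field length in nodes.
#' @param fwhm smoothness as full-width-at-half-maximum, in nodes.
#' @return `n` x `nNodes` numeric matrix.
#' @export
smoothGaussianField <- function(n, nNodes, fwhm) {
  stopifnot(n >= 1, nNodes >= 2, fwhm > 0)
  sdk <- fwhm / sqrt(8 * log(2))
  pad <- ceiling(4 * sdk)
  kern <- stats::dnorm(seq(-pad, pad), sd = sdk)
  kern <- kern / sqrt(sum(kern^2))
  w <- matrix(stats::rnorm(n * (nNodes + 2 * pad)), nrow = n)
  out <- t(apply(w, 1L, function(r) stats::convolve(r, kern, type = "filter")))
  out[, seq_len(nNodes), drop = FALSE]
}

# Circular mean of values expressed in percent of a cycle (period 100).
circularMeanPct <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  ang <- 2 * pi * x / 100
  m <- Arg(mean(exp(1i * ang))) / (2 * pi) * 100
  m %% 100
}

# Maximal runs of TRUE in a logical vector as an m x 2 matrix of
# [start, end+1) sample indices.
logicalRuns <- function(active) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(onset = starts[keep], offset = ends[keep] + 1L)
}
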
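#' Exact one-dimensional k-means clustering
#'
#' Globally optimal k-means in one dimension. Optimal 1D clusters are
#' contiguous intervals of the sorted values, so the minimum
#' within-cluster sum of squares is found exactly by dynamic programming
#' over contiguous partitions (divide-and-conquer over the monotone
#' optimal split positions, O(k n log n)). The result is deterministic
#' and independent of any initialization.
#'
#' @param x numeric vector with at least `k` distinct values.
#' @param k number of clusters.
#' @return list with `centers` (ascending cluster means), `labels`
#'   (cluster index per element of `x`, 1 = lowest cluster) and
#'   `withinss` (total within-cluster sum of squares).
#' @export
kmeans1d <- function(x, k = 3) {
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (length(unique(x)) < k) {
    stop("fewer than k distinct values: clustering is degenerate")
  }
  ord <- order(x)
  xs <- x[ord]
  S1 <- c(0, cumsum(xs))
  S2 <- c(0, cumsum(xs^2))
  segCost <- function(j, i) {
    # SSE of xs[j..i] (vectorized over j)
    s <- S1[i + 1L] - S1[j]
    q <- S2[i + 1L] - S2[j]
    q - s^2 / (i - j + 1)
  }
  D <- matrix(Inf, nrow = k, ncol = n)
  J <- matrix(NA_integer_, nrow = k, ncol = n)
  D[1L, ] <- segCost(1L, seq_len(n))
  J[1L, ] <- 1L
  for (cl in 2:k) {
    Dprev <- D[cl - 1L, ]
    # divide & conquer over rows i with monotone argmin j
    stack <- list(c(cl, n, cl, n))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ilo <- fr[1L]; ihi <- fr[2L]; jlo <- fr[3L]; jhi <- fr[4L]
      if (ilo > ihi) next
      mid <- (ilo + ihi) %/% 2L
      js <- jlo:min(jhi, mid)
      vals <- Dprev[js - 1L] + segCost(js, mid)
      best <- which.min(vals)
      D[cl, mid] <- vals[best]
      jb <- js[best]
      J[cl, mid] <- jb
      stack[[length(stack) + 1L]] <- c(ilo, mid - 1L, jlo, jb)
      stack[[length(stack) + 1L]] <- c(mid + 1L, ihi, jb, jhi)
    }
  }
  # backtrack segment boundaries in sorted order
  bounds <- integer(k + 1L)
  bounds[k + 1L] <- n
  i <- n
  for (cl in k:2) {
    j <- J[cl, i]
    bounds[cl] <- j - 1L
    i <- j - 1L
  }
  bounds[1L] <- 0L
  labSorted <- rep.int(seq_len(k), diff(bounds))
  labels <- integer(n)
  labels[ord] <- labSorted
  centers <- vapply(seq_len(k), function(cl) mean(xs[(bounds[cl] + 1L):bounds[cl + 1L]]),
                    numeric(1))
  list(centers = centers, labels = labels, withinss = D[k, n])
}

#' Detect EMG activity intervals by k-means clustering
#'
#' Clusters the per-sample rectified (analytic-magnitude) amplitudes into
#' `k = 3` groups; the lowest cluster reflects inactivity and a sample is
#' active when it belongs to either of the two upper clusters. Maximal
#' runs of active samples become burst intervals. Feed the result to
#' [cleanBursts()] to apply the minimum-duration and gap-merge rules.
#'
#' @param x non-negative rectified EMG vector (see [rectifyEmg()]); a
#'   configuration switch upstream may substitute the smoothed envelope.
#' @param fs sampling rate in Hz.
#' @param muscleLabel label stored in the result.
#' @param k number of amplitude clusters.
#' @return a [BurstTrain-class]; empty, with a warning, for a silent
#'   channel that cannot support `k` clusters.
#' @export
detectActivity <- function(x, fs, muscleLabel = "unknown", k = 3) {
  if (any(x < 0)) stop("rectified signal must be non-negative")
  if (length(unique(x)) < k) {
    warning("silent channel: fewer than ", k,
            " distinct amplitudes, no bursts detected")
    return(BurstTrain(matrix(numeric(0), ncol = 2L), muscleLabel, fs))
  }
  km <- kmeans1d(x, k)
  active <- km$labels >= 2L
  if (!any(active)) {
    return(BurstTrain(matrix(numeric(0), ncol = 2L), muscleLabel, fs))
  }
  BurstTrain(logicalRuns(active), muscleLabel, fs)
}

#' Apply burst cleaning rules
#'
#' Two rules, applied in this order: (1) every burst shorter than
#' `minDuration` (5 ms) is discarded; (2) bursts separated by a gap
#' shorter than `maxGap` (125 ms) are merged into one burst. Because
#' discarding precedes merging, two sub-threshold bursts close together
#' are removed rather than merged. The operation is idempotent.
#'
#' @param train a [BurstTrain-class].
#' @param minDuration minimum burst duration in seconds.
#' @param maxGap gaps strictly shorter than this (seconds) are merged.
#' @return cleaned [BurstTrain-class].
#' @export
cleanBursts <- function(train, minDuration = 0.005, maxGap = 0.125) {
  iv <- intervals(train)
  fs <- samplingRate(train)
  if (nrow(iv) == 0L) return(train)
  keep <- (iv[, 2L] - iv[, 1L]) / fs >= minDuration
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) > 1L) {
    merged <- iv[1L, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      gap <- (iv[i, 1L] - merged[nrow(merged), 2L]) / fs
      if (gap < maxGap) {
        merged[nrow(merged), 2L] <- iv[i, 2L]
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
    iv <- merged
  }
  BurstTrain(iv, train@muscleLabel, fs)
}

#' Per-cycle burst timing in percent of the gait cycle
#'
#' For each gait cycle the primary burst is the longest interval
#' overlapping the cycle; its onset and offset are expressed in % of that
#' cycle. A burst spanning the heel strike reports its onset in late %
#' and offset in early %, and the across-cycle means of onset and offset
#' are circular (period 100) so wrapped timings average correctly.
#' Duration is averaged arithmetically. Optionally a second burst is
#' reported when a distinct interval lies in the stance-to-swing
#' transition window (used for rectus femoris).
#'
#' @param train a cleaned [BurstTrain-class].
#' @param heelStrikes heel-strike sample indices delimiting the cycles.
#' @param secondBurstWindow numeric length-2 window in % cycle within
#'   which a distinct second burst is reported, or `NULL` to disable.
#' @return list with `perCycle` (data.frame: cycle, onsetPct, offsetPct,
#'   durationPct, and second-burst columns when enabled) and `summary`
#'   (named vector of wrap-aware means; cycles without a burst are
#'   excluded).
#' @export
cycleTiming <- function(train, heelStrikes, secondBurstWindow = NULL) {
  hs <- as.numeric(heelStrikes)
  if (length(hs) < 2L) stop("at least one full cycle is required")
  iv <- intervals(train)
  nC <- length(hs) - 1L
  res <- data.frame(cycle = seq_len(nC), onsetPct = NA_real_,
                    offsetPct = NA_real_, durationPct = NA_real_)
  withSecond <- !is.null(secondBurstWindow)
  if (withSecond) {
    res$onset2Pct <- NA_real_
    res$offset2Pct <- NA_real_
  }
  for (k in seq_len(nC)) {
    lo <- hs[k]; hi <- hs[k + 1L]
    len <- hi - lo
    ov <- which(iv[, 1L] < hi & iv[, 2L] > lo)
    if (length(ov) == 0L) next
    lens <- iv[ov, 2L] - iv[ov, 1L]
    primary <- ov[which.max(lens)]
    toPct <- function(s) ((s - lo) / len * 100) %% 100
    res$onsetPct[k] <- toPct(iv[primary, 1L])
    res$offsetPct[k] <- toPct(iv[primary, 2L])
    res$durationPct[k] <- min((iv[primary, 2L] - iv[primary, 1L]) / len * 100,
                              100)
    if (withSecond) {
      others <- setdiff(ov, primary)
      if (length(others)) {
        mids <- toPct((iv[others, 1L] + iv[others, 2L]) / 2)
        inWin <- others[mids >= secondBurstWindow[1L] &
                        mids <= secondBurstWindow[2L]]
        if (length(inWin)) {
          second <- inWin[which.max(iv[inWin, 2L] - iv[inWin, 1L])]
          res$onset2Pct[k] <- toPct(iv[second, 1L])
          res$offset2Pct[k] <- toPct(iv[second, 2L])
        }
      }
    }
  }
  summary <- c(
    onsetPct = circularMeanPct(res$onsetPct),
    offsetPct = circularMeanPct(res$offsetPct),
    durationPct = mean(res$durationPct, na.rm = TRUE)
  )
  if (withSecond) {
    summary <- c(summary,
                 onset2Pct = circularMeanPct(res$onset2Pct),
                 offset2Pct = circularMeanPct(res$offset2Pct))
  }
  list(perCycle = res, summary = summary)
}
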
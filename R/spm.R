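# 1D statistical parametric mapping via random field theory (RFT).
# A t statistic is computed at every node of the gait-cycle grid; the
# critical threshold controls the family-wise error over the whole
# correlated curve using the expected Euler characteristic of a smooth
# t-field, with smoothness (FWHM) estimated from the normalized
# residuals.

# 1D Euler-characteristic density of a t-field at height u.
ecDensity1d <- function(u, df) {
  sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

#' Estimate field smoothness from residuals
#'
#' Standard gradient estimator: residual curves are normalized to unit
#' pointwise sum of squares and the FWHM is derived from the mean squared
#' gradient of the normalized residuals.
#'
#' @param residuals subjects x nodes matrix of model residuals.
#' @return FWHM in nodes (`Inf` for constant residuals).
#' @export
estimateFwhm <- function(residuals) {
  R <- as.matrix(residuals)
  ssq <- colSums(R^2)
  grad <- function(r) {
    n <- length(r)
    g <- numeric(n)
    g[1L] <- r[2L] - r[1L]
    g[n] <- r[n] - r[n - 1L]
    g[2:(n - 1L)] <- (r[3:n] - r[1:(n - 2L)]) / 2
    g
  }
  dR <- t(apply(R, 1L, grad))
  v <- colSums(dR^2) / (ssq + .Machine$double.eps)
  v <- v[is.finite(v) & ssq > .Machine$double.eps]
  if (length(v) == 0L || mean(v) <= 0) return(Inf)
  reselsPerNode <- sqrt(v / (4 * log(2)))
  1 / mean(reselsPerNode)
}

#' Random-field critical threshold for a 1D t-field
#'
#' Solves `E[EC(u)] = alpha / tails` for u, where the expected Euler
#' characteristic combines the point tail probability with the
#' 1D EC density scaled by the resel count `(nNodes - 1) / fwhm`. As
#' smoothness grows (resels -> 0) the threshold decreases to the
#' ordinary t quantile.
#'
#' @param df degrees of freedom.
#' @param nNodes field length in nodes.
#' @param fwhm smoothness in nodes.
#' @param alpha family-wise significance level.
#' @param tails 1 or 2.
#' @return the critical threshold t*.
#' @export
rftThreshold <- function(df, nNodes = 101, fwhm, alpha = 0.05, tails = 2) {
  stopifnot(df >= 1, fwhm > 0, alpha > 0, alpha < 1)
  resels <- (nNodes - 1) / fwhm
  target <- alpha / tails
  f <- function(u) {
    stats::pt(u, df, lower.tail = FALSE) + resels * ecDensity1d(u, df) - target
  }
  hi <- 50
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 10  # heavy tails at very low df
  if (f(hi) > 0) stop("no critical threshold found")
  stats::uniroot(f, c(1e-8, hi), tol = 1e-10)$root
}

#' Cluster-specific p-value from cluster extent
#'
#' Random-field survival probability for a supra-threshold cluster of the
#' given extent: the expected number of clusters at the threshold times
#' the tail probability of the cluster-extent distribution
#' (`P(extent >= k) = exp(-beta k^2)` in one dimension, with `beta`
#' matched to the expected cluster extent), combined through the Poisson
#' clumping approximation `p = 1 - exp(-E[m] P(extent >= k))`.
#'
#' @param extent cluster extent in nodes.
#' @param tCrit threshold at which the cluster was defined.
#' @param df degrees of freedom.
#' @param fwhm field smoothness in nodes.
#' @param nNodes field length in nodes.
#' @param tails 1 or 2 (clusters of `|t|` for 2).
#' @return p-value in (0, 1].
#' @export
clusterPvalue <- function(extent, tCrit, df, fwhm, nNodes = 101, tails = 2) {
  if (extent <= 0) return(1)
  if (!is.finite(fwhm)) return(1)
  ec <- ecDensity1d(tCrit, df)
  expectedExtent <- stats::pt(tCrit, df, lower.tail = FALSE) / ec  # resels
  beta <- (gamma(1.5) / expectedExtent)^2
  pExtent <- exp(-beta * (extent / fwhm)^2)
  em <- tails * (nNodes - 1) / fwhm * ec
  p <- 1 - exp(-em * pExtent)
  min(max(p, .Machine$double.xmin), 1)
}

#' Two-sample SPM t-test over gait-cycle waveforms
#'
#' Pointwise two-tailed two-sample t statistic with pooled variance at
#' every node, smoothness estimated from the normalized residuals,
#' random-field critical threshold at the requested alpha, and
#' supra-threshold clusters of `|t|` with cluster-specific p-values and
#' the mean Cohen's d over each cluster. Nodes with zero pooled variance
#' are masked (t set to 0) with a warning.
#'
#' @param groupA,groupB subjects x nodes matrices on a common grid, at
#'   least two subjects each.
#' @param alpha family-wise significance level.
#' @param tails 1 or 2.
#' @return an [SpmResult-class].
#' @export
spmTtest2 <- function(groupA, groupB, alpha = 0.05, tails = 2) {
  A <- as.matrix(groupA)
  B <- as.matrix(groupB)
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("at least two subjects per group are required")
  }
  if (ncol(A) != ncol(B)) stop("groups must share one grid")
  nA <- nrow(A); nB <- nrow(B)
  df <- nA + nB - 2
  mA <- colMeans(A); mB <- colMeans(B)
  RA <- sweep(A, 2L, mA)
  RB <- sweep(B, 2L, mB)
  sp <- sqrt((colSums(RA^2) + colSums(RB^2)) / df)
  masked <- which(sp <= .Machine$double.eps * pmax(abs(mA), abs(mB), 1))
  tt <- numeric(ncol(A))
  ok <- setdiff(seq_len(ncol(A)), masked)
  tt[ok] <- (mA[ok] - mB[ok]) / (sp[ok] * sqrt(1 / nA + 1 / nB))
  if (length(masked)) {
    warning(length(masked), " node(s) masked for zero pooled variance")
  }
  R <- rbind(RA, RB)
  Rn <- sweep(R, 2L, ifelse(sp > 0, sp * sqrt(df), 1), "/")
  fwhm <- estimateFwhm(Rn)
  tc <- if (is.finite(fwhm)) {
    rftThreshold(df, ncol(A), fwhm, alpha, tails)
  } else {
    stats::qt(1 - alpha / tails, df)
  }
  dCurve <- numeric(ncol(A))
  dCurve[ok] <- (mA[ok] - mB[ok]) / sp[ok]
  above <- abs(tt) > tc
  above[masked] <- FALSE
  cl <- data.frame(start = numeric(0), end = numeric(0),
                   extent = numeric(0), p = numeric(0), meanD = numeric(0))
  if (any(above)) {
    runs <- logicalRuns(above)
    cl <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
      s <- runs[i, 1L]; e <- runs[i, 2L] - 1L
      nodes <- s:e
      data.frame(start = s - 1, end = e - 1, extent = length(nodes),
                 p = clusterPvalue(length(nodes), tc, df, fwhm,
                                   ncol(A), tails),
                 meanD = mean(dCurve[nodes]))
    }))
  }
  new("SpmResult", tCurve = tt, df = df, fwhm = fwhm, tCrit = tc,
      alpha = alpha, clusters = cl, maskedNodes = as.numeric(masked - 1))
}

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference `(meanA - meanB) / s_pooled` with the
#' pooled standard deviation
#' `s_pooled^2 = ((nA-1) sdA^2 + (nB-1) sdB^2) / (nA + nB - 2)`.
#' Conventional magnitude labels: small >= 0.2, medium >= 0.5,
#' large >= 0.8.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summary statistics.
#' @return Cohen's d (signed).
#' @export
cohensD <- function(meanA, sdA, nA, meanB, sdB, nB) {
  stopifnot(sdA >= 0, sdB >= 0, nA >= 2, nB >= 2)
  sp <- sqrt(((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (meanA - meanB) / sp
}

#' A priori sample size for a two-sample t-test
#'
#' Smallest per-group n achieving the target power for effect size d in
#' a two-sample t-test, using the noncentral t distribution with
#' `ncp = d * sqrt(n / 2)` and `df = 2n - 2`.
#'
#' @param d Cohen's d (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param tails 1 or 2.
#' @param nMax search bound.
#' @return smallest integer n per group (at least 2).
#' @export
powerNPerGroup <- function(d, alpha = 0.05, power = 0.80, tails = 1,
                           nMax = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  achieved <- function(n) {
    df <- 2 * n - 2
    tc <- stats::qt(1 - alpha / tails, df)
    stats::pt(tc, df, ncp = d * sqrt(n / 2), lower.tail = FALSE)
  }
  n <- 2
  while (n <= nMax) {
    if (achieved(n) >= power) return(as.integer(n))
    n <- n + 1
  }
  stop("target power unreachable within n <= ", nMax)
}

#' Two-group scalar comparison with automatic test selection
#'
#' `kind = "auto"` selects the independent-samples t-test when both
#' groups pass the Shapiro-Wilk normality test at 0.05, and the Wilcoxon
#' rank-sum test otherwise. `kind = "chi2"` compares two proportions
#' given as `c(successes, total)` per group with Yates continuity
#' correction.
#'
#' @param a,b numeric vectors of group values, or `c(successes, total)`
#'   for `kind = "chi2"`.
#' @param kind one of auto, t, ranksum, chi2.
#' @return list with `kind`, `statistic`, `p.value`.
#' @export
compareScalar <- function(a, b, kind = c("auto", "t", "ranksum", "chi2")) {
  kind <- match.arg(kind)
  if (kind == "chi2") {
    tab <- rbind(c(a[1L], a[2L] - a[1L]), c(b[1L], b[2L] - b[1L]))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    return(list(kind = "chi2", statistic = unname(ct$statistic),
                p.value = ct$p.value))
  }
  if (length(a) < 2L || length(b) < 2L) {
    stop("at least two values per group are required")
  }
  if (kind == "auto") {
    normal <- function(x) {
      length(unique(x)) > 1L && stats::shapiro.test(x)$p.value > 0.05
    }
    kind <- if (normal(a) && normal(b)) "t" else "ranksum"
  }
  if (kind == "t") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    list(kind = "t", statistic = unname(tt$statistic), p.value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    list(kind = "ranksum", statistic = unname(wt$statistic),
         p.value = wt$p.value)
  }
}
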
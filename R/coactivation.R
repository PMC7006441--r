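#' Antagonist muscle pairs used for co-contraction analysis
#'
#' Three pairs crossing the ankle and four crossing the knee.
#'
#' @return data.frame with columns `a` and `b` (muscle labels) and
#'   `joint`.
#' @export
antagonistPairs <- function() {
  data.frame(
    a = c("MG", "LG", "SOL", "VL", "VM", "LG", "MG"),
    b = c("TA", "TA", "TA", "BF", "ST", "VL", "VM"),
    joint = c("ankle", "ankle", "ankle", "knee", "knee", "knee", "knee"),
    stringsAsFactors = FALSE
  )
}

#' Co-contraction index curve for an antagonist pair
#'
#' At each gait-cycle node `i`, with `L` the normalized amplitude of the
#' less active and `H` of the more active muscle,
#' `CCI_i = (L_i / H_i) * (L_i + H_i)`. CCI ranges from 0 (one muscle
#' silent) to 2 (both muscles at their normalized maximum). The less
#' active muscle is resolved per node, so the index is symmetric in its
#' arguments. When both muscles are silent at a node (`H = 0`) the index
#' is 0, the continuity limit of the formula.
#'
#' @param a,b amplitude-normalized cycle series on a common grid, values
#'   in `[0, 1]`.
#' @param tol tolerance for the normalization check.
#' @return numeric vector of CCI values, one per node.
#' @export
cciCurve <- function(a, b, tol = 1e-9) {
  if (length(a) != length(b)) stop("series must share one grid")
  if (any(a < -tol | a > 1 + tol) || any(b < -tol | b > 1 + tol)) {
    stop("inputs must be amplitude-normalized to [0, 1]")
  }
  a <- pmin(pmax(a, 0), 1)
  b <- pmin(pmax(b, 0), 1)
  L <- pmin(a, b)
  H <- pmax(a, b)
  ifelse(H == 0, 0, (L / H) * (L + H))
}

#' Slope ratio of soleus to lateral gastrocnemius in early stance
#'
#' Least-squares slope of each muscle's mean normalized envelope over the
#' first half of the stance phase (nodes 0 to `stanceEnd / 2`), returned
#' as slope(SOL) / slope(LG). A ratio below the control value indicates a
#' relative shift toward preferential gastrocnemius recruitment.
#'
#' @param sol,lg mean normalized cycle series (101 nodes) for soleus and
#'   lateral gastrocnemius.
#' @param stanceEnd end of the stance phase in % gait cycle.
#' @return the dimensionless slope ratio.
#' @export
slopeRatio <- function(sol, lg, stanceEnd = 60) {
  if (stanceEnd <= 0 || stanceEnd > 100) stop("stanceEnd must be in (0, 100]")
  if (length(sol) != length(lg)) stop("series must share one grid")
  idx <- seq_len(floor(stanceEnd / 2) + 1L)
  x <- idx - 1
  slope <- function(y) {
    xc <- x - mean(x)
    sum(xc * (y[idx] - mean(y[idx]))) / sum(xc^2)
  }
  sSol <- slope(sol)
  sLg <- slope(lg)
  if (abs(sLg) < .Machine$double.eps^0.5 * max(1, abs(sSol))) {
    stop("LG slope is zero over the window: ratio undefined")
  }
  sSol / sLg
}
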
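#' Power of a two-sided two-sample t test
#'
#' Equal group sizes and a common SD; power from the noncentral t
#' distribution with `2n - 2` degrees of freedom and noncentrality
#' `d * sqrt(n / 2)`, where `d` is the standardised effect size.
#'
#' @param n Per-group sample size (>= 2).
#' @param d Standardised effect size (difference in means / SD).
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
twoSampleTPower <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- abs(d) * sqrt(n / 2)
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}

#' Per-group sample size for a two-sample comparison
#'
#' Smallest integer `n` per group for which a two-sided two-sample t test
#' on the effect `relDifference * refMean` (common SD `refSd`) reaches
#' the requested power, using noncentral-t power.  The noncentral-t
#' route matters: a normal-approximation calculation returns one subject
#' fewer for typical inputs of this size.
#'
#' @param refMean Reference group mean (e.g. abdominal fat volume, mL).
#' @param refSd Reference SD (same units).
#' @param relDifference Relative difference to detect (fraction, e.g.
#'   0.30).
#' @param power Target power (fraction).
#' @param alpha Two-sided significance level.
#' @return Integer per-group sample size.
#' @examples
#' sampleSizeTwoSample(3829, 1106, 0.30, 0.80, 0.05)  # 16
#' @export
sampleSizeTwoSample <- function(refMean, refSd, relDifference,
                                power = 0.80, alpha = 0.05) {
  stopifnot(refSd > 0, relDifference > 0, power > 0, power < 1,
            alpha > 0, alpha < 1)
  d <- relDifference * refMean / refSd
  nMax <- 1e6
  ## bracket by doubling, then bisect to the smallest sufficient n
  hi <- 2
  while (twoSampleTPower(hi, d, alpha) < power) {
    hi <- hi * 2
    if (hi > nMax)
      stop(sprintf(
        "required sample size exceeds %g per group; the relative difference is too small",
        nMax))
  }
  lo <- max(2, hi %/% 2)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (twoSampleTPower(mid, d, alpha) >= power) hi <- mid else lo <- mid + 1
  }
  as.integer(hi)
}

## all permutations of 1..n as an (n!) x n matrix, built incrementally
.permMatrix <- function(n) {
  P <- matrix(1L, 1L, 1L)
  if (n == 1L) return(P)
  for (k in 2L:n) {
    m <- nrow(P)
    Pk <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- ((pos - 1L) * m + 1L):(pos * m)
      if (pos > 1L) Pk[rows, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L), drop = FALSE]
      Pk[rows, pos] <- k
      if (pos < k) Pk[rows, (pos + 1L):k] <- P[, pos:(k - 1L), drop = FALSE]
    }
    P <- Pk
  }
  P
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' `rho` is the Pearson correlation of mid-ranks (tie-aware).  The
#' two-sided p-value is computed by exhaustive enumeration of all `n!`
#' rank permutations for `n <= exactMax` (counting permutations with
#' `|rho| >=` the observed value), and by the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` with `n - 2` degrees of freedom
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param method `"auto"` (exact for small n), `"exact"`, or `"approx"`.
#' @param exactMax Largest n for which `"auto"` enumerates exactly.
#' @return List with elements `rho`, `p.value`, `n` and `method`.
#' @examples
#' spearmanRank(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearmanRank <- function(x, y, method = c("auto", "exact", "approx"),
                         exactMax = 9L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("rank correlation is undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  useExact <- method == "exact" || (method == "auto" && n <= exactMax)
  if (useExact) {
    if (n > 10L) stop("exact enumeration is limited to n <= 10")
    ax <- (rx - mean(rx)); ay <- (ry - mean(ry))
    ax <- ax / sqrt(sum(ax^2)); ay <- ay / sqrt(sum(ay^2))
    P <- .permMatrix(n)
    M <- matrix(ax[t(P)], ncol = n, byrow = TRUE)
    rhos <- as.vector(M %*% ay)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    meth <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), n - 2))
    meth <- "t approximation"
  }
  list(rho = rho, p.value = p, n = n, method = meth)
}
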
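## Statistical primitives shared by all pipeline stages: Fisher's Z test for
## vanishing (partial) correlations, Welch's unequal-variance t test (scalar
## and vectorized), Benjamini-Hochberg step-up selection, and the DeLong test
## for comparing correlated AUCs.

.R_CLAMP <- 1 - 1e-12

## samples x columns matrix used by the CI test; the reserved id "phenotype"
## addresses the 0/1 phenotype column of an ExpressionDataset.
.testMatrix <- function(data) {
  if (methods::is(data, "ExpressionDataset")) {
    M <- exprsMatrix(data)
    ph <- phenotype(data)
    if (!is.null(ph)) {
      if ("phenotype" %in% colnames(M))
        stop("a probe is named 'phenotype'; rename it before testing")
      M <- cbind(M, phenotype = as.numeric(ph))
    }
    M
  } else {
    as.matrix(data)
  }
}

## Partial correlation of variables i and j given the set S, all indices into
## the correlation matrix R.  Returns NA when the conditioning submatrix is
## numerically singular (exactly collinear inputs).
.partialCorFromR <- function(R, i, j, S) {
  if (length(S) == 0L)
    return(R[i, j])
  if (length(S) == 1L) {
    den2 <- (1 - R[i, S]^2) * (1 - R[j, S]^2)
    if (!is.finite(den2) || den2 <= 1e-24)
      return(NA_real_)
    return((R[i, j] - R[i, S] * R[j, S]) / sqrt(den2))
  }
  idx <- c(i, j, S)
  P <- tryCatch(solve(R[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(P))
    return(NA_real_)
  den2 <- P[1, 1] * P[2, 2]
  if (!is.finite(den2) || den2 <= 0)
    return(NA_real_)
  -P[1, 2] / sqrt(den2)
}

## Two-sided p-value of the Fisher Z statistic for a (partial) correlation r
## at sample size n with conditioning-set size k.  Vectorized in r.
.fisherZP <- function(r, n, k) {
  r <- pmin(pmax(r, -.R_CLAMP), .R_CLAMP)
  z <- sqrt(n - k - 3) * atanh(r)
  2 * stats::pnorm(-abs(z))
}

.newCITestResult <- function(rPartial, n, condSize, alpha,
                             degenerate = FALSE) {
  if (degenerate || is.na(rPartial)) {
    rPartial <- 0
    zStat <- 0
    p <- 1
    degenerate <- TRUE
  } else {
    rPartial <- min(max(rPartial, -.R_CLAMP), .R_CLAMP)
    zStat <- sqrt(n - condSize - 3) * atanh(rPartial)
    p <- 2 * stats::pnorm(-abs(zStat))
  }
  structure(list(rPartial = rPartial, zStatistic = zStat, pValue = p,
                 n = n, condSize = condSize, alpha = alpha,
                 independent = p > alpha, degenerate = degenerate),
            class = "CITestResult")
}

#' Fisher's Z test for vanishing partial correlations
#'
#' Tests whether variables \code{x} and \code{y} are (conditionally)
#' uncorrelated given the conditioning set \code{cond}.  The sample partial
#' correlation is obtained from the inverse of the correlation submatrix,
#' Fisher-transformed (\code{atanh}) after clamping to \eqn{|r| \le 1 -
#' 10^{-12}}, and standardized by \eqn{\sqrt{n - |cond| - 3}}; the p-value is
#' two-sided normal.  A binary phenotype is treated as a numeric 0/1 column
#' (addressed by the reserved id \code{"phenotype"}), the usual
#' linear-Gaussian surrogate for mixed continuous/binary tests.
#'
#' Degenerate inputs -- a constant column among \code{x}, \code{y},
#' \code{cond}, or an exactly collinear (singular) conditioning submatrix --
#' yield the limiting declaration of independence: \code{rPartial = 0},
#' \code{pValue = 1}, flagged via \code{degenerate}.  A duplicate
#' conditioning variable exhausts the information of its copy, so this is the
#' behaviour required for equivalence-class discovery on (near-)deterministic
#' gene copies.
#'
#' @param data an \code{\link{ExpressionDataset}} or a numeric samples-by-
#'   variables matrix with column names.
#' @param x,y column ids; \code{"phenotype"} addresses the phenotype.
#' @param cond character vector of conditioning column ids (possibly empty).
#' @param alpha significance level used for the \code{independent} decision.
#' @return an object of class \code{CITestResult}: a list with
#'   \code{rPartial}, \code{zStatistic}, \code{pValue}, \code{n},
#'   \code{condSize}, \code{alpha}, \code{independent}, \code{degenerate}.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
#' fisherZTest(m, "a", "b")
#' fisherZTest(m, "a", "b", cond = "c")
#' @export
fisherZTest <- function(data, x, y, cond = character(0), alpha = 0.05) {
  M <- .testMatrix(data)
  cols <- c(x, y, cond)
  if (anyDuplicated(cols))
    stop("x, y and cond must be distinct columns")
  missing <- setdiff(cols, colnames(M))
  if (length(missing))
    stop("unknown column id(s): ", paste(missing, collapse = ", "))
  n <- nrow(M)
  k <- length(cond)
  if (n <= k + 3)
    stop("insufficient sample size: need n > cond size + 3 (n = ", n,
         ", |cond| = ", k, ")")
  V <- M[, cols, drop = FALSE]
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0))
    return(.newCITestResult(NA_real_, n, k, alpha, degenerate = TRUE))
  R <- stats::cor(V)
  r <- .partialCorFromR(R, 1L, 2L, if (k) seq_len(k) + 2L else integer(0))
  .newCITestResult(r, n, k, alpha)
}

#' @export
print.CITestResult <- function(x, ...) {
  cat(sprintf(
    "Fisher Z test: r.partial = %.4f, z = %.3f, p = %.4g (n = %d, |cond| = %d)\n",
    x$rPartial, x$zStatistic, x$pValue, x$n, x$condSize))
  cat(sprintf("  decision at alpha = %g: %s%s\n", x$alpha,
              if (x$independent) "independent" else "dependent",
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided test of equal means with the Welch--Satterthwaite degrees of
#' freedom.  Implemented directly from the moment formulas so that the same
#' code path is shared with the vectorized per-gene version used by the
#' permutation audit (\code{\link{countSignificant}}).
#'
#' @param groupA,groupB numeric vectors of at least 2 values each.
#' @return a list with \code{statistic}, \code{df}, \code{pValue}.
#' @examples
#' welchTTest(rnorm(10), rnorm(10, mean = 3))$pValue
#' @export
welchTTest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  na <- length(groupA); nb <- length(groupB)
  va <- stats::var(groupA); vb <- stats::var(groupB)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    warning("both groups have zero variance")
    d <- mean(groupA) - mean(groupB)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                df = na + nb - 2, pValue = if (d == 0) 1 else 0))
  }
  t <- (mean(groupA) - mean(groupB)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, pValue = 2 * stats::pt(-abs(t), df))
}

## Vectorized Welch test down the columns of a samples x genes matrix.
## Returns the two-sided p-value per gene; genes with zero variance in both
## groups get p = 1 (no evidence against equal means).
.colWelchP <- function(X, labels) {
  labels <- as.integer(labels)
  a <- X[labels == 1L, , drop = FALSE]
  b <- X[labels == 0L, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L)
    stop("each phenotype class needs at least 2 samples")
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  ## zero pooled variance: an exact mean difference is overwhelming
  ## evidence, an exact tie is none
  deg <- se2 == 0
  p[deg] <- ifelse(ma[deg] != mb[deg], 0, 1)
  p
}

#' Benjamini-Hochberg FDR selection mask
#'
#' Step-up selection at FDR level \code{q}: selects every hypothesis whose
#' BH-adjusted p-value is at most \code{q}, which is equivalent to selecting
#' all p-values with rank up to \eqn{k^* = \max\{k : p_{(k)} \le kq/m\}}.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return logical selection mask of the same length as \code{pValues}.
#' @examples
#' bhFdr(c(0.001, 0.5, 0.9), q = 0.2)
#' @export
bhFdr <- function(pValues, q) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE) || anyNA(pValues))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1)
    stop("q must lie in (0, 1)")
  stats::p.adjust(pValues, method = "BH") <= q
}

## Mann-Whitney AUC of scores against binary labels (positive class = 1);
## ties contribute 1/2.
.aucFromScores <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same samples, using
#' the placement-value (structural component) covariance estimator of DeLong
#' et al.  AUCs are Mann--Whitney statistics with ties counted 1/2; the
#' variance of the AUC difference is assembled from the empirical covariance
#' of the per-positive and per-negative placement values of the two
#' classifiers.  When the estimated variance of the difference is zero
#' (e.g. identical score vectors) the test is inconclusive by convention:
#' \code{zStatistic = 0}, \code{pValue = 1}.
#'
#' @param scoresA,scoresB numeric decision scores of the two classifiers,
#'   aligned to the same \code{labels}.
#' @param labels binary 0/1 vector; 1 is the positive class.
#' @return an object of class \code{AucComparison}: list with \code{aucA},
#'   \code{aucB}, \code{zStatistic}, \code{pValue}, \code{varDelta}.
#' @examples
#' set.seed(1)
#' y <- rep(c(0, 1), each = 20)
#' s1 <- y + rnorm(40); s2 <- y + rnorm(40, sd = 2)
#' delongAucTest(s1, s2, y)
#' @export
delongAucTest <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  if (length(scoresA) != length(labels) || length(scoresB) != length(labels))
    stop("scores and labels must have equal length")
  pos <- labels == 1L
  neg <- labels == 0L
  m <- sum(pos); n0 <- sum(neg)
  if (m == 0L || n0 == 0L)
    stop("both classes must be present in labels")

  placement <- function(s) {
    sp <- s[pos]; sn <- s[neg]
    psi <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  pa <- placement(scoresA)
  pb <- placement(scoresB)

  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  varDelta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  if (!is.finite(varDelta) || varDelta <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(varDelta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(aucA = pa$auc, aucB = pb$auc, zStatistic = z, pValue = p,
                 varDelta = varDelta),
            class = "AucComparison")
}

#' @export
print.AucComparison <- function(x, ...) {
  cat(sprintf("DeLong AUC comparison: AUC.A = %.4f, AUC.B = %.4f\n",
              x$aucA, x$aucB))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$zStatistic, x$pValue))
  invisible(x)
}
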
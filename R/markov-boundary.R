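## Semi-interleaved HITON-PC without symmetry correction: the GLL
## instantiation used as the base Markov-boundary inducer.  All conditional
## independence decisions run through Fisher's Z test computed from a shared
## correlation matrix, so repeated runs on column subsets (the TIE* loop)
## cost almost nothing beyond the first.

#' Parameters of the GLL Markov-boundary inducer
#'
#' @param alpha significance level of the Fisher Z conditional-independence
#'   test.  The default is deliberately strict: the inducer screens every
#'   gene on a panel of typically ~10^3 probes, and a per-test level on the
#'   order of 1/(100 m) is required for the output to be free of
#'   chance-correlated genes (see the package vignette); use
#'   \code{alpha = 0.05} only on small, pre-filtered panels.
#' @param maxK maximum cardinality of a conditioning set (the max-k
#'   parameter); 1 is the standard choice for expression panels.
#' @return an object of class \code{GllParams}.
#' @examples
#' gllParams()
#' gllParams(alpha = 0.05, maxK = 2)
#' @export
gllParams <- function(alpha = 1e-5, maxK = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (maxK < 0) stop("maxK must be >= 0")
  structure(list(alpha = alpha, maxK = as.integer(maxK)),
            class = "GllParams")
}

## p-value of the Fisher Z test read off a correlation matrix; singular
## conditioning (exact collinearity) declares independence.
.fisherZPFromR <- function(R, n, i, j, S) {
  r <- .partialCorFromR(R, i, j, S)
  if (is.na(r)) return(1)
  .fisherZP(r, n, length(S))
}

## All k-subsets of the vector x, one per column.  combn() must never see a
## scalar first argument (it would enumerate seq_len(x) instead of {x}).
.kSubsets <- function(x, k) {
  if (k == 1L)
    return(matrix(x, nrow = 1L))
  utils::combn(x, k)
}

## TRUE when some subset S of `set` with |S| <= maxK renders variable xi
## independent of the target at level alpha.
.dismissed <- function(R, n, xi, targetIdx, set, alpha, maxK) {
  if (.fisherZPFromR(R, n, xi, targetIdx, integer(0)) > alpha)
    return(TRUE)
  kmax <- min(maxK, length(set))
  for (k in seq_len(kmax)) {
    subsets <- .kSubsets(set, k)
    for (col in seq_len(ncol(subsets))) {
      if (.fisherZPFromR(R, n, xi, targetIdx, subsets[, col]) > alpha)
        return(TRUE)
    }
  }
  FALSE
}

## Semi-interleaved HITON-PC core working purely on a correlation matrix.
## candOrder: candidate indices in decreasing-association priority order
## (ties already broken); targetIdx: index of the target row/column of R.
## Elimination of admitted members is deferred to the final backward pass;
## only incoming candidates are tested during insertion.
.hitonCore <- function(R, n, candOrder, targetIdx, alpha, maxK) {
  tpc <- integer(0)
  for (ci in candOrder) {
    if (!.dismissed(R, n, ci, targetIdx, tpc, alpha, maxK))
      tpc <- c(tpc, ci)
  }
  keep <- tpc
  for (ci in tpc) {
    others <- setdiff(keep, ci)
    if (.dismissed(R, n, ci, targetIdx, others, alpha, maxK))
      keep <- others
  }
  keep
}

## Shared preparation: samples x genes matrix plus numeric phenotype, with
## constant genes dropped (logged via message()).
.screenInput <- function(data) {
  ph <- phenotype(data)
  if (is.null(ph))
    stop("data has no phenotype")
  if (length(unique(ph)) < 2L)
    stop("phenotype must have 2 classes present")
  X <- exprsMatrix(data)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " constant gene(s) before screening")
    X <- X[, sds > 0, drop = FALSE]
  }
  list(X = X, ph = as.numeric(ph))
}

#' Univariate association screen against the phenotype
#'
#' The prioritization step of semi-interleaved HITON-PC: every gene is
#' tested for unconditional association with the phenotype by Fisher's Z
#' test; genes with p-value at most \code{alpha} are returned sorted by
#' decreasing absolute correlation, ties broken by smaller column index
#' (deterministic).
#'
#' @param data an \code{\link{ExpressionDataset}} with a binary phenotype.
#' @param params a \code{\link{gllParams}} object.
#' @return a data.frame with columns \code{gene}, \code{r}, \code{pValue},
#'   ordered by priority; zero rows when nothing passes the screen.
#' @examples
#' ed <- generateTiedLike(equivalenceSpec(nSamples = 200, nGenes = 30,
#'                                        seed = 1))$data
#' head(univariateScreen(ed, gllParams()))
#' @export
univariateScreen <- function(data, params = gllParams()) {
  si <- .screenInput(data)
  r <- as.vector(stats::cor(si$X, si$ph))
  p <- .fisherZP(r, nrow(si$X), 0)
  keep <- which(p <= params$alpha)
  ord <- keep[order(-abs(r[keep]), keep)]
  data.frame(gene = colnames(si$X)[ord], r = r[ord], pValue = p[ord],
             stringsAsFactors = FALSE)
}

#' Semi-interleaved HITON-PC Markov-boundary induction
#'
#' Returns one maximally predictive, non-redundant gene set for the
#' phenotype.  Candidates passing the univariate screen are iterated in
#' priority order; an incoming candidate is admitted unless some subset of
#' the current tentative set of cardinality at most \code{maxK} renders it
#' independent of the phenotype at level \code{alpha}.  After all
#' insertions, a final backward pass removes any member rendered independent
#' by a subset of the remaining members.  The output is deterministic given
#' the data and parameters and independent of sample ordering.
#'
#' @inheritParams univariateScreen
#' @return character vector of gene ids (sorted); empty when no gene is
#'   associated with the phenotype.
#' @examples
#' tied <- generateTiedLike(equivalenceSpec(nSamples = 400, nGenes = 40,
#'                                          classSizes = c(2, 2), seed = 7))
#' hitonPC(tied$data, gllParams())
#' @export
hitonPC <- function(data, params = gllParams()) {
  si <- .screenInput(data)
  r <- as.vector(stats::cor(si$X, si$ph))
  p <- .fisherZP(r, nrow(si$X), 0)
  keep <- which(p <= params$alpha)
  if (!length(keep))
    return(character(0))
  ord <- keep[order(-abs(r[keep]), keep)]
  V <- cbind(si$X[, ord, drop = FALSE], si$ph)
  R <- stats::cor(V)
  targetIdx <- ncol(V)
  sel <- .hitonCore(R, nrow(V), seq_along(ord), targetIdx,
                    params$alpha, params$maxK)
  sort(colnames(si$X)[ord[sel]])
}

#' Exhaustive enumeration of minimal Markov boundaries (test oracle)
#'
#' Brute-force oracle for small problems: enumerates every minimal gene set
#' M such that each gene outside M is rendered independent of the phenotype
#' (Fisher Z at \code{alpha}) by some subset of M of cardinality at most
#' \code{maxSet}.  Intended purely as a ground-truth reference for the
#' HITON-PC inducer on instances of at most 15 genes.
#'
#' @inheritParams univariateScreen
#' @param alpha significance level of the independence tests.
#' @param maxSet maximum conditioning-set cardinality.
#' @return list of character vectors, each a minimal boundary (sorted);
#'   contains the empty set when no gene is associated with the phenotype.
#' @examples
#' tied <- generateTiedLike(equivalenceSpec(nSamples = 500, nGenes = 6,
#'                                          classSizes = 2, seed = 3))
#' bruteForceMarkovBoundary(tied$data, alpha = 1e-5, maxSet = 1)
#' @export
bruteForceMarkovBoundary <- function(data, alpha = 1e-5, maxSet = 1L) {
  si <- .screenInput(data)
  p <- ncol(si$X)
  if (p > 15L)
    stop("brute-force enumeration refuses more than 15 genes")
  n <- nrow(si$X)
  V <- cbind(si$X, si$ph)
  R <- stats::cor(V)
  targetIdx <- p + 1L

  ## For each gene, the bitmasks of all conditioning sets (|S| <= maxSet)
  ## that render it independent of the target.
  dismissMasks <- vector("list", p)
  for (g in seq_len(p)) {
    masks <- integer(0)
    if (.fisherZPFromR(R, n, g, targetIdx, integer(0)) > alpha)
      masks <- c(masks, 0L)
    others <- setdiff(seq_len(p), g)
    for (k in seq_len(min(maxSet, length(others)))) {
      subsets <- .kSubsets(others, k)
      for (col in seq_len(ncol(subsets))) {
        S <- subsets[, col]
        if (.fisherZPFromR(R, n, g, targetIdx, S) > alpha)
          masks <- c(masks, sum(bitwShiftL(1L, S - 1L)))
      }
    }
    dismissMasks[[g]] <- masks
  }

  isBoundary <- function(mask) {
    outside <- which(bitwAnd(bitwShiftL(1L, seq_len(p) - 1L), mask) == 0L)
    for (g in outside) {
      dm <- dismissMasks[[g]]
      if (!length(dm) || !any(bitwAnd(dm, mask) == dm))
        return(FALSE)
    }
    TRUE
  }

  allMasks <- 0:(2L^p - 1L)
  popcount <- vapply(allMasks, function(m) sum(bitwAnd(bitwShiftL(1L, 0:(p - 1L)), m) != 0L), numeric(1))
  allMasks <- allMasks[order(popcount)]
  sats <- allMasks[vapply(allMasks, isBoundary, logical(1))]
  minimal <- integer(0)
  for (m in sats) {
    if (!any(vapply(minimal, function(s) bitwAnd(s, m) == s, logical(1))))
      minimal <- c(minimal, m)
  }
  lapply(minimal, function(m) {
    sort(colnames(si$X)[bitwAnd(bitwShiftL(1L, seq_len(p) - 1L), m) != 0L])
  })
}
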
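## The six post-normalization preprocessing methods compared by the bias
## audit.  All operate on an ExpressionDataset (or a plain samples x genes
## matrix) and return a transformed copy of the same shape and ordering.

.getX <- function(data) {
  if (methods::is(data, "ExpressionDataset")) exprsMatrix(data)
  else as.matrix(data)
}

#' @importFrom SummarizedExperiment assay<-
.setX <- function(data, X) {
  if (methods::is(data, "ExpressionDataset")) {
    SummarizedExperiment::assay(data, "exprs") <- t(X)
    data
  } else {
    X
  }
}

#' Global centering
#'
#' Subtracts the grand mean (one scalar over all matrix entries) from the
#' whole expression matrix.
#'
#' @param data an \code{\link{ExpressionDataset}} or samples-by-genes matrix.
#' @return transformed copy of the input, same class and shape.
#' @examples
#' centerGlobal(matrix(7, 2, 3))
#' @export
centerGlobal <- function(data) {
  X <- .getX(data)
  .setX(data, X - mean(X))
}

#' Per-gene standardization
#'
#' Rescales every gene to zero mean and unit standard deviation (sample,
#' n-1 denominator).  Constant genes cannot be standardized; they are set to
#' zero with a warning.
#'
#' @inheritParams centerGlobal
#' @return transformed copy of the input.
#' @examples
#' standardizePerGene(cbind(g1 = c(1, 2, 3)))
#' @export
standardizePerGene <- function(data) {
  X <- .getX(data)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  const <- sd == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) set to zero")
    sd[const] <- 1
  }
  Y <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  Y[, const] <- 0
  .setX(data, Y)
}

#' Per-gene [0, 1] rescaling
#'
#' Maps each gene linearly so its minimum is 0 and its maximum is 1.
#' Constant genes are mapped to 0.5 with a warning.
#'
#' @inheritParams centerGlobal
#' @return transformed copy of the input.
#' @examples
#' scale01PerGene(cbind(g1 = c(1, 3, 5)))
#' @export
scale01PerGene <- function(data) {
  X <- .getX(data)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) mapped to 0.5")
    rng[const] <- 1
  }
  Y <- sweep(sweep(X, 2, lo, "-"), 2, rng, "/")
  Y[, const] <- 0.5
  .setX(data, Y)
}

#' Per-cohort reference-mean correction
#'
#' Within each cohort, computes the mean expression profile of the
#' uninfected samples and subtracts it from every profile (infected and
#' uninfected) of that cohort.  This is the batch-correction scheme that
#' anchors each cohort at its uninfected reference; because the subtracted
#' profile is estimated from a phenotype-defined subgroup, the operation is
#' phenotype-aware and is a documented source of selection bias under
#' permutation (see \code{\link{auditBias}}).
#'
#' @inheritParams centerGlobal
#' @param cohorts cohort labels, one per sample; defaults to
#'   \code{cohort(data)}.
#' @param uninfectedMask logical vector marking the uninfected samples;
#'   defaults to \code{phenotype(data) == 0}.
#' @return transformed copy of the input.
#' @export
cohortUninfectedMeanCorrect <- function(data, cohorts = NULL,
                                        uninfectedMask = NULL) {
  X <- .getX(data)
  if (is.null(cohorts) && methods::is(data, "ExpressionDataset"))
    cohorts <- cohort(data)
  if (is.null(uninfectedMask) && methods::is(data, "ExpressionDataset")) {
    ph <- phenotype(data)
    if (!is.null(ph)) uninfectedMask <- ph == 0L
  }
  if (is.null(cohorts))
    stop("cohort labels are required")
  if (is.null(uninfectedMask))
    stop("an uninfected-sample mask is required")
  cohorts <- factor(cohorts)
  if (length(cohorts) != nrow(X) || length(uninfectedMask) != nrow(X))
    stop("label lengths do not match sample count")
  for (lev in levels(cohorts)) {
    inCohort <- cohorts == lev
    ref <- inCohort & uninfectedMask
    if (!any(ref))
      stop("cohort '", lev, "' contains no uninfected samples")
    mu <- colMeans(X[ref, , drop = FALSE])
    X[inCohort, ] <- sweep(X[inCohort, , drop = FALSE], 2, mu, "-")
  }
  .setX(data, X)
}

## ----- parametric empirical-Bayes batch correction ------------------------

.rowVars <- function(M) {
  n <- ncol(M)
  (rowSums(M^2) - n * rowMeans(M)^2) / (n - 1)
}

## Location/scale batch adjustment with parametric empirical-Bayes
## shrinkage.  dat: genes x samples.  mod: optional covariate design columns
## (no intercept).  Follows the standard formulation: gene-wise
## standardization against the batch + covariate fit, normal prior on batch
## locations, inverse-gamma prior on batch scales estimated by method of
## moments, iterative conditional posterior means, back-transformation.
.combatParametric <- function(dat, batch, mod = NULL, conv = 1e-4) {
  batch <- factor(batch)
  if (nlevels(batch) < 2L)
    stop("batch correction needs at least 2 batches")
  counts <- table(batch)
  if (any(counts < 2L))
    stop("every batch needs at least 2 samples")
  nArray <- ncol(dat)
  nBatch <- nlevels(batch)
  batchIdx <- lapply(levels(batch), function(l) which(batch == l))
  nPer <- vapply(batchIdx, length, integer(1))

  batchDesign <- stats::model.matrix(~ -1 + batch)
  design <- if (is.null(mod)) batchDesign else cbind(batchDesign, mod)
  if (qr(design)$rank < ncol(design))
    stop("design matrix (batch indicators + covariates) is rank-deficient")

  BHat <- solve(crossprod(design), t(design) %*% t(dat))
  grandMean <- crossprod(nPer / nArray, BHat[seq_len(nBatch), , drop = FALSE])
  resid <- dat - t(design %*% BHat)
  varPooled <- rowSums(resid^2) / nArray
  zeroVar <- varPooled == 0
  if (any(zeroVar)) {
    warning(sum(zeroVar), " gene(s) with zero pooled variance passed through")
    varPooled[zeroVar] <- 1
  }

  standMean <- matrix(grandMean, nrow(dat), nArray)
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(nBatch)] <- 0
    standMean <- standMean + t(tmp %*% BHat)
  }
  sData <- (dat - standMean) / sqrt(varPooled)

  gammaHat <- solve(crossprod(batchDesign), t(batchDesign) %*% t(sData))
  deltaHat <- t(vapply(batchIdx, function(ii) {
    .rowVars(sData[, ii, drop = FALSE])
  }, numeric(nrow(dat))))
  gammaBar <- rowMeans(gammaHat)
  tau2 <- .rowVars(gammaHat)
  aPrior <- vapply(seq_len(nBatch), function(i) {
    m <- mean(deltaHat[i, ]); s2 <- stats::var(deltaHat[i, ])
    (2 * s2 + m^2) / s2
  }, numeric(1))
  bPrior <- vapply(seq_len(nBatch), function(i) {
    m <- mean(deltaHat[i, ]); s2 <- stats::var(deltaHat[i, ])
    (m * s2 + m^3) / s2
  }, numeric(1))

  bayes <- sData
  for (i in seq_len(nBatch)) {
    ii <- batchIdx[[i]]
    sub <- sData[, ii, drop = FALSE]
    ni <- nPer[i]
    gOld <- gammaHat[i, ]
    dOld <- deltaHat[i, ]
    change <- 1
    while (change > conv) {
      gNew <- (tau2[i] * ni * gammaHat[i, ] + dOld * gammaBar[i]) /
        (tau2[i] * ni + dOld)
      sum2 <- rowSums((sub - gNew)^2)
      dNew <- (0.5 * sum2 + bPrior[i]) / (ni / 2 + aPrior[i] - 1)
      change <- max(abs(gNew - gOld) / gOld, abs(dNew - dOld) / dOld)
      if (!is.finite(change))
        change <- max(abs(gNew - gOld), abs(dNew - dOld))
      gOld <- gNew
      dOld <- dNew
    }
    bayes[, ii] <- (sub - gNew) / sqrt(dNew)
  }
  out <- bayes * sqrt(varPooled) + standMean
  out[zeroVar, ] <- dat[zeroVar, ]
  out
}

#' Empirical-Bayes batch correction (location and scale)
#'
#' Adjusts additive (location) and multiplicative (scale) per-gene batch
#' effects with parametric empirical-Bayes shrinkage: batch effect estimates
#' are pooled across all genes through a normal prior on locations and an
#' inverse-gamma prior on scales, then removed gene-wise.  Supplying the
#' phenotype as a covariate preserves expression variation attributable to
#' the biological response while batch terms are estimated.
#'
#' @inheritParams centerGlobal
#' @param batches batch labels (one per sample); defaults to
#'   \code{cohort(data)}.
#' @param covariates optional binary phenotype vector (or \code{NULL} for a
#'   covariate-free fit); defaults to \code{phenotype(data)} when available.
#' @return transformed copy of the input.
#' @export
combatCorrect <- function(data, batches = NULL, covariates = NULL) {
  X <- .getX(data)
  if (is.null(batches) && methods::is(data, "ExpressionDataset"))
    batches <- cohort(data)
  if (is.null(batches))
    stop("batch labels are required")
  if (is.null(covariates) && methods::is(data, "ExpressionDataset"))
    covariates <- phenotype(data)
  mod <- NULL
  if (!is.null(covariates))
    mod <- stats::model.matrix(~ as.numeric(covariates))[, -1, drop = FALSE]
  Y <- t(.combatParametric(t(X), batches, mod))
  dimnames(Y) <- dimnames(X)
  .setX(data, Y)
}

#' Preprocessing method specification
#'
#' @param method one of \code{"none"}, \code{"center_global"},
#'   \code{"standardize_per_gene"}, \code{"scale01_per_gene"},
#'   \code{"cohort_uninfected_mean"}, \code{"combat"}.
#' @param useCovariate for \code{"combat"}: supply the phenotype as a
#'   covariate of the batch fit (default \code{TRUE}).
#' @return an object of class \code{PreprocessSpec}.
#' @examples
#' preprocessSpec("combat")
#' @export
preprocessSpec <- function(method = c("none", "center_global",
                                      "standardize_per_gene",
                                      "scale01_per_gene",
                                      "cohort_uninfected_mean", "combat"),
                           useCovariate = TRUE) {
  method <- match.arg(method)
  structure(list(method = method, useCovariate = isTRUE(useCovariate)),
            class = "PreprocessSpec")
}

## Matrix fast path shared with the permutation audit: X samples x genes,
## ph 0/1 phenotype (already permuted by the caller where applicable).
.applyPreprocMatrix <- function(X, spec, cohorts, ph) {
  switch(spec$method,
         none = X,
         center_global = X - mean(X),
         standardize_per_gene = standardizePerGene(X),
         scale01_per_gene = scale01PerGene(X),
         cohort_uninfected_mean = cohortUninfectedMeanCorrect(
           X, cohorts = cohorts, uninfectedMask = ph == 0L),
         combat = {
           mod <- if (spec$useCovariate && !is.null(ph))
             stats::model.matrix(~ as.numeric(ph))[, -1, drop = FALSE]
           else NULL
           t(.combatParametric(t(X), cohorts, mod))
         },
         stop("unknown preprocessing method: ", spec$method))
}

#' Apply a preprocessing specification
#'
#' Dispatches to the named preprocessing method.  \code{"none"} returns the
#' input unchanged (bit-identical matrix).
#'
#' @inheritParams centerGlobal
#' @param spec a \code{\link{preprocessSpec}} object (or a method name).
#' @param cohorts cohort/batch labels where the method needs them; defaults
#'   to \code{cohort(data)}.
#' @param phenotype binary phenotype where the method uses it (reference
#'   mask or covariate); defaults to \code{phenotype(data)}.
#' @return transformed copy of the input.
#' @examples
#' m <- matrix(rnorm(20), 5, 4)
#' identical(applyPreprocessing(m, preprocessSpec("none")), m)
#' @export
applyPreprocessing <- function(data, spec, cohorts = NULL, phenotype = NULL) {
  if (is.character(spec))
    spec <- preprocessSpec(spec)
  if (!inherits(spec, "PreprocessSpec"))
    stop("spec must be a PreprocessSpec")
  if (is.null(cohorts) && methods::is(data, "ExpressionDataset"))
    cohorts <- cohort(data)
  if (is.null(phenotype) && methods::is(data, "ExpressionDataset"))
    phenotype <- TieSig::phenotype(data)
  X <- .getX(data)
  Y <- .applyPreprocMatrix(X, spec, cohorts, phenotype)
  dimnames(Y) <- dimnames(X)
  .setX(data, Y)
}
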
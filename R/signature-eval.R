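## Signature-as-classifier evaluation: linear SVM training, repeated
## stratified cross-validated AUC, independent-set validation, and the
## two-step redundancy assessment (conditional-independence screen guarded
## by a DeLong AUC comparison).

#' Evaluation parameters for signature classifiers
#'
#' @param costC SVM cost parameter (default 100, the conventional setting
#'   for linear SVMs on standardized expression panels).
#' @param cvFolds number of stratified cross-validation folds.
#' @param cvRepeats number of cross-validation repeats.
#' @param seed integer seed driving fold assignment.
#' @return an object of class \code{EvalParams}.
#' @examples
#' evalParams()
#' @export
evalParams <- function(costC = 100, cvFolds = 10L, cvRepeats = 10L,
                       seed = 1L) {
  if (costC <= 0) stop("costC must be positive")
  if (cvFolds < 2) stop("cvFolds must be >= 2")
  structure(list(costC = costC, cvFolds = as.integer(cvFolds),
                 cvRepeats = as.integer(cvRepeats), seed = as.integer(seed)),
            class = "EvalParams")
}

.signatureMatrix <- function(data, signature) {
  X <- .getX(data)
  signature <- unique(as.character(signature))
  if (!length(signature))
    stop("empty signature")
  missing <- setdiff(signature, colnames(X))
  if (length(missing))
    stop("signature gene(s) absent from data: ",
         paste(missing, collapse = ", "))
  X[, signature, drop = FALSE]
}

#' Train a linear SVM on a signature's genes
#'
#' Fits a linear support vector machine (cost \code{costC}) on the
#' signature's columns only.  Features are standardized with statistics of
#' the supplied (training) data; the same statistics are reapplied at
#' prediction time so no information leaks from evaluation samples.
#' Decision scores are oriented so larger values indicate the positive
#' (infected/symptomatic) class.
#'
#' @param dataTrain an \code{\link{ExpressionDataset}} (or samples-by-genes
#'   matrix) with both phenotype classes present.
#' @param signature character vector of gene ids.
#' @param params an \code{\link{evalParams}} object.
#' @param phenotype binary labels; defaults to \code{phenotype(dataTrain)}.
#' @return an object of class \code{SvmSignatureModel} with a
#'   \code{predict} method returning decision scores.
#' @examples
#' tied <- generateTiedLike(equivalenceSpec(nSamples = 200, nGenes = 20,
#'                                          classSizes = 2, seed = 1))
#' fit <- trainSvmSignature(tied$data, signatures(tied$groundTruth)[[1]])
#' head(predict(fit, tied$data))
#' @export
trainSvmSignature <- function(dataTrain, signature, params = evalParams(),
                              phenotype = NULL) {
  if (is.null(phenotype) && methods::is(dataTrain, "ExpressionDataset"))
    phenotype <- TieSig::phenotype(dataTrain)
  ph <- .asBinaryPhenotype(phenotype)
  if (length(unique(ph)) < 2L)
    stop("both phenotype classes must be present")
  X <- .signatureMatrix(dataTrain, signature)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  model <- e1071::svm(x = Xs, y = factor(ph, levels = c(0, 1)),
                      kernel = "linear", cost = params$costC,
                      scale = FALSE)
  ## e1071 names the decision column "A/B" with positive values favouring
  ## class A; flip so the positive phenotype always scores higher.
  dv <- attr(stats::predict(model, Xs, decision.values = TRUE),
             "decision.values")
  firstClass <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  flip <- if (identical(firstClass, "1")) 1 else -1
  structure(list(model = model, signature = colnames(X), center = center,
                 scale = scale, flip = flip),
            class = "SvmSignatureModel")
}

#' @export
predict.SvmSignatureModel <- function(object, newdata, ...) {
  X <- .signatureMatrix(newdata, object$signature)
  Xs <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  dv <- attr(stats::predict(object$model, Xs, decision.values = TRUE),
             "decision.values")
  object$flip * as.vector(dv)
}

## Stratified fold assignment: within each class, shuffle and deal
## round-robin, so every fold's training part keeps both classes whenever
## each class has at least 2 members.
.stratifiedFolds <- function(ph, nFolds) {
  folds <- integer(length(ph))
  for (cls in unique(ph)) {
    idx <- sample(which(ph == cls))
    folds[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

#' Repeated cross-validated AUC of a signature
#'
#' Stratified k-fold cross-validation repeated r times with seeded fold
#' shuffles.  Out-of-fold decision scores are pooled within each repeat and
#' summarized as one AUC per repeat.  The pooled scores of the first repeat
#' are retained for paired DeLong comparisons between signatures evaluated
#' under the same seed (identical folds).
#'
#' @inheritParams trainSvmSignature
#' @param data training data with both classes present.
#' @return an object of class \code{PerformanceEstimate}: list with
#'   \code{meanAuc}, \code{perRepeat}, \code{scores} (first-repeat pooled
#'   out-of-fold scores, in sample order), \code{labels}.
#' @export
repeatedCvAuc <- function(data, signature, params = evalParams(),
                          phenotype = NULL) {
  if (is.null(phenotype) && methods::is(data, "ExpressionDataset"))
    phenotype <- TieSig::phenotype(data)
  ph <- .asBinaryPhenotype(phenotype)
  if (min(table(ph)) < 2L)
    stop("each class needs at least 2 samples for stratified folds")
  X <- .signatureMatrix(data, signature)
  nFolds <- min(params$cvFolds, min(table(ph)))

  set.seed(params$seed)
  repeatSeeds <- sample.int(.Machine$integer.max - 1L, params$cvRepeats)
  perRepeat <- numeric(params$cvRepeats)
  firstScores <- NULL
  for (r in seq_len(params$cvRepeats)) {
    set.seed(repeatSeeds[r])
    folds <- .stratifiedFolds(ph, nFolds)
    scores <- numeric(length(ph))
    for (f in seq_len(nFolds)) {
      testIdx <- folds == f
      fit <- trainSvmSignature(X[!testIdx, , drop = FALSE], signature,
                               params, phenotype = ph[!testIdx])
      scores[testIdx] <- predict(fit, X[testIdx, , drop = FALSE])
    }
    perRepeat[r] <- .aucFromScores(scores, ph)
    if (r == 1L)
      firstScores <- scores
  }
  structure(list(meanAuc = mean(perRepeat), perRepeat = perRepeat,
                 scores = firstScores, labels = ph),
            class = "PerformanceEstimate")
}

#' @export
print.PerformanceEstimate <- function(x, ...) {
  cat(sprintf("Cross-validated AUC: %.4f (sd %.4f over %d repeats)\n",
              x$meanAuc, stats::sd(x$perRepeat), length(x$perRepeat)))
  invisible(x)
}

#' Two-step redundancy assessment of a signature
#'
#' Step 1 flags candidate redundant genes: members carrying no association
#' with the phenotype when conditioned on some other single member (Fisher Z
#' at \code{alpha}).  Flagged genes are not readily excluded: step 2 removes
#' them en bloc only if the reduced signature's cross-validated AUC shows no
#' significant decrease against the full signature (DeLong test on pooled
#' out-of-fold scores from identical folds; no decrease means \code{p >
#' alpha} or a non-negative AUC difference).  If en-bloc removal degrades
#' accuracy significantly, candidates are reinstated one at a time in
#' decreasing witness p-value order until non-significance is restored.
#'
#' @param signature character vector of at least 2 gene ids.
#' @param dataTrain training data with a binary phenotype.
#' @param params an \code{\link{evalParams}} object.
#' @param alpha significance level shared by the conditional-independence
#'   screen and the DeLong guard.
#' @return an object of class \code{RedundancyReport}: list with
#'   \code{redundant}, \code{retained}, \code{witnesses} (data.frame gene /
#'   condGene / pValue), \code{aucOriginal}, \code{aucReduced},
#'   \code{delongP}.
#' @examples
#' tied <- generateTiedLike(equivalenceSpec(nSamples = 300, nGenes = 20,
#'                                          classSizes = 2, seed = 2))
#' sig <- unionGenes(tied$groundTruth)   # contains duplicate-information genes
#' assessRedundancy(sig, tied$data, evalParams(cvRepeats = 3))
#' @export
assessRedundancy <- function(signature, dataTrain, params = evalParams(),
                             alpha = 0.05) {
  signature <- unique(as.character(signature))
  if (length(signature) < 2L)
    stop("signature must contain at least 2 genes")
  ph <- phenotype(dataTrain)
  if (is.null(ph))
    stop("training data has no phenotype")

  ## Step 1: sequential conditional-independence screen.  Witnesses must
  ## come from the still-retained members -- otherwise both halves of a
  ## duplicate pair would witness each other and en-bloc removal would drop
  ## the pair's information entirely.  At each round the gene with the
  ## strongest witness (largest conditional p) is flagged and set aside;
  ## flagged genes can no longer serve as witnesses.
  current <- signature
  wit <- list()
  repeat {
    best <- NULL
    for (g in current) {
      for (h in setdiff(current, g)) {
        ct <- fisherZTest(dataTrain, g, "phenotype", cond = h, alpha = alpha)
        if (ct$independent &&
            (is.null(best) || ct$pValue > best$pValue))
          best <- list(gene = g, condGene = h, pValue = ct$pValue)
      }
    }
    if (is.null(best) || length(current) <= 1L)
      break
    wit[[best$gene]] <- best
    current <- setdiff(current, best$gene)
  }
  witnesses <- if (length(wit)) {
    data.frame(gene = vapply(wit, `[[`, character(1), "gene"),
               condGene = vapply(wit, `[[`, character(1), "condGene"),
               pValue = vapply(wit, `[[`, numeric(1), "pValue"),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), condGene = character(0),
               pValue = numeric(0), stringsAsFactors = FALSE)
  }

  full <- repeatedCvAuc(dataTrain, signature, params)
  candidates <- witnesses$gene[order(-witnesses$pValue)]

  evalReduced <- function(removed) {
    reduced <- setdiff(signature, removed)
    perf <- repeatedCvAuc(dataTrain, reduced, params)
    cmp <- delongAucTest(full$scores, perf$scores, full$labels)
    list(perf = perf, cmp = cmp,
         ok = cmp$pValue > alpha || (perf$meanAuc - full$meanAuc) >= 0)
  }

  removed <- candidates
  res <- if (length(removed)) evalReduced(removed) else NULL
  if (!is.null(res) && !res$ok) {
    ## Fallback: reinstate candidates one at a time, most-confidently
    ## redundant (largest witness p) first, until the guard passes.
    for (g in candidates) {
      removed <- setdiff(removed, g)
      if (!length(removed)) {
        res <- NULL
        break
      }
      res <- evalReduced(removed)
      if (res$ok)
        break
    }
  }

  retained <- setdiff(signature, removed)
  structure(list(redundant = sort(removed),
                 retained = sort(retained),
                 witnesses = witnesses,
                 aucOriginal = full$meanAuc,
                 aucReduced = if (is.null(res)) full$meanAuc
                              else res$perf$meanAuc,
                 delongP = if (is.null(res)) 1 else res$cmp$pValue),
            class = "RedundancyReport")
}

#' @export
print.RedundancyReport <- function(x, ...) {
  cat("Redundancy assessment\n")
  cat("  retained (", length(x$retained), "): ",
      paste(x$retained, collapse = ", "), "\n", sep = "")
  cat("  removed  (", length(x$redundant), "): ",
      paste(x$redundant, collapse = ", "), "\n", sep = "")
  cat(sprintf("  CV AUC %.4f -> %.4f (DeLong p = %.3g)\n",
              x$aucOriginal, x$aucReduced, x$delongP))
  invisible(x)
}

#' Validate a signature on independent data
#'
#' Trains the signature's classifier on the full training data, scores the
#' validation samples, and reports the validation AUC.  When a
#' \code{reference} signature is supplied, its classifier is trained and
#' scored the same way and the two score vectors are compared with the
#' DeLong test -- the standard check that a reduced, non-redundant signature
#' has lost no predictive accuracy.
#'
#' @inheritParams assessRedundancy
#' @param dataValid independent validation data sharing the signature's gene
#'   ids (a partial intersection is an error for the missing genes).
#' @param reference optional second signature to compare against.
#' @return list with \code{auc}, \code{scores}, \code{labels}, and (when
#'   \code{reference} is given) \code{aucReference} and \code{comparison}
#'   (an \code{AucComparison}).
#' @export
validateIndependent <- function(signature, dataTrain, dataValid,
                                params = evalParams(), reference = NULL) {
  phValid <- phenotype(dataValid)
  if (is.null(phValid))
    stop("validation data has no phenotype")
  fit <- trainSvmSignature(dataTrain, signature, params)
  scores <- predict(fit, dataValid)
  out <- list(auc = .aucFromScores(scores, phValid), scores = scores,
              labels = phValid)
  if (!is.null(reference)) {
    refFit <- trainSvmSignature(dataTrain, reference, params)
    refScores <- predict(refFit, dataValid)
    out$aucReference <- .aucFromScores(refScores, phValid)
    out$comparison <- delongAucTest(scores, refScores, phValid)
  }
  out
}
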
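## Seed-deterministic generators: (a) equivalence-class expression data with
## known signature-multiplicity ground truth, (b) multi-cohort data with
## additive per-gene batch shifts for the bias audit, (c) a one-gene
## separation fixture illustrating the variance-collapse phenomenon, and
## (d) small linear-Gaussian networks for Markov-boundary oracle checks.

#' Ground-truth specification for equivalence-class data
#'
#' Describes the generative structure of a benchmark dataset in which the
#' phenotype has many information-equivalent Markov boundaries: one latent
#' factor per equivalence class, whose member genes are exact (up to
#' microscale jitter) invertible affine copies of the class latent, plus one
#' always-present gene with its own latent.  Every signature consists of the
#' always-present gene and one representative per class, so the number of
#' distinct maximally predictive non-redundant signatures equals the product
#' of the class sizes.
#'
#' The default is shaped like the classic 750-observation, 999-gene
#' multiplicity benchmark: classes of sizes 4, 2, 3, 3 (members X1, X2, X3,
#' X11; X5, X9; X12, X13, X14; X19, X20, X21) plus the always-present gene
#' X10, yielding 4 x 2 x 3 x 3 = 72 signatures of 5 genes each.
#'
#' @param nSamples number of observations.
#' @param nGenes total number of genes (class members + always-present gene
#'   + pure-noise genes).
#' @param classSizes integer vector of equivalence-class sizes.
#' @param seed integer seed for the sampling randomness (latents, noise,
#'   phenotype); two datasets differing only in \code{seed} are independent
#'   draws from the same population.
#' @param populationSeed integer seed for the structural randomness (the
#'   affine coefficients tying member genes to their class latents).  Kept
#'   separate from \code{seed} so that independently sampled training and
#'   validation datasets share the same gene-phenotype relationships, as
#'   profiles from one platform and population would.
#' @param corNoiseFraction fraction of the noise genes placed in small
#'   mutually correlated blocks (correlated among themselves, never with the
#'   phenotype).
#' @param jitterSd standard deviation of the microscale jitter added to
#'   affine copies; keeps covariance matrices numerically invertible while
#'   preserving every test decision (see the vignette).
#' @param phenotypeNoiseSd standard deviation of the latent threshold noise
#'   in the phenotype link.
#' @return an object of class \code{EquivalenceSpec}: list with
#'   \code{nSamples}, \code{nGenes}, \code{classes} (list of gene-id
#'   vectors), \code{alwaysMember}, \code{noiseGenes},
#'   \code{nTrueSignatures}, and the generator options.
#' @examples
#' sp <- equivalenceSpec()
#' sp$nTrueSignatures   # 72
#' @export
equivalenceSpec <- function(nSamples = 750L, nGenes = 999L,
                            classSizes = c(4L, 2L, 3L, 3L), seed = 1L,
                            populationSeed = 2024L,
                            corNoiseFraction = 0.1, jitterSd = 1e-6,
                            phenotypeNoiseSd = 1) {
  classSizes <- as.integer(classSizes)
  if (any(classSizes < 1L))
    stop("class sizes must be >= 1")
  needed <- sum(classSizes) + 1L
  if (nGenes < needed)
    stop("nGenes must be at least ", needed,
         " (class members plus the always-present gene)")
  if (identical(classSizes, c(4L, 2L, 3L, 3L))) {
    classes <- list(c("X1", "X2", "X3", "X11"),
                    c("X5", "X9"),
                    c("X12", "X13", "X14"),
                    c("X19", "X20", "X21"))
    alwaysMember <- "X10"
  } else {
    ids <- sprintf("X%d", seq_len(needed))
    classes <- vector("list", length(classSizes))
    at <- 1L
    for (i in seq_along(classSizes)) {
      classes[[i]] <- ids[at:(at + classSizes[i] - 1L)]
      at <- at + classSizes[i]
    }
    alwaysMember <- ids[needed]
  }
  allIds <- sprintf("X%d", seq_len(nGenes))
  noiseGenes <- setdiff(allIds, c(unlist(classes), alwaysMember))
  structure(list(nSamples = as.integer(nSamples),
                 nGenes = as.integer(nGenes),
                 classes = classes,
                 alwaysMember = alwaysMember,
                 noiseGenes = noiseGenes,
                 nTrueSignatures = prod(classSizes),
                 seed = as.integer(seed),
                 populationSeed = as.integer(populationSeed),
                 corNoiseFraction = corNoiseFraction,
                 jitterSd = jitterSd,
                 phenotypeNoiseSd = phenotypeNoiseSd),
            class = "EquivalenceSpec")
}

#' Generate equivalence-class data with known signature ground truth
#'
#' Draws one standard-normal latent per equivalence class and one for the
#' always-present gene; class members are invertible affine transforms of
#' their class latent (plus microscale jitter), which makes every member
#' information-equivalent to every other under the linear-Gaussian test.
#' The phenotype is a noisy linear-threshold function of all latents, so
#' each latent carries independent predictive information and every Markov
#' boundary must contain the always-present gene plus exactly one
#' representative per class.  Remaining genes are pure noise, a configurable
#' fraction of them correlated in small blocks but never with the
#' phenotype.
#'
#' @param spec an \code{\link{equivalenceSpec}} object.
#' @return list with \code{data} (an \code{\link{ExpressionDataset}}),
#'   \code{groundTruth} (a \code{\link{SignatureSet}} of all true
#'   signatures), and \code{spec}.
#' @examples
#' tied <- generateTiedLike(equivalenceSpec(nSamples = 300, nGenes = 30,
#'                                          classSizes = c(2, 2), seed = 1))
#' tied$data
#' length(tied$groundTruth)   # 4
#' @export
generateTiedLike <- function(spec = equivalenceSpec()) {
  stopifnot(inherits(spec, "EquivalenceSpec"))
  n <- spec$nSamples
  nClasses <- length(spec$classes)
  structGenes <- c(unlist(spec$classes), spec$alwaysMember)

  ## structural randomness: the affine map tying each member gene to its
  ## class latent is a property of the population, not of one sample draw
  set.seed(spec$populationSeed)
  coefA <- stats::setNames(stats::runif(length(structGenes), -0.5, 0.5),
                           structGenes)
  coefB <- stats::setNames(sample(c(-1, 1), length(structGenes),
                                  replace = TRUE) *
                             stats::runif(length(structGenes), 0.5, 2),
                           structGenes)

  ## sampling randomness
  set.seed(spec$seed)
  latents <- matrix(stats::rnorm(n * (nClasses + 1L)), nrow = n)

  eta <- rowSums(latents)
  ph <- as.integer(eta + stats::rnorm(n, sd = spec$phenotypeNoiseSd) > 0)

  X <- matrix(NA_real_, n, spec$nGenes,
              dimnames = list(sprintf("s%d", seq_len(n)),
                              sprintf("X%d", seq_len(spec$nGenes))))
  affineCopy <- function(g, latent) {
    coefA[[g]] + coefB[[g]] * latent + stats::rnorm(n, sd = spec$jitterSd)
  }
  for (ci in seq_len(nClasses)) {
    for (g in spec$classes[[ci]])
      X[, g] <- affineCopy(g, latents[, ci])
  }
  X[, spec$alwaysMember] <- affineCopy(spec$alwaysMember,
                                       latents[, nClasses + 1L])

  noise <- spec$noiseGenes
  nBlockGenes <- round(spec$corNoiseFraction * length(noise))
  blockGenes <- noise[seq_len(nBlockGenes)]
  freeGenes <- setdiff(noise, blockGenes)
  blockSize <- 3L
  at <- 1L
  while (at <= length(blockGenes)) {
    members <- blockGenes[at:min(at + blockSize - 1L, length(blockGenes))]
    shared <- stats::rnorm(n)
    for (g in members)
      X[, g] <- 0.7 * shared + sqrt(1 - 0.49) * stats::rnorm(n)
    at <- at + blockSize
  }
  if (length(freeGenes))
    X[, freeGenes] <- matrix(stats::rnorm(n * length(freeGenes)), n)

  combos <- expand.grid(spec$classes, stringsAsFactors = FALSE)
  truth <- lapply(seq_len(nrow(combos)), function(i) {
    c(unlist(combos[i, ], use.names = FALSE), spec$alwaysMember)
  })
  list(data = ExpressionDataset(X, phenotype = ph,
                                metadata = list(generator = "tied-like",
                                                seed = spec$seed)),
       groundTruth = SignatureSet(truth),
       spec = spec)
}

#' Multi-cohort specification for batch-effect data
#'
#' Describes a multi-cohort expression layout (infected and uninfected
#' samples per cohort, echoing a three-cohort viral-challenge design) with
#' additive per-gene cohort shifts and optional true signal.
#'
#' @param cohorts data.frame with columns \code{name}, \code{nInfected},
#'   \code{nUninfected}.  The default mirrors a three-batch infection study
#'   in which only a handful of unexposed controls are profiled per batch
#'   (uninfected samples are the scarce minority) -- the regime where
#'   reference-profile batch correction is most error-prone.
#' @param nGenes number of genes.
#' @param batchShiftSd standard deviation of the additive per-gene,
#'   per-cohort shift, in units of the unit-SD within-group noise.  The
#'   default 0.25 represents modest technical variation that leaves
#'   uncorrected permutation tests essentially calibrated.
#' @param nSignalGenes number of genes carrying a true between-class shift.
#' @param effectSize between-class mean shift of signal genes, in units of
#'   \code{noiseSd}.
#' @param noiseSd within-group residual standard deviation.
#' @param seed integer seed.
#' @return an object of class \code{CohortSpec}.
#' @examples
#' cohortSpec()
#' @export
cohortSpec <- function(cohorts = data.frame(
                         name = c("cohortA", "cohortB", "cohortC"),
                         nInfected = c(25L, 25L, 26L),
                         nUninfected = c(8L, 8L, 8L)),
                       nGenes = 2000L, batchShiftSd = 0.25,
                       nSignalGenes = 0L, effectSize = 2, noiseSd = 1,
                       seed = 1L) {
  stopifnot(is.data.frame(cohorts),
            all(c("name", "nInfected", "nUninfected") %in% names(cohorts)))
  if (any(cohorts$nInfected < 1L) || any(cohorts$nUninfected < 1L))
    stop("every cohort needs at least 1 infected and 1 uninfected sample")
  structure(list(cohorts = cohorts, nGenes = as.integer(nGenes),
                 batchShiftSd = batchShiftSd,
                 nSignalGenes = as.integer(nSignalGenes),
                 effectSize = effectSize, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Generate multi-cohort expression data with batch effects
#'
#' Per cohort, an additive per-gene shift drawn from
#' \code{N(0, batchShiftSd^2)} is applied to all of the cohort's samples on
#' top of i.i.d. within-group noise.  Under \code{nullPhenotype = TRUE} no
#' gene depends on the phenotype (the audit's null condition); otherwise the
#' first \code{nSignalGenes} genes receive a between-class mean shift of
#' \code{effectSize * noiseSd}.
#'
#' @param spec a \code{\link{cohortSpec}} object.
#' @param nullPhenotype when \code{TRUE} (default), the phenotype labels are
#'   attached but no gene depends on them.
#' @return an \code{\link{ExpressionDataset}} with phenotype and cohort
#'   labels.
#' @examples
#' ed <- generateCohortData(cohortSpec(nGenes = 100, seed = 5))
#' ed
#' @export
generateCohortData <- function(spec = cohortSpec(), nullPhenotype = TRUE) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  co <- spec$cohorts
  nPer <- co$nInfected + co$nUninfected
  n <- sum(nPer)
  cohortLab <- rep(as.character(co$name), nPer)
  ph <- unlist(lapply(seq_len(nrow(co)), function(i) {
    c(rep(1L, co$nInfected[i]), rep(0L, co$nUninfected[i]))
  }))
  X <- matrix(stats::rnorm(n * spec$nGenes, sd = spec$noiseSd), n,
              dimnames = list(sprintf("s%d", seq_len(n)),
                              sprintf("g%d", seq_len(spec$nGenes))))
  for (nm in unique(cohortLab)) {
    shift <- stats::rnorm(spec$nGenes, sd = spec$batchShiftSd)
    idx <- cohortLab == nm
    X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, shift, "+")
  }
  if (!nullPhenotype && spec$nSignalGenes > 0L) {
    sg <- seq_len(min(spec$nSignalGenes, spec$nGenes))
    X[ph == 1L, sg] <- X[ph == 1L, sg] + spec$effectSize * spec$noiseSd
  }
  ExpressionDataset(X, phenotype = ph, cohort = cohortLab,
                    metadata = list(generator = "cohort",
                                    seed = spec$seed))
}

#' One-gene fixture for the variance-collapse phenomenon
#'
#' Generates a single-gene, two-cohort dataset in which the infected and
#' uninfected groups overlap heavily before batch correction (large
#' opposite-sign cohort offsets swamp the modest within-cohort class
#' difference) but separate clearly after per-cohort reference-mean
#' correction: the correction removes the cohort offsets, collapsing the
#' within-group variances while the within-cohort group-mean difference is
#' untouched, so the Welch p-value drops by orders of magnitude.
#'
#' @param nPerGroup samples per phenotype group per cohort.
#' @param cohortOffsets numeric vector of per-cohort additive offsets (one
#'   per cohort, opposite signs recommended).
#' @param withinEffect within-cohort infected-minus-uninfected mean shift.
#' @param noiseSd within-group residual SD.
#' @param seed integer seed.
#' @return an \code{\link{ExpressionDataset}} with one gene.
#' @examples
#' ed <- generateSeparationFixture()
#' x <- exprsMatrix(ed)[, 1]
#' welchTTest(x[phenotype(ed) == 1], x[phenotype(ed) == 0])$pValue
#' @export
generateSeparationFixture <- function(nPerGroup = 25L,
                                      cohortOffsets = c(-6, 6),
                                      withinEffect = 1, noiseSd = 1,
                                      seed = 1L) {
  if (length(cohortOffsets) < 2L)
    stop("at least 2 cohorts are required")
  set.seed(as.integer(seed))
  nCohorts <- length(cohortOffsets)
  nPer <- 2L * nPerGroup
  n <- nCohorts * nPer
  cohortLab <- rep(sprintf("cohort%d", seq_len(nCohorts)), each = nPer)
  ph <- rep(rep(c(1L, 0L), each = nPerGroup), nCohorts)
  x <- rep(cohortOffsets, each = nPer) + withinEffect * ph +
    stats::rnorm(n, sd = noiseSd)
  X <- matrix(x, ncol = 1L,
              dimnames = list(sprintf("s%d", seq_len(n)), "gene1"))
  ExpressionDataset(X, phenotype = ph, cohort = cohortLab,
                    metadata = list(generator = "separation-fixture",
                                    seed = seed))
}

#' Random small linear-Gaussian network instance
#'
#' Generates a compact benchmark for Markov-boundary induction: a handful of
#' parent genes drive a binary phenotype through a noisy linear threshold;
#' some remaining genes are children of parents (associated with the
#' phenotype but rendered independent by their parent), optionally one
#' parent has a near-exact duplicate (creating two equivalent boundaries),
#' and the rest are independent noise.  Used for comparing
#' \code{\link{hitonPC}} against \code{\link{bruteForceMarkovBoundary}}.
#'
#' @param nGenes total gene count (at most 15 for oracle compatibility).
#' @param nSamples number of observations.
#' @param nParents number of direct parents of the phenotype.
#' @param childProb probability that a non-parent gene is a child of a
#'   random parent rather than independent noise.
#' @param duplicateParent when \code{TRUE}, one parent receives a near-exact
#'   affine duplicate.
#' @param seed integer seed.
#' @return list with \code{data} (\code{\link{ExpressionDataset}}),
#'   \code{parents} (gene ids of the direct parents), and
#'   \code{duplicateOf} (named character: duplicate gene -> parent, empty
#'   when none).
#' @examples
#' net <- generateLinearGaussianNetwork(nGenes = 8, nSamples = 500, seed = 2)
#' net$parents
#' @export
generateLinearGaussianNetwork <- function(nGenes = 10L, nSamples = 2000L,
                                          nParents = 2L, childProb = 0.4,
                                          duplicateParent = FALSE,
                                          seed = 1L) {
  if (nGenes > 15L)
    stop("keep nGenes <= 15 for oracle comparisons")
  if (nParents + duplicateParent > nGenes)
    stop("too many parents for nGenes")
  set.seed(as.integer(seed))
  n <- nSamples
  ids <- sprintf("g%d", seq_len(nGenes))
  X <- matrix(NA_real_, n, nGenes, dimnames = list(NULL, ids))

  parentIdx <- seq_len(nParents)
  for (j in parentIdx)
    X[, j] <- stats::rnorm(n)
  w <- sample(c(-1, 1), nParents, replace = TRUE) *
    stats::runif(nParents, 0.7, 1.2)
  eta <- X[, parentIdx, drop = FALSE] %*% w
  ph <- as.integer(eta + stats::rnorm(n) > 0)

  rest <- setdiff(seq_len(nGenes), parentIdx)
  duplicateOf <- character(0)
  if (duplicateParent && length(rest)) {
    dupIdx <- rest[1]
    src <- parentIdx[1]
    X[, dupIdx] <- 0.2 + 1.3 * X[, src] + stats::rnorm(n, sd = 1e-6)
    duplicateOf <- stats::setNames(ids[src], ids[dupIdx])
    rest <- rest[-1]
  }
  for (j in rest) {
    if (stats::runif(1) < childProb) {
      src <- sample(parentIdx, 1)
      X[, j] <- 0.7 * X[, src] + stats::rnorm(n, sd = sqrt(1 - 0.49))
    } else {
      X[, j] <- stats::rnorm(n)
    }
  }
  list(data = ExpressionDataset(X, phenotype = ph,
                                metadata = list(generator = "linear-network",
                                                seed = seed)),
       parents = ids[parentIdx],
       duplicateOf = duplicateOf)
}
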
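## Permutation framework quantifying preprocessing-induced gene-selection
## bias under the null of no gene-phenotype association, plus the
## before/after comparison of significant-gene sets on unpermuted data.

#' Seeded permutation of a binary phenotype
#'
#' Uniformly random rearrangement of the phenotype vector, reproducible
#' under \code{seed}; class counts are preserved exactly.  Cohort labels are
#' never permuted by the audit -- only the phenotype.
#'
#' @param phenotype binary 0/1 vector.
#' @param seed integer seed.
#' @return permuted integer vector.
#' @examples
#' permutePhenotype(c(0, 0, 1, 1, 1), seed = 42)
#' @export
permutePhenotype <- function(phenotype, seed) {
  ph <- .asBinaryPhenotype(phenotype)
  set.seed(as.integer(seed))
  sample(ph)
}

#' Number of FDR-significant genes
#'
#' Per-gene Welch two-sample t-tests of expression against the phenotype,
#' followed by Benjamini-Hochberg selection at level \code{fdrQ}.
#'
#' @param data an \code{\link{ExpressionDataset}} or samples-by-genes matrix.
#' @param phenotype binary 0/1 vector; defaults to \code{phenotype(data)}.
#' @param fdrQ FDR level (default 0.2, the conventional screening level for
#'   expression panels).
#' @return integer count of selected genes.
#' @export
countSignificant <- function(data, phenotype = NULL, fdrQ = 0.2) {
  X <- .getX(data)
  if (is.null(phenotype) && methods::is(data, "ExpressionDataset"))
    phenotype <- TieSig::phenotype(data)
  if (is.null(phenotype))
    stop("a phenotype is required")
  ph <- .asBinaryPhenotype(phenotype)
  sum(bhFdr(.colWelchP(X, ph), fdrQ))
}

#' Permutation audit of preprocessing-induced selection bias
#'
#' Under the null hypothesis of no gene-phenotype association (enforced by
#' permuting the phenotype), an unbiased preprocessing method should leave
#' essentially no gene FDR-significant.  For each permutation the phenotype
#' is permuted first, the preprocessing method is then applied (so any
#' phenotype-aware step sees the permuted labels, and the true cohort labels),
#' and the number of FDR-significant genes is recorded.  Phenotype-aware
#' batch corrections inflate this count; phenotype-blind transforms do not.
#'
#' Per-permutation RNG streams are derived deterministically from
#' \code{seed} and the permutation index, so results are reproducible and
#' independent of execution order.
#'
#' @inheritParams countSignificant
#' @param spec a \code{\link{preprocessSpec}} (or method name).
#' @param cohorts cohort labels; defaults to \code{cohort(data)}.
#' @param nPermutations number of phenotype permutations (default 10000; use
#'   a few hundred for quick audits).
#' @param seed integer master seed.
#' @return an object of class \code{BiasAuditResult}: list with
#'   \code{counts} (per-permutation significant-gene counts), \code{mean},
#'   \code{sd}, \code{stderr}, \code{interval} (central 95\% percentile
#'   interval, linear interpolation), \code{nPermutations}, \code{method},
#'   \code{fdrQ}, \code{seed}.
#' @examples
#' cs <- cohortSpec(nGenes = 50, seed = 3)
#' ed <- generateCohortData(cs)
#' auditBias(ed, "none", nPermutations = 20, seed = 1)
#' @export
auditBias <- function(data, spec, cohorts = NULL, phenotype = NULL,
                      nPermutations = 10000L, fdrQ = 0.2, seed = 1L) {
  if (is.character(spec))
    spec <- preprocessSpec(spec)
  X <- .getX(data)
  if (is.null(cohorts) && methods::is(data, "ExpressionDataset"))
    cohorts <- cohort(data)
  if (is.null(phenotype) && methods::is(data, "ExpressionDataset"))
    phenotype <- TieSig::phenotype(data)
  if (is.null(phenotype))
    stop("a phenotype is required")
  ph <- .asBinaryPhenotype(phenotype)

  set.seed(as.integer(seed))
  permSeeds <- sample.int(.Machine$integer.max - 1L, nPermutations)
  counts <- integer(nPermutations)
  for (i in seq_len(nPermutations)) {
    counts[i] <- tryCatch({
      phi <- permutePhenotype(ph, permSeeds[i])
      Xi <- .applyPreprocMatrix(X, spec, cohorts, phi)
      sum(bhFdr(.colWelchP(Xi, phi), fdrQ))
    }, error = function(e) {
      stop("permutation ", i, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  structure(list(counts = counts,
                 mean = mean(counts),
                 sd = stats::sd(counts),
                 stderr = stats::sd(counts) / sqrt(nPermutations),
                 interval = unname(stats::quantile(counts,
                                                   c(0.025, 0.975),
                                                   type = 7)),
                 nPermutations = nPermutations,
                 method = spec,
                 fdrQ = fdrQ,
                 seed = as.integer(seed)),
            class = "BiasAuditResult")
}

#' @export
print.BiasAuditResult <- function(x, ...) {
  cat("Permutation bias audit (", x$nPermutations, " permutations, FDR q = ",
      x$fdrQ, ")\n", sep = "")
  cat("  method:", x$method$method, "\n")
  cat(sprintf("  significant genes: mean %.3f, sd %.3f, stderr %.4f\n",
              x$mean, x$sd, x$stderr))
  cat(sprintf("  95%% interval: [%.1f, %.1f]\n",
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' Significant-gene sets before and after preprocessing
#'
#' On the real (unpermuted) phenotype, computes the FDR-significant gene set
#' for each preprocessing specification and compares it against the
#' no-preprocessing baseline: which genes are retained, lost, and gained.
#'
#' @inheritParams auditBias
#' @param specs list of \code{\link{preprocessSpec}} objects or method
#'   names.
#' @return an object of class \code{SignificanceComparison}: list with
#'   \code{baseline} (significant gene ids under no preprocessing) and
#'   \code{perMethod}, a named list with elements \code{significant},
#'   \code{retained}, \code{lost}, \code{gained} per spec.
#' @export
beforeAfterSignificance <- function(data, specs, cohorts = NULL,
                                    phenotype = NULL, fdrQ = 0.2) {
  X <- .getX(data)
  if (is.null(cohorts) && methods::is(data, "ExpressionDataset"))
    cohorts <- cohort(data)
  if (is.null(phenotype) && methods::is(data, "ExpressionDataset"))
    phenotype <- TieSig::phenotype(data)
  ph <- .asBinaryPhenotype(phenotype)
  geneIds <- colnames(X)
  if (is.null(geneIds))
    geneIds <- sprintf("gene_%d", seq_len(ncol(X)))

  sigSet <- function(Y) geneIds[bhFdr(.colWelchP(Y, ph), fdrQ)]
  baseline <- sigSet(X)
  perMethod <- lapply(specs, function(spec) {
    if (is.character(spec)) spec <- preprocessSpec(spec)
    sig <- sigSet(.applyPreprocMatrix(X, spec, cohorts, ph))
    list(method = spec$method,
         significant = sig,
         retained = intersect(baseline, sig),
         lost = setdiff(baseline, sig),
         gained = setdiff(sig, baseline))
  })
  names(perMethod) <- vapply(perMethod, `[[`, character(1), "method")
  structure(list(baseline = baseline, perMethod = perMethod, fdrQ = fdrQ),
            class = "SignificanceComparison")
}

#' @export
print.SignificanceComparison <- function(x, ...) {
  cat("Significant genes (FDR q = ", x$fdrQ, "): ", length(x$baseline),
      " with no preprocessing\n", sep = "")
  for (nm in names(x$perMethod)) {
    m <- x$perMethod[[nm]]
    cat(sprintf("  %-24s %5d significant (retained %d, lost %d, gained %d)\n",
                nm, length(m$significant), length(m$retained),
                length(m$lost), length(m$gained)))
  }
  invisible(x)
}
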
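## TIE*: enumeration of all maximally predictive, non-redundant signatures.
## The inducer is re-run on data with subsets of already-discovered signature
## genes hidden; each candidate boundary is verified for information
## equivalence against the primary (full-data) signature.

#' Parameters of the TIE* signature enumeration
#'
#' @param maxRemovalCardinality maximum number of genes hidden in one
#'   enumeration step (default 5).  Removals accumulate along a signature's
#'   lineage: a signature found with hidden set H can spawn candidates with
#'   hidden set H union G for any new subset G up to this cardinality, so
#'   deeply nested equivalence structures remain reachable while each
#'   individual step stays small.
#' @param alphaVerify significance level for candidate verification;
#'   defaults to the base inducer's alpha.
#' @param baseParams a \code{\link{gllParams}} object for the base inducer.
#' @param maxSignatures safety cap on the number of accepted signatures;
#'   reaching it raises a warning (never a silent truncation).
#' @return an object of class \code{TieStarParams}.
#' @examples
#' tieStarParams()
#' @export
tieStarParams <- function(maxRemovalCardinality = 5L, alphaVerify = NULL,
                          baseParams = gllParams(), maxSignatures = 10000L) {
  if (maxRemovalCardinality < 1) stop("maxRemovalCardinality must be >= 1")
  if (is.null(alphaVerify)) alphaVerify <- baseParams$alpha
  if (alphaVerify <= 0 || alphaVerify >= 1) stop("alphaVerify must lie in (0, 1)")
  structure(list(maxRemovalCardinality = as.integer(maxRemovalCardinality),
                 alphaVerify = alphaVerify, baseParams = baseParams,
                 maxSignatures = as.integer(maxSignatures)),
            class = "TieStarParams")
}

#' Enumerate all maximally predictive, non-redundant signatures (TIE*)
#'
#' Runs the base inducer (\code{\link{hitonPC}}) on the full data to obtain
#' the primary signature, then systematically hides subsets of the genes
#' appearing in accepted signatures and re-runs the inducer on the reduced
#' data.  A candidate signature is accepted when it is new and passes
#' verification: every gene of the primary signature not contained in the
#' candidate must be rendered independent of the phenotype by some subset of
#' the candidate (cardinality at most max-k) at level \code{alphaVerify} --
#' i.e. the primary signature carries no information beyond the candidate.
#' Hidden subsets accumulate along lineages (see
#' \code{\link{tieStarParams}}), and enumeration proceeds in increasing
#' cardinality, lexicographically within cardinality, until no new signature
#' is accepted.  The result is deterministic given data and parameters, and
#' invariant to gene-column order up to canonicalization.
#'
#' @param data an \code{\link{ExpressionDataset}} with a binary phenotype.
#' @param params a \code{\link{tieStarParams}} object.
#' @return a \code{\link{SignatureSet}}; the primary signature is first and
#'   provenance records each signature's hidden-set lineage.
#' @examples
#' tied <- generateTiedLike(equivalenceSpec(nSamples = 400, nGenes = 40,
#'                                          classSizes = c(2, 2), seed = 7))
#' ss <- tieStar(tied$data)
#' length(ss)   # 4 = 2 x 2 equivalent signatures
#' @export
tieStar <- function(data, params = tieStarParams()) {
  base <- params$baseParams
  si <- .screenInput(data)
  n <- nrow(si$X)
  r <- as.vector(stats::cor(si$X, si$ph))
  pmarg <- .fisherZP(r, n, 0)
  keep <- which(pmarg <= base$alpha)
  if (!length(keep))
    return(SignatureSet(list()))
  ord <- keep[order(-abs(r[keep]), keep)]
  genes <- colnames(si$X)[ord]
  V <- cbind(si$X[, ord, drop = FALSE], si$ph)
  R <- stats::cor(V)
  targetIdx <- ncol(V)
  nc <- length(ord)

  runInducer <- function(hidden) {
    candOrder <- setdiff(seq_len(nc), hidden)
    .hitonCore(R, n, candOrder, targetIdx, base$alpha, base$maxK)
  }
  setKey <- function(idx) paste0("k", paste(sort(idx), collapse = ","))

  m0 <- runInducer(integer(0))
  verifyIdx <- function(candIdx) {
    for (g in setdiff(m0, candIdx)) {
      if (!.dismissed(R, n, g, targetIdx, candIdx, params$alphaVerify,
                      base$maxK))
        return(FALSE)
    }
    TRUE
  }

  accepted <- list(list(sig = m0, hidden = integer(0)))
  sigKeys <- setKey(m0)
  processedHidden <- new.env(parent = emptyenv())
  assign(setKey(integer(0)), TRUE, envir = processedHidden)
  capped <- FALSE

  repeat {
    unionIdx <- sort(unique(unlist(lapply(accepted, `[[`, "sig"))))
    newThisSweep <- FALSE
    for (node in accepted) {
      pool <- setdiff(unionIdx, node$hidden)
      kmax <- min(params$maxRemovalCardinality, length(pool))
      for (k in seq_len(kmax)) {
        combs <- .kSubsets(pool, k)
        for (col in seq_len(ncol(combs))) {
          hidden <- sort(c(node$hidden, combs[, col]))
          hkey <- setKey(hidden)
          if (!is.null(processedHidden[[hkey]]))
            next
          assign(hkey, TRUE, envir = processedHidden)
          cand <- runInducer(hidden)
          if (!length(cand))
            next
          ckey <- setKey(cand)
          if (ckey %in% sigKeys)
            next
          if (!verifyIdx(cand))
            next
          accepted[[length(accepted) + 1L]] <- list(sig = cand,
                                                    hidden = hidden)
          sigKeys <- c(sigKeys, ckey)
          newThisSweep <- TRUE
          if (length(accepted) >= params$maxSignatures) {
            warning("signature cap (", params$maxSignatures,
                    ") reached; enumeration stopped early")
            capped <- TRUE
            break
          }
        }
        if (capped) break
      }
      if (capped) break
    }
    if (capped || !newThisSweep)
      break
  }

  SignatureSet(signatures = lapply(accepted, function(a) genes[a$sig]),
               provenance = lapply(accepted, function(a) genes[a$hidden]),
               verified = rep(TRUE, length(accepted)))
}

#' Verify a candidate signature against a reference signature
#'
#' A candidate is information-equivalent to the reference when the reference
#' carries no information about the phenotype beyond the candidate: every
#' reference gene outside the candidate must be independent of the phenotype
#' given some subset of the candidate of cardinality at most \code{maxK}
#' (Fisher Z at \code{alphaVerify}).
#'
#' @param data an \code{\link{ExpressionDataset}} with a binary phenotype.
#' @param candidate,reference character vectors of gene ids.
#' @param alphaVerify significance level of the verification tests.
#' @param maxK maximum conditioning-set cardinality.
#' @return \code{TRUE} when the candidate is accepted.
#' @examples
#' tied <- generateTiedLike(equivalenceSpec(nSamples = 400, nGenes = 20,
#'                                          classSizes = 2, seed = 1))
#' gt <- signatures(tied$groundTruth)
#' verifyCandidate(tied$data, gt[[1]], gt[[2]])
#' @export
verifyCandidate <- function(data, candidate, reference,
                            alphaVerify = 1e-5, maxK = 1L) {
  M <- .testMatrix(data)
  candidate <- unique(as.character(candidate))
  reference <- unique(as.character(reference))
  missing <- setdiff(c(candidate, reference), colnames(M))
  if (length(missing))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  toExplain <- setdiff(reference, candidate)
  if (!length(toExplain))
    return(TRUE)
  cols <- c(toExplain, candidate, "phenotype")
  V <- M[, cols, drop = FALSE]
  R <- stats::cor(V)
  n <- nrow(V)
  targetIdx <- length(cols)
  candIdx <- seq_along(candidate) + length(toExplain)
  for (gi in seq_along(toExplain)) {
    if (!.dismissed(R, n, gi, targetIdx, candIdx, alphaVerify, maxK))
      return(FALSE)
  }
  TRUE
}
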
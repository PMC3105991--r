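#' SignatureSet: a collection of canonicalized gene signatures
#'
#' Holds the output of \code{\link{tieStar}}: a list of maximally predictive,
#' non-redundant gene sets for one phenotype.  Signatures are canonicalized
#' (gene ids sorted, duplicates removed) on construction.  Each signature
#' carries its removed-subset lineage (the cumulative set of genes that was
#' hidden from the inducer when the signature was discovered) and a verified
#' flag.
#'
#' @param signatures list of character vectors of gene/probe ids.
#' @param provenance list of character vectors: per signature, the genes
#'   hidden from the data when it was found (empty for the primary
#'   signature).
#' @param verified logical vector, one flag per signature.
#' @param x,object a \code{SignatureSet}.
#'
#' @return \code{SignatureSet()} returns a \code{SignatureSet}.
#'   \code{signatures()} the list of sorted gene-id vectors;
#'   \code{signatureSizes()} an integer vector; \code{unionGenes()} the
#'   sorted union of all member genes; \code{provenance()} the lineage list.
#'
#' @examples
#' ss <- SignatureSet(list(c("g2", "g1"), c("g1", "g3")))
#' signatures(ss)
#' unionGenes(ss)
#'
#' @name SignatureSet
#' @aliases SignatureSet-class signatures signatureSizes unionGenes provenance
#' @export SignatureSet
#' @exportClass SignatureSet
setClass("SignatureSet",
         representation(signatures = "list",
                        provenance = "list",
                        verified = "logical"))

.canonSignature <- function(genes) sort(unique(as.character(genes)))

.signatureKey <- function(genes) paste(.canonSignature(genes), collapse = ",")

.validSignatureSet <- function(object) {
  msg <- character(0)
  sigs <- object@signatures
  if (!all(vapply(sigs, is.character, logical(1))))
    msg <- c(msg, "signatures must be character vectors")
  keys <- vapply(sigs, .signatureKey, character(1))
  if (anyDuplicated(keys))
    msg <- c(msg, "duplicate signatures after canonicalization")
  if (length(object@provenance) != length(sigs))
    msg <- c(msg, "provenance length must match signature count")
  if (length(object@verified) != length(sigs))
    msg <- c(msg, "verified length must match signature count")
  if (length(msg)) msg else TRUE
}
setValidity("SignatureSet", .validSignatureSet)

SignatureSet <- function(signatures = list(), provenance = NULL,
                         verified = NULL) {
  signatures <- lapply(signatures, .canonSignature)
  if (is.null(provenance))
    provenance <- rep(list(character(0)), length(signatures))
  provenance <- lapply(provenance, as.character)
  if (is.null(verified))
    verified <- rep(TRUE, length(signatures))
  methods::new("SignatureSet", signatures = signatures,
               provenance = provenance, verified = as.logical(verified))
}

#' @rdname SignatureSet
#' @export
setMethod("signatures", "SignatureSet", function(x) x@signatures)

#' @rdname SignatureSet
#' @export
setMethod("signatureSizes", "SignatureSet", function(x) {
  vapply(x@signatures, length, integer(1))
})

#' @rdname SignatureSet
#' @export
setMethod("unionGenes", "SignatureSet", function(x) {
  sort(unique(unlist(x@signatures, use.names = FALSE)))
})

#' @rdname SignatureSet
#' @export
setMethod("provenance", "SignatureSet", function(x) x@provenance)

#' @rdname SignatureSet
#' @export
setMethod("length", "SignatureSet", function(x) length(x@signatures))

setMethod("show", "SignatureSet", function(object) {
  n <- length(object@signatures)
  cat("SignatureSet with", n, "signature(s)\n")
  if (n) {
    sz <- signatureSizes(object)
    cat("  sizes: min", min(sz), "/ mean", round(mean(sz), 2),
        "/ max", max(sz), "\n")
    cat("  union:", length(unionGenes(object)), "distinct genes\n")
    show_n <- min(n, 5L)
    for (i in seq_len(show_n))
      cat("  [", i, "] ", paste(object@signatures[[i]], collapse = ", "),
          "\n", sep = "")
    if (n > show_n) cat("  ...\n")
  }
})

#' Summary statistics of a signature collection
#'
#' Reports the number of signatures, mean signature size, size of the union
#' of member genes, and per-gene participation: the percentage of signatures
#' each gene appears in (the statistic tabulated for frequently selected
#' probes).
#'
#' @param x a \code{SignatureSet}.
#' @return a list with elements \code{count}, \code{meanSize},
#'   \code{unionSize}, and \code{participation} (a data.frame with columns
#'   \code{gene} and \code{percent}, sorted by decreasing participation).
#' @examples
#' ss <- SignatureSet(list(c("a", "b"), c("a", "c")))
#' summarizeSignatures(ss)
#' @rdname summarizeSignatures
#' @export
setMethod("summarizeSignatures", "SignatureSet", function(x) {
  sigs <- signatures(x)
  if (!length(sigs))
    stop("empty SignatureSet")
  genes <- sort(unique(unlist(sigs, use.names = FALSE)))
  counts <- vapply(genes, function(g) {
    sum(vapply(sigs, function(s) g %in% s, logical(1)))
  }, integer(1))
  pct <- 100 * counts / length(sigs)
  ord <- order(-pct, genes)
  list(count = length(sigs),
       meanSize = mean(signatureSizes(x)),
       unionSize = length(genes),
       participation = data.frame(gene = genes[ord],
                                  percent = unname(pct[ord]),
                                  stringsAsFactors = FALSE))
})
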
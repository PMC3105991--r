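## Generics are collated first (C-locale filename order) so the class files
## can attach methods at load time.

#' @rdname ExpressionDataset
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname ExpressionDataset
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname ExpressionDataset
#' @export
setGeneric("phenotype<-", function(x, value) standardGeneric("phenotype<-"))

#' @rdname ExpressionDataset
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))

#' @rdname ExpressionDataset
#' @export
setGeneric("cohort<-", function(x, value) standardGeneric("cohort<-"))

#' @rdname ExpressionDataset
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname ExpressionDataset
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SignatureSet
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname SignatureSet
#' @export
setGeneric("signatureSizes", function(x) standardGeneric("signatureSizes"))

#' @rdname SignatureSet
#' @export
setGeneric("unionGenes", function(x) standardGeneric("unionGenes"))

#' @rdname SignatureSet
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname summarizeSignatures
#' @export
setGeneric("summarizeSignatures", function(x) standardGeneric("summarizeSignatures"))
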
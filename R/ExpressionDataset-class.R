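#' ExpressionDataset: expression matrix with phenotype and cohort labels
#'
#' The pipeline currency: a \linkS4class{SummarizedExperiment} holding one
#' assay of normalized (typically log-scale) expression values, stored
#' genes-in-rows as is conventional for Bioconductor containers.  The binary
#' phenotype (1 = infected/symptomatic, 0 = uninfected) and an optional
#' cohort/batch label live in \code{colData}.  Most algorithms in the package
#' consume the samples-by-genes orientation, available via
#' \code{exprsMatrix()}.
#'
#' @param exprs numeric matrix of expression values, samples in rows and
#'   genes in columns (the orientation of a delimited text export; it is
#'   transposed internally).  Must be finite, with unique row and column
#'   names (generated when absent).
#' @param phenotype optional binary phenotype, coercible to 0/1 (logical,
#'   two-level factor, or numeric vector of 0s and 1s), one value per sample.
#' @param cohort optional cohort/batch label, one per sample.
#' @param metadata optional named list of free-form provenance.
#' @param x an \code{ExpressionDataset}.
#' @param value replacement value for the setter.
#'
#' @return \code{ExpressionDataset()} returns an \code{ExpressionDataset}
#'   object.  \code{exprsMatrix()} returns the samples-by-genes numeric
#'   matrix; \code{phenotype()} an integer 0/1 vector (or \code{NULL});
#'   \code{cohort()} a factor (or \code{NULL}); \code{probeIds()} and
#'   \code{sampleIds()} character vectors.
#'
#' @examples
#' m <- matrix(rnorm(40), nrow = 10,
#'             dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
#' ed <- ExpressionDataset(m, phenotype = rep(c(0, 1), each = 5))
#' dim(exprsMatrix(ed))
#' table(phenotype(ed))
#'
#' @name ExpressionDataset
#' @aliases ExpressionDataset-class exprsMatrix phenotype phenotype<- cohort
#'   cohort<- probeIds sampleIds
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
#' @importFrom S4Vectors DataFrame metadata
#' @export ExpressionDataset
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

.validExpressionDataset <- function(object) {
  msg <- character(0)
  a <- SummarizedExperiment::assay(object)
  if (!is.numeric(a))
    msg <- c(msg, "assay must be numeric")
  if (anyNA(a) || any(!is.finite(a)))
    msg <- c(msg, "assay contains missing or non-finite values")
  cd <- SummarizedExperiment::colData(object)
  if ("phenotype" %in% colnames(cd)) {
    ph <- cd$phenotype
    if (!all(ph %in% c(0L, 1L)))
      msg <- c(msg, "phenotype must be coded 0/1")
  }
  if ("cohort" %in% colnames(cd)) {
    co <- cd$cohort
    if (anyNA(co) || any(!nzchar(as.character(co))))
      msg <- c(msg, "cohort labels must be nonempty")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionDataset", .validExpressionDataset)

.asBinaryPhenotype <- function(phenotype) {
  if (is.logical(phenotype)) return(as.integer(phenotype))
  if (is.factor(phenotype)) {
    if (nlevels(droplevels(phenotype)) != 2L)
      stop("phenotype must have exactly 2 levels")
    return(as.integer(droplevels(phenotype)) - 1L)
  }
  ph <- as.numeric(phenotype)
  if (!all(ph %in% c(0, 1)))
    stop("numeric phenotype must contain only 0 and 1")
  as.integer(ph)
}

ExpressionDataset <- function(exprs, phenotype = NULL, cohort = NULL,
                              metadata = list()) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (is.null(rownames(exprs)))
    rownames(exprs) <- sprintf("sample_%d", seq_len(nrow(exprs)))
  if (is.null(colnames(exprs)))
    colnames(exprs) <- sprintf("gene_%d", seq_len(ncol(exprs)))
  if (anyDuplicated(rownames(exprs)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(exprs)))
    stop("duplicate probe ids")
  cd <- S4Vectors::DataFrame(row.names = rownames(exprs))
  if (!is.null(phenotype)) {
    if (length(phenotype) != nrow(exprs))
      stop("phenotype length does not match sample count")
    cd$phenotype <- .asBinaryPhenotype(phenotype)
  }
  if (!is.null(cohort)) {
    if (length(cohort) != nrow(exprs))
      stop("cohort length does not match sample count")
    cd$cohort <- factor(cohort)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = t(exprs)), colData = cd, metadata = metadata)
  methods::new("ExpressionDataset", se)
}

#' @rdname ExpressionDataset
#' @export
setMethod("exprsMatrix", "ExpressionDataset", function(x) {
  t(SummarizedExperiment::assay(x, "exprs"))
})

#' @rdname ExpressionDataset
#' @export
setMethod("phenotype", "ExpressionDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("phenotype" %in% colnames(cd)) as.integer(cd$phenotype) else NULL
})

#' @rdname ExpressionDataset
#' @export
setMethod("phenotype<-", "ExpressionDataset", function(x, value) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(value)) {
    cd$phenotype <- NULL
  } else {
    if (length(value) != ncol(x))
      stop("phenotype length does not match sample count")
    cd$phenotype <- .asBinaryPhenotype(value)
  }
  SummarizedExperiment::colData(x) <- cd
  methods::validObject(x)
  x
})

#' @rdname ExpressionDataset
#' @export
setMethod("cohort", "ExpressionDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("cohort" %in% colnames(cd)) factor(cd$cohort) else NULL
})

#' @rdname ExpressionDataset
#' @export
setMethod("cohort<-", "ExpressionDataset", function(x, value) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(value)) {
    cd$cohort <- NULL
  } else {
    if (length(value) != ncol(x))
      stop("cohort length does not match sample count")
    cd$cohort <- factor(value)
  }
  SummarizedExperiment::colData(x) <- cd
  methods::validObject(x)
  x
})

#' @rdname ExpressionDataset
#' @export
setMethod("probeIds", "ExpressionDataset", function(x) rownames(x))

#' @rdname ExpressionDataset
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset:", ncol(object), "samples x", nrow(object), "genes\n")
  ph <- phenotype(object)
  if (!is.null(ph))
    cat("  phenotype: ", sum(ph == 1L), " positive / ", sum(ph == 0L),
        " negative\n", sep = "")
  co <- cohort(object)
  if (!is.null(co))
    cat("  cohorts:", paste(sprintf("%s (%d)", levels(co), table(co)),
                            collapse = ", "), "\n")
})
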